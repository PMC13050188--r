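# random locus draws used by property-style tests
random_locus <- function(with_sibling = TRUE) {
  locus_params(q2 = runif(1, 0.05, 0.95),
               beta_c = runif(1, -1, 1), beta_m = runif(1, -1, 1),
               beta_f = runif(1, -1, 1), beta_i = runif(1, -1, 1),
               beta_s = if (with_sibling) runif(1, -1, 1) else 0)
}

# allele relabeling A2 <-> A1: q2 -> q1, all betas flip sign
relabel_locus <- function(l) {
  locus_params(q2 = l$q1, beta_c = -l$beta_c, beta_m = -l$beta_m,
               beta_f = -l$beta_f, beta_i = -l$beta_i, beta_s = -l$beta_s)
}

# tiny deterministic simulation shared by several tests
small_sim <- function(scenario = NULL,
                      n = 400, n_loci = 40, generations = 2, rho_y = 0,
                      seed = 99, ...) {
  if (is.null(scenario)) scenario <- effect_scenario("V1", n_causal = n_loci)
  set.seed(seed)
  panel <- founder_panel(n, n_loci, ld_decay = 0.2)
  run_generations(panel, scenario, generations = generations,
                  rho_y = rho_y, ...)
}
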