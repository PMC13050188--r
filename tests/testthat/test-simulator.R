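test_that("founder panels are reproducible and honor the LD-decay knob", {
  p1 <- founder_panel(300, 80, ld_decay = 0.5, seed = 7)
  p2 <- founder_panel(300, 80, ld_decay = 0.5, seed = 7)
  expect_identical(p1$hap, p2$hap)
  expect_true(all(p1$hap %in% c(0L, 1L)))
  expect_true(all(p1$freq > 0 & p1$freq < 1))

  p0 <- founder_panel(1000, 60, ld_decay = 0, seed = 8)
  adj0 <- sapply(2:60, function(j) cor(p0$hap[, j - 1], p0$hap[, j]))
  expect_lt(mean(abs(adj0)), 3 / sqrt(2000))

  p9 <- founder_panel(1000, 60, ld_decay = 0.9, seed = 8)
  adj1 <- mean(abs(sapply(2:60, function(j)
    cor(p9$hap[, j - 1], p9$hap[, j]))))
  lag5 <- mean(abs(sapply(6:60, function(j)
    cor(p9$hap[, j - 5], p9$hap[, j]))))
  expect_gt(adj1, 0.5)
  expect_gt(adj1, lag5)  # correlation decays with distance
  expect_error(founder_panel(10, 5, ld_decay = 1), "ld_decay")
})

test_that("meiosis respects linkage limits and Mendelian transmission", {
  set.seed(20)
  p <- founder_panel(500, 40, ld_decay = 0.3)
  mat <- p$hap[seq(1, 1000, 2), ]
  pat <- p$hap[seq(2, 1000, 2), ]
  g0 <- meiosis(mat, pat, recomb_rate = 0, seed = 21)
  intact <- sapply(seq_len(500), function(i)
    all(g0[i, ] == mat[i, ]) || all(g0[i, ] == pat[i, ]))
  expect_true(all(intact))
  # transmitted allele frequency equals parental frequency (binomial tol)
  g1 <- meiosis(mat, pat, recomb_rate = 0.5, seed = 22)
  pf <- colMeans(mat + pat) / 2
  expect_lt(max(abs(colMeans(g1) - pf)), 4 * sqrt(0.25 / 500))
})

test_that("phenotype-ordering assortment hits its target correlation", {
  set.seed(30)
  yf <- rnorm(3000); ym <- rnorm(3000)
  pr0 <- assort_mates(yf, ym, 0)
  expect_lt(abs(cor(yf[pr0[, 1]], ym[pr0[, 2]])), 3 / sqrt(3000))
  pr1 <- assort_mates(yf, ym, 1)
  expect_gt(cor(yf[pr1[, 1]], ym[pr1[, 2]]), 0.99)
  pr2 <- assort_mates(yf, ym, 0.2)
  expect_equal(cor(yf[pr2[, 1]], ym[pr2[, 2]]), 0.2, tolerance = 0.1)
  expect_error(assort_mates(rnorm(5), rnorm(6), 0.5), "equal numbers")
})

test_that("sampled effects match scenario targets and correlations", {
  set.seed(40)
  p <- founder_panel(2000, 1200, ld_decay = 0.1)
  e1 <- sample_effects(effect_scenario("V1", n_causal = 300), p)
  expect_true(all(e1$beta_m == 0) && all(e1$beta_f == 0) &&
                all(e1$beta_i == 0) && all(e1$beta_s == 0))
  expect_equal(sum(2 * e1$q2 * e1$q1 * e1$beta_c^2), 0.5, tolerance = 1e-12)
  e5 <- sample_effects(effect_scenario("V5", n_causal = 1000), p)
  expect_lt(abs(cor(e5$beta_c, e5$beta_m) - 0.3), 0.1)
  expect_lt(abs(cor(e5$beta_f, e5$beta_i) + 0.2), 0.1)
  expect_equal(sum(2 * e5$q2 * e5$q1 * e5$beta_i^2), 0.1, tolerance = 1e-12)
  expect_error(sample_effects(effect_scenario("V1", n_causal = 5000), p),
               "n_causal")
})

test_that("phenotypes follow the mating-table term structure", {
  eff <- locus_params(0.5, beta_c = 1, beta_m = 0.5, beta_f = -0.5,
                      beta_i = 0.2)
  # trio: mother A1A1, father A1A2, child A1A2 (paternal A2)
  ph <- compute_phenotypes(mat = matrix(0L, 1, 1), pat = matrix(1L, 1, 1),
                           effects = eff,
                           mother_geno = matrix(0L, 1, 1),
                           father_geno = matrix(1L, 1, 1),
                           env_var = 0)
  expect_equal(ph$genetic, 1 - 0.5 - 0.2)  # bc + bf - bi
  # all effects zero: pure environmental noise
  set.seed(50)
  z <- compute_phenotypes(matrix(0L, 5000, 1), matrix(0L, 5000, 1),
                          locus_params(0.5), env_var = 0.7)
  expect_equal(var(z$phenotype), 0.7, tolerance = 0.05)
  expect_error(
    compute_phenotypes(matrix(0L, 2, 1), matrix(0L, 2, 1),
                       locus_params(0.5, beta_s = 1), env_var = 1),
    "sib_geno")
})

test_that("generations preserve phase consistency, frequencies and determinism", {
  s1 <- small_sim(generations = 3, seed = 60)
  s2 <- small_sim(generations = 3, seed = 60)
  expect_identical(s1$gen[[4]]$mat, s2$gen[[4]]$mat)
  expect_identical(s1$log, s2$log)
  for (g in s1$gen) {
    expect_true(all(g$mat %in% c(0L, 1L)) && all(g$pat %in% c(0L, 1L)))
    x <- g$mat + g$pat
    xi <- g$mat - g$pat
    expect_true(all(xi[x != 1L] == 0L))
    expect_true(all(abs(xi[x == 1L]) == 1L))
  }
  # sibling links are mutual and share both parents
  g <- s1$gen[[2]]
  expect_identical(g$sib[g$sib], seq_along(g$sib))
  expect_identical(g$mother, g$mother[g$sib])
  # allele frequencies stay within drift bounds across 3 generations
  f0 <- colMeans(s1$gen[[1]]$mat + s1$gen[[1]]$pat) / 2
  f3 <- colMeans(s1$gen[[4]]$mat + s1$gen[[4]]$pat) / 2
  expect_lt(max(abs(f3 - f0)), 6 * sqrt(3 * 0.25 / (2 * s1$n)))
})

test_that("assortative mating inflates variance and homozygosity but not frequencies", {
  scen <- effect_scenario("V1", n_causal = 60)
  set.seed(70)
  panel <- founder_panel(2000, 60, ld_decay = 0.2)
  eff <- sample_effects(scen, panel)
  set.seed(71)
  s_rm <- run_generations(panel, scen, generations = 6, rho_y = 0,
                          effects = eff)
  set.seed(71)
  s_am <- run_generations(panel, scen, generations = 6, rho_y = 0.6,
                          effects = eff)
  n_gen <- 6
  expect_gt(s_am$log$var_genetic[n_gen], s_rm$log$var_genetic[n_gen])
  expect_lt(s_am$log$het_causal[n_gen], s_rm$log$het_causal[n_gen])
  expect_gt(s_am$log$rho_g_realized[n_gen], 0.2)
  f_am <- colMeans(s_am$gen[[7]]$mat + s_am$gen[[7]]$pat) / 2
  expect_lt(max(abs(f_am - panel$freq[s_am$causal])),
            6 * sqrt(6 * 0.25 / (2 * 2000)))
  # one generation of random mating roughly preserves genetic variance
  expect_equal(s_rm$log$var_genetic[1], var(s_rm$gen[[1]]$genetic),
               tolerance = 0.15)
})

test_that("closed-loop calibration reaches a target mate score correlation", {
  scen <- effect_scenario("V1", n_causal = 50)
  set.seed(80)
  panel <- founder_panel(3000, 50, ld_decay = 0.2)
  s <- run_generations(panel, scen, generations = 4, calibrate_rho_g = 0.2)
  expect_lt(abs(mean(s$log$rho_g_realized[2:4]) - 0.2), 0.03)
})
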