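#' Gamete formation with recombination
#'
#' Produces one gamete per parent row from phased parental genotypes. The
#' starting strand is chosen fairly, and crossovers occur independently in
#' each adjacent-locus interval with probability `recomb_rate` (0.5 gives
#' free recombination, 0 transmits an intact haplotype).
#'
#' @param mat,pat Parent haplotype matrices (n x L, 0/1), maternal and
#'   paternal strands.
#' @param recomb_rate Per-interval crossover probability in \[0, 0.5\].
#' @param seed Optional integer seed.
#' @return An n x L 0/1 integer matrix of transmitted haplotypes.
#' @export
meiosis <- function(mat, pat, recomb_rate = 0.5, seed = NULL) {
  stopifnot(is.matrix(mat), is.matrix(pat), all(dim(mat) == dim(pat)),
            recomb_rate >= 0, recomb_rate <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mat); L <- ncol(mat)
  strand <- matrix(0L, n, L)
  acc <- as.integer(runif(n) < 0.5)
  strand[, 1] <- acc
  if (L > 1) for (j in 2:L) {
    acc <- (acc + as.integer(runif(n) < recomb_rate)) %% 2L
    strand[, j] <- acc
  }
  out <- mat * (1L - strand) + pat * strand
  storage.mode(out) <- "integer"
  out
}

#' Mate pairing by phenotype ordering
#'
#' Pairs prospective mothers and fathers so that the realized correlation of
#' their phenotypes approximates `rho_y`. A bivariate Gaussian template with
#' correlation `rho_y` is drawn; the two sexes' phenotypes are rank-matched
#' against the template's two coordinates, which yields smooth intermediate
#' correlations (rho_y = 0 is random pairing, rho_y = 1 sorts both lists).
#'
#' @param phen_f,phen_m Phenotypes of prospective mothers and fathers;
#'   must have equal length.
#' @param rho_y Target mate phenotypic correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A two-column integer matrix `cbind(mother, father)` of indices
#'   into `phen_f` / `phen_m`, one row per pair.
#' @export
assort_mates <- function(phen_f, phen_m, rho_y, seed = NULL) {
  if (length(phen_f) != length(phen_m))
    stop("equal numbers of prospective mothers and fathers are required")
  stopifnot(rho_y >= 0, rho_y <= 1)
  if (!is.null(seed)) set.seed(seed)
  np <- length(phen_f)
  u <- rnorm(np)
  v <- rho_y * u + sqrt(1 - rho_y^2) * rnorm(np)
  mo <- order(phen_f)[rank(u, ties.method = "first")]
  fa <- order(phen_m)[rank(v, ties.method = "first")]
  cbind(mother = mo, father = fa)
}

#' Phenotypes from phased genotypes, parental genotypes and effects
#'
#' Builds `Y = sum_j [Xc*beta_c + Xm*beta_m + Xf*beta_f + Xi*beta_i +
#' Xs*beta_s] + e`, with `Xc = Am + Af` the child dosage, `Xi = Am - Af`
#' the imprinting code (maternal minus paternal allele), `Xm`, `Xf`, `Xs`
#' the mother's, father's and sibling's dosages, and
#' `e ~ Normal(0, env_var)`. Missing parent matrices contribute zero (as
#' for founders); a missing sibling matrix is an error when any sibling
#' effect is nonzero.
#'
#' @param mat,pat Child haplotype matrices at the causal loci (n x l, 0/1).
#' @param effects A [locus_params] for the causal loci (l rows).
#' @param mother_geno,father_geno,sib_geno Optional n x l dosage matrices.
#' @param env_var Environmental variance (>= 0).
#' @param seed Optional integer seed.
#' @return A list with `phenotype`, `genetic` (the genotype-side sum) and
#'   `parts` (n x 5 matrix of per-class genetic values).
#' @export
compute_phenotypes <- function(mat, pat, effects, mother_geno = NULL,
                               father_geno = NULL, sib_geno = NULL,
                               env_var = 0.5, seed = NULL) {
  effects <- as_locus_params(effects)
  stopifnot(ncol(mat) == nrow(effects), all(dim(mat) == dim(pat)),
            env_var >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mat)
  if (is.null(sib_geno) && any(effects$beta_s != 0))
    stop("sibling effects are active but `sib_geno` is missing")
  parts <- matrix(0, n, 5,
                  dimnames = list(NULL, c("direct", "maternal", "paternal",
                                          "imprinting", "sibling")))
  parts[, "direct"] <- (mat + pat) %*% effects$beta_c
  parts[, "imprinting"] <- (mat - pat) %*% effects$beta_i
  if (!is.null(mother_geno))
    parts[, "maternal"] <- mother_geno %*% effects$beta_m
  if (!is.null(father_geno))
    parts[, "paternal"] <- father_geno %*% effects$beta_f
  if (!is.null(sib_geno))
    parts[, "sibling"] <- sib_geno %*% effects$beta_s
  g <- rowSums(parts)
  list(phenotype = g + rnorm(n, 0, sqrt(env_var)), genetic = g,
       parts = parts)
}

#' Forward-in-time family simulation
#'
#' Iterates mate pairing, meiosis and phenotype construction over discrete
#' generations. Each generation pairs the previous generation's females and
#' males ([assort_mates]) and every pair produces two offspring (one female,
#' one male, keeping sex counts equal), so population size is constant.
#' Sibling links are the two offspring of a pair. Founder phenotypes carry
#' no indirect parental or sibling terms (their parents are outside the
#' panel).
#'
#' Assortment can either use a fixed `rho_y`, or be calibrated: with
#' `calibrate_rho_g` set, the pairing is re-drawn within each generation,
#' adjusting the working phenotypic correlation until the realized
#' correlation of the mates' causal-locus genetic values hits the target
#' (the per-locus mate genotype correlation is not a usable dial for a
#' polygenic trait — it is of order target/l — so calibration acts on the
#' genetic score).
#'
#' @param panel A [founder_panel] (or panel from [read_founder_vcf]).
#' @param scenario An [effect_scenario].
#' @param generations Number of offspring generations (>= 1).
#' @param rho_y Target mate phenotypic correlation (ignored when
#'   `calibrate_rho_g` is given).
#' @param recomb_rate Per-interval crossover probability.
#' @param calibrate_rho_g Optional target for the realized correlation of
#'   mates' causal genetic values.
#' @param effects Optional pre-drawn [locus_params] from [sample_effects];
#'   drawn internally when NULL.
#' @param keep `"all"` retains every generation's haplotype matrices;
#'   `"last2"` drops genotypes of older generations as the simulation
#'   advances (pedigree, sex and phenotypes are always kept), which keeps
#'   long runs with many loci at desk-scale memory.
#' @param seed Optional integer seed governing the whole run.
#' @return An object of class `fam_sim`: list with `gen` (per-generation
#'   populations: `mat`, `pat`, `sex` (1 female, 2 male), `phen`,
#'   `genetic`, `mother`, `father`, `sib` index vectors), `effects`,
#'   `scenario`, `panel_freq`, `causal`, `log` (per-generation realized
#'   assortment and variance summaries) and the call parameters.
#' @examples
#' p <- founder_panel(200, 50, seed = 1)
#' s <- run_generations(p, effect_scenario("V1", n_causal = 50),
#'                      generations = 2, seed = 1)
#' s$log
#' @export
run_generations <- function(panel, scenario, generations = 10, rho_y = 0,
                            recomb_rate = 0.5, calibrate_rho_g = NULL,
                            effects = NULL, keep = c("all", "last2"),
                            seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(scenario, "effect_scenario"), generations >= 1)
  keep <- match.arg(keep)
  if (!is.null(seed)) set.seed(seed)
  n <- panel$n
  if (n %% 2L != 0L) stop("population size must be even")
  if (is.null(effects)) effects <- sample_effects(scenario, panel)
  causal <- attr(effects, "loci")
  L <- ncol(panel$hap)
  ev <- scenario$env_var

  founders <- list(
    mat = panel$hap[seq(1, 2 * n, by = 2), , drop = FALSE],
    pat = panel$hap[seq(2, 2 * n, by = 2), , drop = FALSE],
    sex = rep(c(1L, 2L), length.out = n),
    mother = rep(NA_integer_, n), father = rep(NA_integer_, n),
    sib = rep(NA_integer_, n))
  ph <- compute_phenotypes(founders$mat[, causal, drop = FALSE],
                           founders$pat[, causal, drop = FALSE],
                           effects, env_var = ev,
                           sib_geno = if (any(effects$beta_s != 0))
                             matrix(0L, n, length(causal)))
  founders$phen <- ph$phenotype
  founders$genetic <- ph$genetic
  gen <- vector("list", generations + 1)
  gen[[1]] <- founders

  logrows <- vector("list", generations)
  work_rho_y <- if (is.null(calibrate_rho_g)) rho_y else
    min(0.95, 2 * calibrate_rho_g)

  for (g in seq_len(generations)) {
    prev <- gen[[g]]
    fem <- which(prev$sex == 1L)
    mal <- which(prev$sex == 2L)
    gscore <- function(idx) prev$genetic[idx]
    pair_once <- function(ry) {
      pr <- assort_mates(prev$phen[fem], prev$phen[mal], ry)
      cbind(mother = fem[pr[, 1]], father = mal[pr[, 2]])
    }
    pairs <- pair_once(work_rho_y)
    if (!is.null(calibrate_rho_g)) {
      for (it in 1:6) {
        r_g <- cor(gscore(pairs[, 1]), gscore(pairs[, 2]))
        if (abs(r_g - calibrate_rho_g) < 0.005) break
        work_rho_y <- min(1, max(0, work_rho_y *
                                   calibrate_rho_g / max(r_g, 1e-6)))
        pairs <- pair_once(work_rho_y)
      }
    }
    np <- nrow(pairs)
    mo <- pairs[, 1]; fa <- pairs[, 2]
    r_y <- cor(prev$phen[mo], prev$phen[fa])
    r_g <- cor(prev$genetic[mo], prev$genetic[fa])
    xm <- prev$mat[mo, causal, drop = FALSE] +
      prev$pat[mo, causal, drop = FALSE]
    xf <- prev$mat[fa, causal, drop = FALSE] +
      prev$pat[fa, causal, drop = FALSE]
    rho_bar <- mean(suppressWarnings(
      vapply(seq_along(causal),
             function(j) cor(xm[, j], xf[, j]), 0)), na.rm = TRUE)

    # two offspring per pair: child 1 female, child 2 male
    mo2 <- rep(mo, 2); fa2 <- rep(fa, 2)
    cm <- meiosis(prev$mat[mo2, , drop = FALSE],
                  prev$pat[mo2, , drop = FALSE], recomb_rate)
    cp <- meiosis(prev$mat[fa2, , drop = FALSE],
                  prev$pat[fa2, , drop = FALSE], recomb_rate)
    sib <- c(np + seq_len(np), seq_len(np))
    xs <- (cm[, causal, drop = FALSE] + cp[, causal, drop = FALSE])[sib, ,
                                                                    drop = FALSE]
    ph <- compute_phenotypes(
      cm[, causal, drop = FALSE], cp[, causal, drop = FALSE], effects,
      mother_geno = xm[rep(seq_len(np), 2), , drop = FALSE],
      father_geno = xf[rep(seq_len(np), 2), , drop = FALSE],
      sib_geno = xs, env_var = ev)
    kid <- list(mat = cm, pat = cp,
                sex = rep(c(1L, 2L), each = np),
                mother = mo2, father = fa2, sib = sib,
                phen = ph$phenotype, genetic = ph$genetic)
    gen[[g + 1]] <- kid
    if (keep == "last2" && g >= 2)
      gen[[g - 1]][c("mat", "pat")] <- NULL

    dsib <- ph$genetic[seq_len(np)] - ph$genetic[np + seq_len(np)]
    het <- mean((cm[, causal, drop = FALSE] +
                   cp[, causal, drop = FALSE]) == 1L)
    logrows[[g]] <- data.frame(
      generation = g, rho_y_target = work_rho_y, rho_y_realized = r_y,
      rho_g_realized = r_g, rho_bar = rho_bar,
      var_genetic = var(ph$genetic), var_phenotype = var(ph$phenotype),
      var_sibdiff_genetic = var(dsib), het_causal = het)
  }

  structure(list(gen = gen, effects = effects, scenario = scenario,
                 panel_freq = panel$freq, causal = causal,
                 generations = generations, n = n,
                 rho_y = rho_y, recomb_rate = recomb_rate,
                 calibrate_rho_g = calibrate_rho_g,
                 log = do.call(rbind, logrows)),
            class = "fam_sim")
}

#' @export
print.fam_sim <- function(x, ...) {
  cat("<fam_sim> ", x$scenario$id, ": ", x$n, " individuals x ",
      x$generations, " generations, ", length(x$causal),
      " causal loci\n", sep = "")
  lg <- x$log[nrow(x$log), ]
  cat(sprintf(
    "  final generation: Vg = %.3f, Vp = %.3f, mate rho_y = %.3f, rho_g = %.3f\n",
    lg$var_genetic, lg$var_phenotype, lg$rho_y_realized, lg$rho_g_realized))
  invisible(x)
}

#' @export
summary.fam_sim <- function(object, ...) {
  cat("Forward family simulation, scenario ", object$scenario$id, "\n",
      sep = "")
  print(object$log, digits = 3, row.names = FALSE)
  invisible(object$log)
}

#' Pedigree table of a simulation
#'
#' Assembles the id / father / mother / sex / generation / phenotype table
#' across all generations, with globally unique ids and parent ids
#' resolvable within the previous generation (NA for founders).
#'
#' @param sim A `fam_sim` object.
#' @return A data frame with columns `id`, `father`, `mother`, `sex`
#'   ("F"/"M"), `generation` (0 = founders), `phenotype`.
#' @export
pedigree <- function(sim) {
  stopifnot(inherits(sim, "fam_sim"))
  offs <- cumsum(c(0, vapply(sim$gen, function(g) length(g$phen), 0)))
  out <- lapply(seq_along(sim$gen), function(gi) {
    g <- sim$gen[[gi]]
    data.frame(
      id = offs[gi] + seq_along(g$phen),
      father = if (gi == 1) NA_integer_ else offs[gi - 1] + g$father,
      mother = if (gi == 1) NA_integer_ else offs[gi - 1] + g$mother,
      sex = c("F", "M")[g$sex],
      generation = gi - 1L,
      phenotype = g$phen)
  })
  do.call(rbind, out)
}
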