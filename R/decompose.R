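#' Variance decomposition of simulated genetic values
#'
#' Splits the realized genetic variance of one simulated generation into the
#' per-class components (direct, maternal, paternal, imprinting, sibling)
#' and all pairwise covariances between the class-specific genotypic value
#' vectors (`Xc*beta_c`, `Xm*beta_m`, `Xf*beta_f`, `Xi*beta_i`,
#' `Xs*beta_s`), using the true simulated effects. In the sibling-difference
#' design the vectors are the within-pair differences (one entry per family),
#' where the maternal and paternal vectors vanish identically and the
#' direct-sibling covariance enters with negative sign whenever direct and
#' sibling effects are positively coupled. Components plus twice the
#' covariances reconstruct the total exactly.
#'
#' @param sim A `fam_sim` from [run_generations].
#' @param generation Generation index (1-based offspring generation;
#'   defaults to the last). Founders (0) have no parental links and are not
#'   decomposable in the trio design.
#' @param design `"trio"` or `"sibdiff"`.
#' @return An object of class `variance_decomposition`: list with
#'   `components` (named variances), `covariances` (named, unordered
#'   pairs), `total` (variance of the summed value) and `design`.
#' @export
decompose_variance <- function(sim, generation = NULL,
                               design = c("trio", "sibdiff")) {
  stopifnot(inherits(sim, "fam_sim"))
  design <- match.arg(design)
  if (is.null(generation)) generation <- sim$generations
  stopifnot(generation >= 1, generation <= sim$generations)
  vals <- class_values(sim, generation)
  if (design == "sibdiff") {
    g <- sim$gen[[generation + 1]]
    np <- length(g$phen) / 2
    first <- seq_len(np)
    vals <- vals[first, , drop = FALSE] -
      vals[g$sib[first], , drop = FALSE]
  }
  cv <- cov(vals)
  comps <- diag(cv)
  pairs <- which(upper.tri(cv), arr.ind = TRUE)
  covs <- cv[pairs]
  names(covs) <- paste(colnames(cv)[pairs[, 1]],
                       colnames(cv)[pairs[, 2]], sep = "-")
  structure(list(components = comps, covariances = covs,
                 total = var(rowSums(vals)), design = design,
                 generation = generation),
            class = "variance_decomposition")
}

# n x 5 matrix of per-class genetic value sums for one offspring generation
class_values <- function(sim, generation) {
  g <- sim$gen[[generation + 1]]
  prev <- sim$gen[[generation]]
  ca <- sim$causal
  e <- sim$effects
  xm <- prev$mat[g$mother, ca, drop = FALSE] +
    prev$pat[g$mother, ca, drop = FALSE]
  xf <- prev$mat[g$father, ca, drop = FALSE] +
    prev$pat[g$father, ca, drop = FALSE]
  xc <- g$mat[, ca, drop = FALSE] + g$pat[, ca, drop = FALSE]
  xi <- g$mat[, ca, drop = FALSE] - g$pat[, ca, drop = FALSE]
  xs <- xc[g$sib, , drop = FALSE]
  cbind(direct = drop(xc %*% e$beta_c),
        maternal = drop(xm %*% e$beta_m),
        paternal = drop(xf %*% e$beta_f),
        imprinting = drop(xi %*% e$beta_i),
        sibling = drop(xs %*% e$beta_s))
}

# per-locus (families x l) matrices of summed class values, for k_ij
per_locus_values <- function(sim, generation, design) {
  g <- sim$gen[[generation + 1]]
  prev <- sim$gen[[generation]]
  ca <- sim$causal
  e <- sim$effects
  xm <- prev$mat[g$mother, ca, drop = FALSE] +
    prev$pat[g$mother, ca, drop = FALSE]
  xf <- prev$mat[g$father, ca, drop = FALSE] +
    prev$pat[g$father, ca, drop = FALSE]
  xc <- g$mat[, ca, drop = FALSE] + g$pat[, ca, drop = FALSE]
  xi <- g$mat[, ca, drop = FALSE] - g$pat[, ca, drop = FALSE]
  xs <- xc[g$sib, , drop = FALSE]
  scale_cols <- function(m, b) m * rep(b, each = nrow(m))
  v <- scale_cols(xc, e$beta_c) + scale_cols(xm, e$beta_m) +
    scale_cols(xf, e$beta_f) + scale_cols(xi, e$beta_i) +
    scale_cols(xs, e$beta_s)
  if (design == "sibdiff") {
    np <- length(g$phen) / 2
    first <- seq_len(np)
    v <- v[first, , drop = FALSE] - v[g$sib[first], , drop = FALSE]
  }
  v
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition> ", x$design, " design, generation ",
      x$generation, "\n", sep = "")
  act <- x$components[x$components > 1e-12]
  cat("  components: ",
      paste(names(act), signif(act, 4), sep = "=", collapse = ", "), "\n",
      sep = "")
  cc <- x$covariances[abs(x$covariances) > 1e-12]
  if (length(cc))
    cat("  covariances:", paste(names(cc), signif(cc, 4), sep = "=",
                                collapse = ", "), "\n")
  cat("  total:", signif(x$total, 5), "\n")
  invisible(x)
}

#' Theoretical total variance for a simulated generation
#'
#' Plugs realized quantities from the simulation — parental allele
#' frequencies, the drawn effect sizes, the realized per-locus mate genotype
#' correlation rho-bar, and inter-locus correlations k_ij — into the
#' single-locus closed forms and combines them with the multilocus cross
#' term `sum_{i != j} k_ij sqrt(V_i V_j)`. Per-locus variances come from the
#' assortative-mating forms evaluated at each locus's realized rho-bar
#' (which reduce to the random-mating forms when mates are uncorrelated);
#' `k_ij` is estimated as the correlation between the per-locus genotypic
#' values of the predicted generation (sibling-difference values in the
#' sibdiff design), which keeps the sign of cross-locus covariance correct
#' when effect sizes differ in sign across loci.
#'
#' @inheritParams decompose_variance
#' @return A list with `expected` (total), `per_locus` (theory variances),
#'   `rho_bar` (per-locus realized mate genotype correlations) and
#'   `cross` (the summed inter-locus term).
#' @export
expected_total <- function(sim, generation = NULL,
                           design = c("trio", "sibdiff")) {
  stopifnot(inherits(sim, "fam_sim"))
  design <- match.arg(design)
  if (is.null(generation)) generation <- sim$generations
  g <- sim$gen[[generation + 1]]
  prev <- sim$gen[[generation]]
  ca <- sim$causal
  e <- sim$effects

  fam <- !duplicated(paste(g$mother, g$father))
  mo <- g$mother[fam]; fa <- g$father[fam]
  xm <- prev$mat[mo, ca, drop = FALSE] + prev$pat[mo, ca, drop = FALSE]
  xf <- prev$mat[fa, ca, drop = FALSE] + prev$pat[fa, ca, drop = FALSE]
  q <- (colMeans(xm) + colMeans(xf)) / 4
  rho_bar <- vapply(seq_along(ca), function(j) {
    r <- suppressWarnings(cor(xm[, j], xf[, j]))
    if (is.na(r)) 0 else r
  }, 0)
  rho_bar_cl <- pmin(1, pmax(0, rho_bar))

  loc <- e
  loc$q2 <- pmin(1 - 1e-6, pmax(1e-6, q))
  loc$q1 <- 1 - loc$q2
  vj <- vapply(seq_len(nrow(loc)), function(j) {
    lj <- locus_params(loc$q2[j], loc$beta_c[j], loc$beta_m[j],
                       loc$beta_f[j], loc$beta_i[j], loc$beta_s[j])
    if (design == "trio") var_am(lj, rho_bar_cl[j])
    else var_sibdiff_am(lj, rho_bar_cl[j])
  }, 0)

  pl <- per_locus_values(sim, generation, design)
  keep <- apply(pl, 2, sd) > 0
  kmat <- matrix(0, length(vj), length(vj))
  if (sum(keep) > 1) kmat[keep, keep] <- cor(pl[, keep, drop = FALSE])
  diag(kmat) <- 0
  s <- sqrt(pmax(vj, 0))
  cross <- sum(kmat * (s %o% s))
  list(expected = sum(vj) + cross, per_locus = vj,
       rho_bar = rho_bar, cross = cross)
}

#' Replicated theory-vs-simulation variance comparison
#'
#' Runs the forward simulator across effect scenarios, mating regimes and
#' family designs, decomposing each replicate's realized genetic variance
#' and computing the corresponding theoretical expectation from realized
#' allele frequencies, mate correlations and inter-locus correlations.
#' Regimes share seeds, so "rm" and "am" replicates with the same index are
#' matched.
#'
#' @param scenarios Character vector of scenario ids (see
#'   [effect_scenario]).
#' @param regimes Subset of `c("rm", "am")`; "am" uses `rho_y`.
#' @param designs Subset of `c("trio", "sibdiff")`.
#' @param n_reps Replicates per cell.
#' @param n Individuals per generation.
#' @param n_loci Panel (= causal) loci.
#' @param generations Offspring generations.
#' @param rho_y Mate phenotypic correlation for the "am" regime.
#' @param sibling_var Sibling-effect variance used in sibdiff-design runs
#'   (trio runs keep it 0: the trio closed forms deliberately exclude
#'   sibling effects, which belong to the sibling-difference design).
#' @param seed Integer seed; replicate r of either regime uses `seed + r`,
#'   so "rm" and "am" cells are matched.
#' @return A data frame of class `variance_experiment` with one row per
#'   (scenario, regime, design, replicate): `estimated`, `expected`, and
#'   the realized `rho_g`.
#' @export
variance_experiment <- function(scenarios = c("V1", "V2", "V3", "V4", "V5"),
                                regimes = c("rm", "am"),
                                designs = c("trio", "sibdiff"),
                                n_reps = 10, n = 4000, n_loci = 200,
                                generations = 10, rho_y = 0.2,
                                sibling_var = 0.1, seed = 1) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  designs <- match.arg(designs, several.ok = TRUE)
  rows <- list()
  for (sc in scenarios) {
    for (d in designs) {
      scen <- effect_scenario(
        sc, sibling_var = if (d == "sibdiff") sibling_var else 0,
        n_causal = n_loci)
      for (r in seq_len(n_reps)) {
        for (reg in regimes) {
          set.seed(seed + r)
          panel <- founder_panel(n, n_loci, ld_decay = 0.2)
          sim <- run_generations(panel, scen, generations = generations,
                                 rho_y = if (reg == "am") rho_y else 0)
          est <- decompose_variance(sim, design = d)
          ex <- expected_total(sim, design = d)
          rows[[length(rows) + 1]] <- data.frame(
            scenario = sc, regime = reg, design = d, replicate = r,
            estimated = est$total, expected = ex$expected,
            rho_g = sim$log$rho_g_realized[generations])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("variance_experiment", "data.frame")
  out
}

#' @export
print.variance_experiment <- function(x, ...) {
  agg <- aggregate(cbind(estimated, expected) ~ scenario + regime + design,
                   data = x, FUN = mean)
  sds <- aggregate(estimated ~ scenario + regime + design, data = x,
                   FUN = sd)
  agg$sd_estimated <- sds$estimated
  cat("<variance_experiment> replicate means\n")
  print(agg, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-locus joint effect regression (diagnostic)
#'
#' Fits, locus by locus, the regression of the child phenotype on the
#' child dosage, mother dosage, father dosage and imprinting code jointly.
#' This is a diagnostic only: marginal per-locus estimates from family data
#' are confounded across classes and loci and are not causally
#' interpretable; the package's variance comparisons use the true simulated
#' effects instead.
#'
#' @param sim A `fam_sim`.
#' @param generation Offspring generation (default last).
#' @param loci Indices into the causal set (default first 10).
#' @return A data frame with per-locus estimated and true effects.
#' @export
fit_trio_effects <- function(sim, generation = NULL, loci = NULL) {
  stopifnot(inherits(sim, "fam_sim"))
  if (is.null(generation)) generation <- sim$generations
  if (is.null(loci)) loci <- seq_len(min(10, length(sim$causal)))
  g <- sim$gen[[generation + 1]]
  prev <- sim$gen[[generation]]
  ca <- sim$causal
  e <- sim$effects
  y <- g$phen
  out <- lapply(loci, function(j) {
    cj <- ca[j]
    xc <- g$mat[, cj] + g$pat[, cj]
    xi <- g$mat[, cj] - g$pat[, cj]
    xm <- prev$mat[g$mother, cj] + prev$pat[g$mother, cj]
    xf <- prev$mat[g$father, cj] + prev$pat[g$father, cj]
    fit <- coef(lm(y ~ xc + xm + xf + xi))
    data.frame(locus = j,
               est_c = fit[["xc"]], true_c = e$beta_c[j],
               est_m = fit[["xm"]], true_m = e$beta_m[j],
               est_f = fit[["xf"]], true_f = e$beta_f[j],
               est_i = fit[["xi"]], true_i = e$beta_i[j])
  })
  do.call(rbind, out)
}
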