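#' Effect-class scenarios for the simulator
#'
#' Defines which genetic effect classes act on the trait, their target
#' population-level variance contributions (trait-variance units, via the
#' genic sum `sum_j 2 q_j (1-q_j) beta_j^2` over causal loci) and the
#' correlation structure of effect sizes across classes within a locus.
#' The named presets follow the standard scenario ladder:
#' \describe{
#'   \item{V1}{direct effects only;}
#'   \item{V2}{direct + imprinting (uncorrelated);}
#'   \item{V3}{direct + maternal + paternal;}
#'   \item{V4}{direct + maternal + paternal + imprinting;}
#'   \item{V5}{as V4 with cross-class effect correlations;}
#'   \item{V6}{direct correlated with maternal and paternal.}
#' }
#' Default component variances: direct 0.5 (the SNP heritability when no
#' other class is active and the environmental variance is 0.5), maternal
#' and paternal 0.125 each, imprinting 0.1, sibling 0 (set `sibling_var`
#' to add indirect sibling effects, e.g. for sibling-difference studies;
#' a direct-sibling effect correlation of 0.3 is then applied by default).
#'
#' @param id One of "V1".."V6" or "custom".
#' @param direct_var,maternal_var,paternal_var,imprint_var,sibling_var
#'   Target variance contributions per class; `NULL` takes the preset.
#' @param effect_cor Optional 5x5 correlation matrix over
#'   (direct, maternal, paternal, imprinting, sibling) effect draws;
#'   must be positive semidefinite. `NULL` takes the preset.
#' @param env_var Environmental variance of the trait (default 0.5).
#' @param n_causal Number of causal loci drawn by [sample_effects]
#'   (default 200).
#' @return An object of class `effect_scenario`.
#' @examples
#' effect_scenario("V3")
#' @export
effect_scenario <- function(id = c("V1", "V2", "V3", "V4", "V5", "V6",
                                   "custom"),
                            direct_var = NULL, maternal_var = NULL,
                            paternal_var = NULL, imprint_var = NULL,
                            sibling_var = NULL, effect_cor = NULL,
                            env_var = 0.5, n_causal = 200) {
  id <- match.arg(id)
  preset_var <- list(
    V1 = c(0.5, 0,     0,     0,   0),
    V2 = c(0.5, 0,     0,     0.1, 0),
    V3 = c(0.5, 0.125, 0.125, 0,   0),
    V4 = c(0.5, 0.125, 0.125, 0.1, 0),
    V5 = c(0.5, 0.125, 0.125, 0.1, 0),
    V6 = c(0.5, 0.125, 0.125, 0,   0),
    custom = c(0.5, 0, 0, 0, 0))
  v <- preset_var[[id]]
  names(v) <- c("direct", "maternal", "paternal", "imprinting", "sibling")
  if (!is.null(direct_var))   v["direct"]     <- direct_var
  if (!is.null(maternal_var)) v["maternal"]   <- maternal_var
  if (!is.null(paternal_var)) v["paternal"]   <- paternal_var
  if (!is.null(imprint_var))  v["imprinting"] <- imprint_var
  if (!is.null(sibling_var))  v["sibling"]    <- sibling_var
  if (any(v < 0)) stop("target variances must be >= 0")
  if (is.null(effect_cor)) {
    r <- diag(5)
    if (id == "V5") {
      r[1, 2] <- r[2, 1] <- 0.3   # direct-maternal
      r[1, 3] <- r[3, 1] <- 0.3   # direct-paternal
      r[2, 3] <- r[3, 2] <- 0.3   # maternal-paternal
      r[2, 4] <- r[4, 2] <- 0.2   # maternal-imprinting
      r[3, 4] <- r[4, 3] <- -0.2  # paternal-imprinting
    }
    if (id == "V6") {
      r[1, 2] <- r[2, 1] <- 0.5
      r[1, 3] <- r[3, 1] <- 0.5
      r[2, 3] <- r[3, 2] <- 0.25
    }
    if (v["sibling"] > 0) r[1, 5] <- r[5, 1] <- 0.3
    effect_cor <- r
  }
  effect_cor <- as.matrix(effect_cor)
  stopifnot(all(dim(effect_cor) == 5),
            max(abs(effect_cor - t(effect_cor))) < 1e-10)
  if (min(eigen(effect_cor, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("`effect_cor` must be positive semidefinite")
  stopifnot(env_var >= 0, n_causal >= 1)
  dimnames(effect_cor) <- list(names(v), names(v))
  structure(list(id = id, target_var = v, effect_cor = effect_cor,
                 env_var = env_var, n_causal = as.integer(n_causal)),
            class = "effect_scenario")
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat("<effect_scenario> ", x$id, "\n  target variances: ",
      paste(names(x$target_var), signif(x$target_var, 3), sep = "=",
            collapse = ", "),
      "\n  environmental variance: ", x$env_var,
      "; causal loci: ", x$n_causal, "\n", sep = "")
  off <- x$effect_cor[upper.tri(x$effect_cor)]
  if (any(off != 0)) cat("  correlated effect classes\n")
  invisible(x)
}

#' Draw per-locus effect sizes for a scenario
#'
#' Selects `n_causal` loci from the panel and draws the five effect classes
#' jointly from a multivariate normal with the scenario's cross-class
#' correlation matrix. Each locus's raw draw is scaled by
#' `1/sqrt(2 q_j (1-q_j))` (equal expected contribution per locus), then
#' each active class is rescaled so its genic variance on the panel's
#' realized allele frequencies, `sum_j 2 q_j (1-q_j) beta_j^2`, equals the
#' scenario target exactly. Inactive classes are exactly zero.
#'
#' @param scenario An [effect_scenario].
#' @param panel A [founder_panel] (realized allele frequencies are used).
#' @param seed Optional integer seed.
#' @return A [locus_params] with one row per causal locus and attributes
#'   `loci` (panel column indices) and `scenario`.
#' @export
sample_effects <- function(scenario, panel, seed = NULL) {
  stopifnot(inherits(scenario, "effect_scenario"),
            inherits(panel, "haplotype_panel"))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(panel$hap)
  nc <- scenario$n_causal
  if (nc > L) stop("n_causal exceeds the number of panel loci")
  loci <- if (nc == L) seq_len(L) else sort(sample.int(L, nc))
  q <- panel$freq[loci]
  r <- scenario$effect_cor
  ev <- eigen(r, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  z <- matrix(rnorm(nc * 5), nc, 5) %*% rt
  w <- 1 / sqrt(2 * q * (1 - q))
  beta <- z * w
  for (cl in 1:5) {
    tv <- scenario$target_var[cl]
    if (tv == 0) { beta[, cl] <- 0; next }
    genic <- sum(2 * q * (1 - q) * beta[, cl]^2)
    beta[, cl] <- beta[, cl] * sqrt(tv / genic)
  }
  out <- locus_params(q2 = q, beta_c = beta[, 1], beta_m = beta[, 2],
                      beta_f = beta[, 3], beta_i = beta[, 4],
                      beta_s = beta[, 5])
  attr(out, "loci") <- loci
  attr(out, "scenario") <- scenario
  out
}
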