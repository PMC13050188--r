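#' Population mean of the child phenotype under random mating
#'
#' Single-locus mean of the genotypic value contributed by direct, indirect
#' maternal and indirect paternal effects, `2 q2 (beta_c + beta_m + beta_f)`.
#' Parent-of-origin effects average to zero over reciprocal heterozygotes and
#' do not move the mean; sibling effects are likewise absent.
#'
#' @param locus A [locus_params] object (possibly many loci; vectorized).
#' @return Numeric vector of per-locus means.
#' @examples
#' mean_rm(locus_params(0.5, beta_c = 1, beta_m = 1, beta_f = 1, beta_i = 7))
#' @export
mean_rm <- function(locus) {
  locus <- as_locus_params(locus)
  2 * locus$q2 * (locus$beta_c + locus$beta_m + locus$beta_f)
}

#' Single-locus genetic variance under random mating
#'
#' The trio-design variance contributed by one locus when direct, indirect
#' maternal/paternal and parent-of-origin effects act jointly:
#' `2 q1 q2 (bc^2 + bm^2 + bf^2 + bi^2 + bc*bm + bc*bf + bm*bi - bf*bi)`.
#' The negative sign on `bf*bi` follows from the imprinting coding (positive
#' for a maternally inherited A2, negative for a paternally inherited one).
#' Sibling effects do not enter the trio variance.
#'
#' @inheritParams mean_rm
#' @return Numeric vector of per-locus variances.
#' @export
var_rm <- function(locus) {
  locus <- as_locus_params(locus)
  with(locus, 2 * q1 * q2 *
         (beta_c^2 + beta_m^2 + beta_f^2 + beta_i^2 +
            beta_c * beta_m + beta_c * beta_f +
            beta_m * beta_i - beta_f * beta_i))
}

#' Single-locus variance of the sibling difference under random mating
#'
#' Variance of `Yc - Ys` between two full siblings,
#' `2 q1 q2 (bc^2 + bi^2 + bs^2 - 2 bc*bs)`. Indirect parental effects are
#' shared by both siblings and cancel; direct and indirect sibling effects
#' always oppose each other in the difference, hence the negative covariance
#' term.
#'
#' @inheritParams mean_rm
#' @return Numeric vector of per-locus sibling-difference variances.
#' @export
var_sibdiff_rm <- function(locus) {
  locus <- as_locus_params(locus)
  with(locus, 2 * q1 * q2 *
         (beta_c^2 + beta_i^2 + beta_s^2 - 2 * beta_c * beta_s))
}

#' Single-locus genetic variance under assortative mating
#'
#' Trio-design variance at mate allele correlation `rho`, a quadratic
#' polynomial in `rho` whose rho^0 term is [var_rm]:
#' \deqn{V_{AM} = 2q_1q_2(\beta_c^2+\beta_i^2+\beta_m^2+\beta_f^2+
#'   \beta_c\beta_m+\beta_c\beta_f+\beta_m\beta_i-\beta_f\beta_i)
#'   + q_1q_2\rho(\beta_c^2+2\beta_m^2+2\beta_f^2-\beta_i^2
#'   +4\beta_c\beta_m+4\beta_c\beta_f+4\beta_m\beta_f)
#'   + q_1q_2\rho^2(\beta_c^2-\beta_i^2+2\beta_c\beta_m+2\beta_c\beta_f
#'   -2\beta_m\beta_i+2\beta_f\beta_i+4\beta_m\beta_f).}
#' Equals the exact enumeration over the assortative-mating offspring
#' frequencies (see [am_frequency]).
#'
#' @inheritParams mean_rm
#' @param rho Mate allele correlation in \[0, 1\] (scalar), or an
#'   [assortment_params] object.
#' @return Numeric vector of per-locus variances.
#' @export
var_am <- function(locus, rho = 0) {
  if (inherits(rho, "assortment_params")) rho <- rho$rho
  check_rho(rho)
  locus <- as_locus_params(locus)
  var_rm(locus) + with(locus, {
    q12 <- q1 * q2
    q12 * rho * (beta_c^2 + 2 * beta_m^2 + 2 * beta_f^2 - beta_i^2 +
                     4 * beta_c * beta_m + 4 * beta_c * beta_f +
                     4 * beta_m * beta_f) +
      q12 * rho^2 * (beta_c^2 - beta_i^2 +
                       2 * beta_c * beta_m + 2 * beta_c * beta_f -
                       2 * beta_m * beta_i + 2 * beta_f * beta_i +
                       4 * beta_m * beta_f)
  })
}

#' Sibling-difference variance under assortative mating
#'
#' `(1 - rho)` times the random-mating sibling-difference variance:
#' assortment shrinks within-family segregation variance through the
#' increased homozygosity of parents.
#'
#' @inheritParams var_am
#' @return Numeric vector of per-locus sibling-difference variances.
#' @export
var_sibdiff_am <- function(locus, rho = 0) {
  if (inherits(rho, "assortment_params")) rho <- rho$rho
  check_rho(rho)
  (1 - rho) * var_sibdiff_rm(locus)
}

#' Total multilocus genetic variance with inter-locus correlations
#'
#' Combines per-locus variances `V_j` (dispatched per `regime` to [var_rm],
#' [var_am], [var_sibdiff_rm] or [var_sibdiff_am]) with inter-locus genotype
#' correlations `k_ij`:
#' \deqn{V_{tot} = \sum_j V_j + \sum_{i \neq j} k_{ij} \sqrt{V_i V_j},}
#' the off-diagonal sum running over ordered pairs (equivalently twice the
#' sum over unordered pairs).
#'
#' @inheritParams var_am
#' @param k_matrix Symmetric l x l matrix of inter-locus genotype
#'   correlations; the diagonal is ignored. `NULL` means independent loci.
#' @param regime One of `"rm"`, `"am"`, `"sibdiff-rm"`, `"sibdiff-am"`.
#' @return Total variance (length-1 numeric).
#' @export
var_total <- function(locus, k_matrix = NULL,
                      regime = c("rm", "am", "sibdiff-rm", "sibdiff-am"),
                      rho = 0) {
  regime <- match.arg(regime)
  locus <- as_locus_params(locus)
  v <- switch(regime,
              "rm"         = var_rm(locus),
              "am"         = var_am(locus, rho),
              "sibdiff-rm" = var_sibdiff_rm(locus),
              "sibdiff-am" = var_sibdiff_am(locus, rho))
  if (any(v < 0))
    stop("negative per-locus variance under regime '", regime,
         "'; sqrt(Vi*Vj) in the cross term requires nonnegative variances")
  l <- length(v)
  if (is.null(k_matrix)) return(sum(v))
  k_matrix <- as.matrix(k_matrix)
  stopifnot(nrow(k_matrix) == l, ncol(k_matrix) == l)
  if (max(abs(k_matrix - t(k_matrix))) > 1e-8)
    stop("k_matrix must be symmetric")
  if (max(abs(k_matrix)) > 1 + 1e-8) stop("|k_ij| must be <= 1")
  s <- sqrt(v)
  cross <- s %o% s * k_matrix
  diag(cross) <- 0
  sum(v) + sum(cross)
}

#' Variance of single maternally and paternally inherited alleles
#'
#' At the allele level (parent-of-origin effects set aside), a maternally
#' inherited allele carries effect `beta_c + beta_m` with frequency `q2`
#' and 0 with frequency `q1`, giving variance `q1 q2 (beta_c + beta_m)^2`;
#' symmetrically `q1 q2 (beta_c + beta_f)^2` for the paternal allele.
#'
#' @inheritParams mean_rm
#' @return A two-column matrix with columns `maternal` and `paternal`.
#' @export
allele_variances <- function(locus) {
  locus <- as_locus_params(locus)
  cbind(maternal = with(locus, q1 * q2 * (beta_c + beta_m)^2),
        paternal = with(locus, q1 * q2 * (beta_c + beta_f)^2))
}

#' Allele-level multilocus variance with assortment-induced correlations
#'
#' The equal-frequency, equal-effect multilocus model at the level of single
#' alleles: `l` loci each with maternal-allele variance
#' `q1 q2 (beta_c+beta_m)^2` and paternal-allele variance
#' `q1 q2 (beta_c+beta_f)^2`, plus the three classes of covariance induced
#' by assortative mating between child alleles:
#' \itemize{
#'   \item same-locus maternal-paternal pairs (`l` pairs, correlation `f`):
#'     `l f q1 q2 (beta_c+beta_m)(beta_c+beta_f)`;
#'   \item different loci within one gamete (`l(l-1)/2` pairs per gamete,
#'     correlation `k`): `l(l-1)/2 k q1 q2 (beta_c+beta_m)^2` for the
#'     maternal gamete and the `beta_f` analogue for the paternal one;
#'   \item maternal-paternal pairs at different loci (`l(l-1)` pairs,
#'     correlation `s`): `l(l-1) s q1 q2 (beta_c+beta_m)(beta_c+beta_f)`.
#' }
#' Each term is the total over unordered allele pairs of its class; in the
#' variance of the summed genetic value every unordered pair contributes
#' twice, so `v_x = v_base + 2 (f_term + k_term + s_term)`.
#'
#' @param locus A single-locus [locus_params] (the model assumes all loci
#'   share this frequency and these effects). Imprinting and sibling effects
#'   are ignored at the allele level.
#' @param assort An [assortment_params] carrying `f`, `k`, `s`.
#' @param n_loci Number of loci `l` (>= 1).
#' @return A list with `v_base` (the no-correlation variance
#'   `2 l q1 q2 (bc^2 + bm^2/2 + bf^2/2 + bc*bm + bc*bf)`), the three
#'   covariance terms `f_term`, `k_term` (with `k_maternal`/`k_paternal`
#'   parts), `s_term`, `cov_total = f_term + k_term + s_term` and
#'   `v_x = v_base + 2 * cov_total`.
#' @export
am_multilocus_covariance <- function(locus, assort, n_loci) {
  locus <- as_locus_params(locus)
  stopifnot(nrow(locus) == 1, inherits(assort, "assortment_params"))
  if (!is.numeric(n_loci) || length(n_loci) != 1 || n_loci < 1 ||
      n_loci != round(n_loci))
    stop("`n_loci` must be a positive integer")
  l <- n_loci
  q12 <- locus$q1 * locus$q2
  em <- locus$beta_c + locus$beta_m
  ef <- locus$beta_c + locus$beta_f
  v_base <- with(locus, 2 * l * q12 *
                   (beta_c^2 + beta_m^2 / 2 + beta_f^2 / 2 +
                      beta_c * beta_m + beta_c * beta_f))
  f_term <- l * assort$f * q12 * em * ef
  k_m <- l * (l - 1) / 2 * assort$k * q12 * em^2
  k_f <- l * (l - 1) / 2 * assort$k * q12 * ef^2
  s_term <- l * (l - 1) * assort$s * q12 * em * ef
  cov_total <- f_term + k_m + k_f + s_term
  list(v_base = v_base, f_term = f_term,
       k_term = k_m + k_f, k_maternal = k_m, k_paternal = k_f,
       s_term = s_term, cov_total = cov_total,
       v_x = v_base + 2 * cov_total)
}

#' Labeled single-locus variance decomposition table
#'
#' Evaluates the per-component contributions to the single-locus variance,
#' grouped exactly as in the closed forms: squared-effect terms and pairwise
#' covariance terms, under a chosen regime.
#'
#' @inheritParams var_am
#' @param regime One of `"rm"`, `"am"`, `"sibdiff-rm"`, `"sibdiff-am"`.
#' @return A data frame with columns `component` and `value`; the values sum
#'   to the corresponding variance function.
#' @export
run_variance_table <- function(locus,
                               regime = c("rm", "am", "sibdiff-rm",
                                          "sibdiff-am"),
                               rho = 0) {
  regime <- match.arg(regime)
  locus <- as_locus_params(locus)
  stopifnot(nrow(locus) == 1)
  q12 <- locus$q1 * locus$q2
  b <- locus
  comp <- switch(regime,
    "rm" = , "am" = {
      x <- c(direct      = b$beta_c^2,
             maternal    = b$beta_m^2,
             paternal    = b$beta_f^2,
             imprinting  = b$beta_i^2,
             `direct-maternal` = b$beta_c * b$beta_m,
             `direct-paternal` = b$beta_c * b$beta_f,
             `maternal-imprinting` = b$beta_m * b$beta_i,
             `paternal-imprinting` = -b$beta_f * b$beta_i)
      2 * q12 * x
    },
    "sibdiff-rm" = , "sibdiff-am" = {
      x <- c(direct     = b$beta_c^2,
             imprinting = b$beta_i^2,
             sibling    = b$beta_s^2,
             `direct-sibling` = -2 * b$beta_c * b$beta_s)
      2 * q12 * x
    })
  if (regime == "am") {
    check_rho(rho)
    rho1 <- q12 * rho * c(direct = b$beta_c^2, maternal = 2 * b$beta_m^2,
                          paternal = 2 * b$beta_f^2,
                          imprinting = -b$beta_i^2,
                          `direct-maternal` = 4 * b$beta_c * b$beta_m,
                          `direct-paternal` = 4 * b$beta_c * b$beta_f,
                          `maternal-paternal` = 4 * b$beta_m * b$beta_f)
    rho2 <- q12 * rho^2 * c(direct = b$beta_c^2, imprinting = -b$beta_i^2,
                            `direct-maternal` = 2 * b$beta_c * b$beta_m,
                            `direct-paternal` = 2 * b$beta_c * b$beta_f,
                            `maternal-imprinting` = -2 * b$beta_m * b$beta_i,
                            `paternal-imprinting` = 2 * b$beta_f * b$beta_i,
                            `maternal-paternal` = 4 * b$beta_m * b$beta_f)
    out <- rbind(
      data.frame(order = "rho^0", component = names(comp), value = unname(comp)),
      data.frame(order = "rho^1", component = names(rho1), value = unname(rho1)),
      data.frame(order = "rho^2", component = names(rho2), value = unname(rho2)))
  } else if (regime == "sibdiff-am") {
    check_rho(rho)
    out <- data.frame(order = "(1-rho)", component = names(comp),
                      value = unname(comp) * (1 - rho))
  } else {
    out <- data.frame(order = "rho^0", component = names(comp),
                      value = unname(comp))
  }
  attr(out, "regime") <- regime
  attr(out, "total") <- sum(out$value)
  out
}
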