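#' Exact parent-offspring mating table for one biallelic locus
#'
#' Enumerates the 16 distinct (mother genotype, father genotype, ordered
#' child genotype) combinations with positive probability, together with the
#' integer multipliers that build the child phenotype
#' `Yc = c_c*beta_c + c_m*beta_m + c_f*beta_f + c_i*beta_i` and the
#' random-mating probability `z` (Hardy-Weinberg parent frequencies times
#' Mendelian transmission). Child genotypes are ordered maternal-allele
#' first; heterozygous parents are unordered. The imprinting multiplier is
#' `c_i = Am - Af` over allele indicators, so it is nonzero only for
#' heterozygous children: +1 when A2 came from the mother, -1 from the
#' father. This reproduces the confounding between reciprocal heterozygotes:
#' the phenotypes of AmAf = A1A2 vs A2A1 children differ whenever either
#' imprinting or unequal parental effects are present.
#'
#' @param locus A single-locus [locus_params].
#' @return A data frame of class `mating_table` with columns `x_m`, `x_f`
#'   (parent dosages 0/1/2), `a_m`, `a_f` (child allele indicators), `x_c`
#'   (child dosage), `c_c`, `c_m`, `c_f`, `c_i` (phenotype multipliers),
#'   `y_c` (numeric phenotype value for the locus effects) and `z`
#'   (random-mating probability at the locus frequency).
#' @examples
#' tab <- trio_table(locus_params(0.3, beta_c = 1, beta_f = 0.5))
#' sum(tab$z)  # 1
#' @export
trio_table <- function(locus) {
  locus <- as_locus_params(locus)
  stopifnot(nrow(locus) == 1)
  g <- expand.grid(a_f = 0:1, a_m = 0:1, x_f = 0:2, x_m = 0:2)
  tm <- transmission_prob(g$x_m, g$a_m)
  tf <- transmission_prob(g$x_f, g$a_f)
  keep <- tm * tf > 0
  g <- g[keep, c("x_m", "x_f", "a_m", "a_f")]
  tm <- tm[keep]; tf <- tf[keep]
  g$x_c <- g$a_m + g$a_f
  g$c_c <- g$x_c
  g$c_m <- g$x_m
  g$c_f <- g$x_f
  g$c_i <- g$a_m - g$a_f
  g$y_c <- g$c_c * locus$beta_c + g$c_m * locus$beta_m +
    g$c_f * locus$beta_f + g$c_i * locus$beta_i
  g$z <- hw_freq(g$x_m, locus$q2) * hw_freq(g$x_f, locus$q2) * tm * tf
  rownames(g) <- NULL
  structure(g, class = c("mating_table", "data.frame"),
            locus = locus, design = "trio")
}

# P(transmitted allele = a | parent dosage x), unordered heterozygotes
transmission_prob <- function(x, a) ifelse(a == 1, x / 2, 1 - x / 2)

# Hardy-Weinberg genotype frequency, optionally with inbreeding-type
# departure F (used for the assortative-mating marginals)
hw_freq <- function(x, q2, f = 0) {
  q1 <- 1 - q2
  p <- c(q1^2 + f * q1 * q2, 2 * q1 * q2 * (1 - f), q2^2 + f * q1 * q2)
  p[x + 1]
}

#' Sibling-pair extension of the mating table
#'
#' Extends [trio_table] with a second offspring per parental pair: all 36
#' distinct (parents, ordered child, ordered sibling) combinations, the two
#' phenotypes `y_c`, `y_s` (each including the indirect effect of the other
#' sibling's genotype when `beta_s != 0`) and their difference `y_diff`,
#' plus the conditional sibling factor `fz` (1, 1/2 or 1/4) such that
#' `z * fz` is the joint probability of the row. Indirect parental effects
#' are common to both siblings, so `y_diff` never contains `beta_m` or
#' `beta_f`.
#'
#' @inheritParams trio_table
#' @return A data frame of class `mating_table` with the trio columns plus
#'   `a_ms`, `a_fs`, `x_s`, `c_is`, `y_s`, `y_diff`, `fz`.
#' @export
sibling_table <- function(locus) {
  locus <- as_locus_params(locus)
  stopifnot(nrow(locus) == 1)
  tt <- trio_table(locus)
  sib <- expand.grid(a_fs = 0:1, a_ms = 0:1)
  out <- tt[rep(seq_len(nrow(tt)), each = nrow(sib)), ]
  sib <- sib[rep(seq_len(nrow(sib)), times = nrow(tt)), ]
  out$a_ms <- sib$a_ms
  out$a_fs <- sib$a_fs
  out$fz <- transmission_prob(out$x_m, out$a_ms) *
    transmission_prob(out$x_f, out$a_fs)
  out <- out[out$fz > 0, ]
  out$x_s <- out$a_ms + out$a_fs
  out$c_is <- out$a_ms - out$a_fs
  out$y_c <- out$y_c + out$x_s * locus$beta_s
  out$y_s <- out$x_s * locus$beta_c + out$x_m * locus$beta_m +
    out$x_f * locus$beta_f + out$c_is * locus$beta_i +
    out$x_c * locus$beta_s
  out$y_diff <- out$y_c - out$y_s
  rownames(out) <- NULL
  structure(out, class = c("mating_table", "data.frame"),
            locus = locus, design = "sibling")
}

#' @export
print.mating_table <- function(x, ...) {
  loc <- attr(x, "locus")
  cat("<mating_table> ", attr(x, "design"), " design, ", nrow(x),
      " rows, q2 = ", loc$q2, "\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Offspring frequencies under assortative mating
#'
#' Evaluates the assortative-mating probability of each mating-table row at
#' mate allele correlation `rho`:
#' `z_AM = P_AM(x_m) P_AM(x_f) T(child | parents) [1 + rho*d_m*d_f / S]`,
#' where `P_AM` are the genotype frequencies with inbreeding-type departure
#' `F = rho`, `d = x - 2 q2` is the genotype deviation from its mean,
#' and `S = 2 q1 q2 (1 + rho)` is the parental genotype variance. The
#' bracket makes the mates' genotype correlation exactly `rho`; at
#' `rho = 0` the row frequency reduces to `z`. For sibling tables the
#' conditional factor `fz` multiplies in, so the result is the joint row
#' probability in either design. Allele frequencies are invariant: the
#' `z_AM`-weighted child A2 frequency equals `q2` for every `rho`.
#'
#' Of the two typographically possible readings of the printed bracket
#' (`1 + rho*d_m*d_f/S` vs `1 + rho*S*d_m*d_f`), both conserve total
#' probability and allele frequency (the correction is mean-zero either
#' way); only this one also reproduces the closed-form assortative-mating
#' variance, which is what pins the parse (see the test suite).
#'
#' @param table A `mating_table` from [trio_table] or [sibling_table].
#' @param rho Mate allele correlation in \[0, 1\].
#' @return Numeric vector of row probabilities summing to 1.
#' @export
am_frequency <- function(table, rho) {
  stopifnot(inherits(table, "mating_table"))
  check_rho(rho)
  locus <- attr(table, "locus")
  q2 <- locus$q2
  s <- 2 * (1 - q2) * q2 * (1 + rho)
  dm <- table$x_m - 2 * q2
  df <- table$x_f - 2 * q2
  w <- hw_freq(table$x_m, q2, rho) * hw_freq(table$x_f, q2, rho) *
    (1 + rho * dm * df / s) *
    transmission_prob(table$x_m, table$a_m) *
    transmission_prob(table$x_f, table$a_f)
  if (attr(table, "design") == "sibling") w <- w * table$fz
  w
}

#' Weighted moments of the mating-table phenotype
#'
#' First and second central moments of the child phenotype (trio design) or
#' of the sibling difference (sibdiff design) under a supplied weight
#' vector — the brute-force counterpart of the closed-form means and
#' variances. With random-mating weights it reproduces [mean_rm]/[var_rm]
#' (or [var_sibdiff_rm]); with [am_frequency] weights it reproduces
#' [var_am] (or [var_sibdiff_am]) and leaves the mean unchanged.
#'
#' @param table A `mating_table`.
#' @param weights Row probabilities; defaults to the random-mating
#'   probabilities of the table (`z`, times `fz` for sibling tables).
#'   Must sum to 1 within 1e-12.
#' @param design `"trio"` (moments of `y_c`) or `"sibdiff"` (moments of
#'   `y_c - y_s`; requires a sibling table).
#' @return Named numeric vector `c(mean, variance)`.
#' @export
enumerate_moments <- function(table, weights = NULL,
                              design = c("trio", "sibdiff")) {
  stopifnot(inherits(table, "mating_table"))
  design <- match.arg(design)
  if (is.null(weights)) {
    weights <- table$z
    if (attr(table, "design") == "sibling") weights <- weights * table$fz
  }
  stopifnot(length(weights) == nrow(table), all(weights >= -1e-15))
  if (abs(sum(weights) - 1) > 1e-12)
    stop("`weights` must be normalized (|sum - 1| <= 1e-12)")
  y <- if (design == "sibdiff") {
    if (attr(table, "design") != "sibling")
      stop("sibdiff moments require a sibling_table()")
    table$y_diff
  } else {
    table$y_c
  }
  m <- sum(y * weights)
  c(mean = m, variance = sum(y^2 * weights) - m^2)
}
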