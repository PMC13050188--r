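#' Per-locus allele frequency and effect sizes
#'
#' Bundles the parameters of a single biallelic locus: the frequency `q2` of
#' the trait-associated allele A2 and the five effect sizes acting on a
#' child's phenotype. All effects are in trait units per copy of A2
#' (dosage coding 0/1/2); the parent-of-origin effect `beta_i` is coded
#' +1 for a maternally inherited A2 and -1 for a paternally inherited A2
#' in heterozygotes, 0 otherwise. This coding is fixed package-wide.
#'
#' All arguments recycle to a common length, so a `locus_params` object can
#' describe one locus or a whole set of causal loci.
#'
#' @param q2 Frequency of allele A2, in (0, 1).
#' @param beta_c Direct effect of the child's own genotype.
#' @param beta_m Indirect maternal effect (per copy of A2 in the mother).
#' @param beta_f Indirect paternal effect (per copy of A2 in the father).
#' @param beta_i Parent-of-origin (imprinting) effect.
#' @param beta_s Indirect sibling effect (per copy of A2 in the sibling).
#' @return An object of class `locus_params`: a data frame with columns
#'   `q2`, `q1`, `beta_c`, `beta_m`, `beta_f`, `beta_i`, `beta_s`.
#' @examples
#' locus_params(q2 = 0.3, beta_c = 1, beta_m = 0.5)
#' @export
locus_params <- function(q2, beta_c = 0, beta_m = 0, beta_f = 0,
                         beta_i = 0, beta_s = 0) {
  stopifnot(is.numeric(q2), all(is.finite(q2)), all(q2 > 0), all(q2 < 1))
  b <- list(beta_c, beta_m, beta_f, beta_i, beta_s)
  if (!all(vapply(b, function(x) is.numeric(x) && all(is.finite(x)), TRUE)))
    stop("all effect sizes must be finite numerics")
  out <- data.frame(q2 = q2, q1 = 1 - q2, beta_c = beta_c, beta_m = beta_m,
                    beta_f = beta_f, beta_i = beta_i, beta_s = beta_s)
  class(out) <- c("locus_params", "data.frame")
  out
}

#' @export
print.locus_params <- function(x, ...) {
  cat("<locus_params> ", nrow(x), " locus/loci\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

as_locus_params <- function(x) {
  if (inherits(x, "locus_params")) return(x)
  if (is.data.frame(x)) {
    miss <- setdiff(c("q2", "beta_c", "beta_m", "beta_f", "beta_i", "beta_s"),
                    names(x))
    for (m in miss) x[[m]] <- 0
    return(locus_params(x$q2, x$beta_c, x$beta_m, x$beta_f, x$beta_i, x$beta_s))
  }
  stop("cannot interpret `locus` as locus_params")
}

#' Assortative-mating parameters
#'
#' Holds the correlations induced by assortative mating: `rho`, the
#' correlation among mates' alleles (equivalently genotypes) at a causal
#' locus, which plays the role of an inbreeding coefficient F in the
#' offspring generation; `rho_y`, the target phenotypic correlation among
#' mates used by the simulator's phenotype-ordering assortment; and the
#' child-level allele correlations `f` (maternal vs paternal allele, same
#' locus), `k` (alleles at different loci within the same gamete) and `s`
#' (maternal vs paternal allele at different loci).
#'
#' @param rho Mate allele correlation at a causal locus, in \[0, 1\].
#'   Disassortative mating (negative rho) is rejected: the mating-table
#'   frequencies are only established for rho >= 0.
#' @param rho_y Target mate phenotypic correlation, in \[0, 1\].
#' @param f,k,s Child allele correlations, each in \[-1, 1\].
#' @return An object of class `assortment_params` (a list).
#' @export
assortment_params <- function(rho = 0, rho_y = 0, f = 0, k = 0, s = 0) {
  check_rho(rho)
  stopifnot(is.numeric(rho_y), length(rho_y) == 1, rho_y >= 0, rho_y <= 1)
  for (v in list(f, k, s))
    stopifnot(is.numeric(v), length(v) == 1, abs(v) <= 1)
  structure(list(rho = rho, rho_y = rho_y, f = f, k = k, s = s),
            class = "assortment_params")
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) ||
      rho < 0 || rho > 1)
    stop("`rho` must be a single value in [0, 1]")
  invisible(rho)
}
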