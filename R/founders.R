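#' Synthetic founder haplotype panel
#'
#' Generates `2n` binary haplotypes at `n_loci` biallelic loci from a
#' first-order Markov copying model along the genome: locus `j`'s allele is
#' drawn conditionally on locus `j-1` so that the adjacent-haplotype allele
#' correlation is approximately `ld_decay`, and correlation between loci a
#' distance `d` apart decays roughly as `ld_decay^d`. Target A2 frequencies
#' are drawn uniformly from `maf_range`. This is a synthetic stand-in for a
#' phased reference panel (e.g. a random SNP subset of a public resource);
#' [read_founder_vcf] accepts real phased genotypes instead.
#'
#' @param n Number of diploid founder individuals (>= 1).
#' @param n_loci Number of loci (>= 1).
#' @param maf_range Length-2 range in (0, 1) for the A2 frequency draw.
#' @param ld_decay Adjacent-locus haplotype allele correlation in \[0, 1).
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @return An object of class `haplotype_panel`: list with `hap`
#'   (2n x n_loci 0/1 integer matrix; rows 2i-1 and 2i are individual i's
#'   maternal and paternal haplotypes), `freq` (realized A2 frequencies),
#'   `positions` (abstract coordinates 1..n_loci) and `n`.
#' @examples
#' p <- founder_panel(100, 50, ld_decay = 0.5, seed = 1)
#' range(p$freq)
#' @export
founder_panel <- function(n, n_loci, maf_range = c(0.1, 0.9),
                          ld_decay = 0, seed = NULL) {
  stopifnot(n >= 1, n_loci >= 1, length(maf_range) == 2,
            all(maf_range > 0), all(maf_range < 1))
  if (!is.numeric(ld_decay) || length(ld_decay) != 1 ||
      ld_decay < 0 || ld_decay >= 1)
    stop("`ld_decay` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  nh <- 2L * as.integer(n)
  q <- runif(n_loci, min(maf_range), max(maf_range))
  hap <- matrix(0L, nh, n_loci)
  hap[, 1] <- as.integer(runif(nh) < q[1])
  for (j in seq_len(n_loci)[-1]) {
    # conditional Bernoulli keeping marginal q[j]; clamped where the
    # frequency contrast makes the exact correlation unattainable
    p <- q[j] + ld_decay * sqrt(q[j] * (1 - q[j]) /
                                  (q[j - 1] * (1 - q[j - 1]))) *
      (hap[, j - 1] - q[j - 1])
    p <- pmin(1, pmax(0, p))
    hap[, j] <- as.integer(runif(nh) < p)
  }
  freq <- colMeans(hap)
  # guard against fixation at small n: redraw monomorphic columns freely
  mono <- which(freq <= 0 | freq >= 1)
  for (j in mono) {
    hap[, j] <- as.integer(runif(nh) < q[j])
    while (sum(hap[, j]) %in% c(0L, nh))
      hap[, j] <- as.integer(runif(nh) < q[j])
  }
  if (length(mono)) freq <- colMeans(hap)
  structure(list(hap = hap, freq = freq, positions = seq_len(n_loci),
                 n = as.integer(n)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", x$n, " individuals (", nrow(x$hap),
      " haplotypes) x ", ncol(x$hap), " loci\n", sep = "")
  cat("  A2 frequency range: ",
      paste(signif(range(x$freq), 3), collapse = " - "), "\n", sep = "")
  invisible(x)
}
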