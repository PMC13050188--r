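#' Pairwise genomic relatedness
#'
#' Standard genomic relationship values: per-locus dosages are standardized
#' as `(X - 2q) / sqrt(2 q (1-q))` and cross-products averaged over loci.
#' Monomorphic loci are excluded (with their count reported via attribute).
#' Intended for moderate n; the binned curve ([relatedness_curve]) streams
#' pairs in blocks instead of materializing them.
#'
#' @param geno n x L dosage matrix (0/1/2).
#' @param freqs A2 frequencies per locus; computed from `geno` when NULL.
#' @return A data frame with columns `i`, `j` (i < j) and `pi`, with
#'   attributes `diag` (the self-relatedness diagnostic, approximately
#'   1 + inbreeding deviation) and `n_monomorphic`.
#' @export
grm_pairs <- function(geno, freqs = NULL) {
  stopifnot(is.matrix(geno))
  if (is.null(freqs)) freqs <- colMeans(geno) / 2
  poly <- freqs > 0 & freqs < 1
  n_mono <- sum(!poly)
  z <- scale(geno[, poly, drop = FALSE],
             center = 2 * freqs[poly],
             scale = sqrt(2 * freqs[poly] * (1 - freqs[poly])))
  g <- tcrossprod(z) / sum(poly)
  ut <- which(upper.tri(g), arr.ind = TRUE)
  out <- data.frame(i = ut[, 1], j = ut[, 2], pi = g[ut])
  attr(out, "diag") <- diag(g)
  attr(out, "n_monomorphic") <- n_mono
  out
}

#' Phenotypic correlation of pairs as a function of genomic relatedness
#'
#' Bins all pairs of individuals by their genomic relationship and computes,
#' per bin, the Pearson correlation between the two members' (standardized)
#' phenotypes, with each unordered pair entered once in randomized member
#' order (`double_entry = TRUE` symmetrizes instead). A weighted
#' least-squares line is fitted to the bin correlations over the
#' unrelated-pair region `fit_range`; under a purely direct-effect trait
#' and random mating its slope estimates the heritability.
#'
#' Pairs are processed in column blocks of the relationship matrix, so the
#' full n x n matrix is never held in memory.
#'
#' @param geno n x L dosage matrix at the loci used for relatedness.
#' @param phen Length-n phenotype vector.
#' @param bin_width Relatedness bin width (default 0.01).
#' @param min_pairs Minimum pairs for a bin to be retained (default 30).
#' @param fit_range Relatedness interval for the slope fit
#'   (default c(-0.02, 0.02)).
#' @param double_entry Enter each pair twice in symmetrical order instead
#'   of once in random order.
#' @param block Individuals per block in the streamed computation.
#' @param freqs Optional allele frequencies for standardization.
#' @return An object of class `relatedness_curve`: list with `bins` (data
#'   frame: `midpoint`, `n_pairs`, `correlation`, `se`), `slope`,
#'   `slope_se`, `close_excess` (mean excess of the close-relative bins,
#'   relatedness 0.35-0.65, over the unrelated-region extrapolation — a
#'   positive value flags a change of slope towards close relatives),
#'   `fit_range`, `n` and `n_loci`.
#' @export
relatedness_curve <- function(geno, phen, bin_width = 0.01, min_pairs = 30,
                              fit_range = c(-0.02, 0.02),
                              double_entry = FALSE, block = 2000,
                              freqs = NULL) {
  stopifnot(is.matrix(geno), nrow(geno) == length(phen))
  n <- nrow(geno)
  if (is.null(freqs)) freqs <- colMeans(geno) / 2
  poly <- freqs > 0 & freqs < 1
  z <- scale(geno[, poly, drop = FALSE],
             center = 2 * freqs[poly],
             scale = sqrt(2 * freqs[poly] * (1 - freqs[poly])))
  L <- sum(poly)
  y <- as.numeric(scale(phen))

  breaks <- seq(-0.5, 1.5, by = bin_width)
  nb <- length(breaks) - 1
  acc <- matrix(0, nb, 6)  # n, sx, sy, sxx, syy, sxy
  starts <- seq(1, n, by = block)
  # columns are processed in blocks and, within a block, pairs in slices,
  # so peak memory stays modest even for tens of millions of pairs
  slice_cols <- max(1L, as.integer(2e6 %/% n))
  for (s in starts) {
    idx <- s:min(s + block - 1, n)
    gb <- tcrossprod(z, z[idx, , drop = FALSE]) / L  # n x |idx|
    for (cs in seq(1, length(idx), by = slice_cols)) {
      cols <- cs:min(cs + slice_cols - 1, length(idx))
      jj <- rep(idx[cols], each = n)
      ii <- rep(seq_len(n), times = length(cols))
      keep <- ii < jj
      pi_v <- as.numeric(gb[, cols])[keep]
      y1 <- y[ii[keep]]; y2 <- y[jj[keep]]
      if (!double_entry) {
        sw <- runif(length(y1)) < 0.5
        tmp <- y1[sw]; y1[sw] <- y2[sw]; y2[sw] <- tmp
      }
      b <- findInterval(pi_v, breaks, rightmost.closed = TRUE)
      b[b < 1] <- 1; b[b > nb] <- nb
      upd <- rowsum(cbind(1, y1, y2, y1^2, y2^2, y1 * y2), b)
      rows <- as.integer(rownames(upd))
      acc[rows, ] <- acc[rows, ] + upd
      if (double_entry) {
        upd2 <- rowsum(cbind(1, y2, y1, y2^2, y1^2, y1 * y2), b)
        acc[rows, ] <- acc[rows, ] + upd2
      }
    }
  }
  nn <- acc[, 1]
  keep <- nn >= max(3, min_pairs)
  mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
  r <- rep(NA_real_, nb)
  vx <- acc[, 4] - acc[, 2]^2 / pmax(nn, 1)
  vy <- acc[, 5] - acc[, 3]^2 / pmax(nn, 1)
  cxy <- acc[, 6] - acc[, 2] * acc[, 3] / pmax(nn, 1)
  ok <- keep & vx > 0 & vy > 0
  r[ok] <- cxy[ok] / sqrt(vx[ok] * vy[ok])
  se <- sqrt(pmax(0, (1 - r^2)) / pmax(nn - 2, 1))
  bins <- data.frame(midpoint = mid, n_pairs = nn,
                     correlation = r, se = se)[ok, ]
  rownames(bins) <- NULL

  fit_bins <- bins[bins$midpoint >= fit_range[1] &
                     bins$midpoint <= fit_range[2], ]
  slope <- slope_se <- NA_real_
  close_excess <- NA_real_
  if (nrow(fit_bins) >= 2) {
    fit <- lm(correlation ~ midpoint, data = fit_bins,
              weights = fit_bins$n_pairs)
    slope <- coef(fit)[["midpoint"]]
    slope_se <- summary(fit)$coefficients["midpoint", "Std. Error"]
    # flag a change of slope towards close relatives: observed minus the
    # unrelated-region extrapolation, over the sib/parent-offspring bins
    close <- bins[bins$midpoint > 0.35 & bins$midpoint < 0.65, ]
    if (nrow(close) > 0) {
      pred <- coef(fit)[1] + slope * close$midpoint
      close_excess <- sum((close$correlation - pred) * close$n_pairs) /
        sum(close$n_pairs)
    }
  }
  structure(list(bins = bins, slope = slope, slope_se = slope_se,
                 close_excess = close_excess,
                 fit_range = fit_range, n = n, n_loci = L),
            class = "relatedness_curve")
}

#' @export
print.relatedness_curve <- function(x, ...) {
  cat("<relatedness_curve> ", x$n, " individuals, ", x$n_loci, " loci, ",
      nrow(x$bins), " bins\n", sep = "")
  cat(sprintf("  unrelated-region slope (pi in [%g, %g]): %.4f (se %.4f)\n",
              x$fit_range[1], x$fit_range[2], x$slope, x$slope_se))
  if (is.finite(x$close_excess))
    cat(sprintf("  close-relative excess over linear fit: %+.4f\n",
                x$close_excess))
  invisible(x)
}

#' @export
plot.relatedness_curve <- function(x, ...) {
  b <- x$bins
  plot(b$midpoint, b$correlation, pch = 19, cex = 0.6,
       xlab = "genomic relationship", ylab = "phenotypic correlation",
       ...)
  arrows(b$midpoint, b$correlation - b$se, b$midpoint,
         b$correlation + b$se, angle = 90, code = 3, length = 0.02)
  if (is.finite(x$slope))
    abline(a = mean(b$correlation[b$midpoint >= x$fit_range[1] &
                                    b$midpoint <= x$fit_range[2]],
                    na.rm = TRUE) -
             x$slope * mean(x$fit_range), b = x$slope, lty = 3)
  invisible(x)
}

#' Full-sibling phenotypic correlation
#'
#' Pearson correlation over all within-family pairs of full siblings (pairs
#' sharing both parents). Each unordered pair enters once, in randomized
#' member order.
#'
#' @param sim_or_ped A `fam_sim` or a pedigree data frame with columns
#'   `id`, `mother`, `father`, `generation`, `phenotype`.
#' @param generations Generation indices whose sibling pairs are pooled
#'   (default: the last generation of a `fam_sim`; all offspring
#'   generations of a pedigree).
#' @param seed Optional integer seed for the randomized ordering.
#' @return The correlation, with attribute `n_pairs`.
#' @export
full_sib_correlation <- function(sim_or_ped, generations = NULL,
                                 seed = NULL) {
  if (inherits(sim_or_ped, "fam_sim")) {
    ped <- pedigree(sim_or_ped)
    if (is.null(generations)) generations <- sim_or_ped$generations
  } else {
    ped <- sim_or_ped
    stopifnot(all(c("mother", "father", "generation", "phenotype") %in%
                    names(ped)))
    if (is.null(generations))
      generations <- setdiff(unique(ped$generation), 0)
  }
  if (!is.null(seed)) set.seed(seed)
  ped <- ped[ped$generation %in% generations & !is.na(ped$mother), ]
  fam <- split(ped$phenotype, paste(ped$generation, ped$mother, ped$father))
  pairs <- do.call(rbind, lapply(fam, function(y) {
    if (length(y) < 2) return(NULL)
    cmb <- utils::combn(length(y), 2)
    cbind(y[cmb[1, ]], y[cmb[2, ]])
  }))
  if (is.null(pairs) || nrow(pairs) < 3)
    stop("fewer than 3 full-sibling pairs with phenotypes")
  sw <- runif(nrow(pairs)) < 0.5
  pairs[sw, ] <- pairs[sw, 2:1]
  r <- cor(pairs[, 1], pairs[, 2])
  attr(r, "n_pairs") <- nrow(pairs)
  r
}

#' Relatedness-curve experiment on simulated families
#'
#' Runs the forward simulator under a chosen scenario and mating regime,
#' then computes the binned phenotypic-correlation-vs-relatedness curve
#' (relatedness taken at the causal loci) and the full-sibling correlation.
#' The pair set is either the final generation alone or the last two
#' generations pooled (which populates the close-relative bins with both
#' sibling and parent-offspring pairs).
#'
#' @param scenario An [effect_scenario] (typically "V1" or "V6").
#' @param regime `"rm"` or `"am"`.
#' @param n Individuals per generation.
#' @param n_loci Panel loci (all causal).
#' @param generations Offspring generations.
#' @param rho_y Mate phenotypic correlation for "am" (ignored when
#'   `calibrate_rho_g` is given).
#' @param calibrate_rho_g Optional target mate causal-score correlation
#'   passed to [run_generations].
#' @param pair_set `"final"` or `"last2"`.
#' @param seed Integer seed.
#' @param ... Passed to [relatedness_curve].
#' @return A list with `curve` (a `relatedness_curve`), `full_sib`
#'   (correlation with `n_pairs` attribute) and `sim` (the `fam_sim`).
#' @export
relatedness_experiment <- function(scenario, regime = c("rm", "am"),
                                   n = 8000, n_loci = 1000,
                                   generations = 10, rho_y = 0.2,
                                   calibrate_rho_g = NULL,
                                   pair_set = c("final", "last2"),
                                   seed = 1, ...) {
  regime <- match.arg(regime)
  pair_set <- match.arg(pair_set)
  set.seed(seed)
  panel <- founder_panel(n, n_loci, ld_decay = 0.2)
  sim <- run_generations(
    panel, scenario, generations = generations,
    rho_y = if (regime == "am") rho_y else 0,
    calibrate_rho_g = if (regime == "am") calibrate_rho_g else NULL,
    keep = "last2")
  gidx <- if (pair_set == "final") sim$generations + 1 else
    sim$generations + 0:1
  geno <- do.call(rbind, lapply(gidx, function(gi)
    sim$gen[[gi]]$mat[, sim$causal, drop = FALSE] +
      sim$gen[[gi]]$pat[, sim$causal, drop = FALSE]))
  phen <- unlist(lapply(gidx, function(gi) sim$gen[[gi]]$phen))
  curve <- relatedness_curve(geno, phen, ...)
  fs <- full_sib_correlation(sim)
  list(curve = curve, full_sib = fs, sim = sim)
}
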