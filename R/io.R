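#' Read phased founder genotypes from a VCF file
#'
#' Imports a phased biallelic VCF into a founder [haplotype_panel].
#' Only phased ("|"-separated GT) biallelic SNP records are used; unphased
#' or multiallelic records are skipped with counts reported in a message
#' and in attributes. The first haplotype column of each sample is taken as
#' the maternal strand by convention.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A `haplotype_panel` with attributes `n_skipped_unphased` and
#'   `n_skipped_multiallelic`.
#' @export
read_founder_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0) stop("no genotype records in ", path)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & nchar(alt) > 0
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- rowSums(!grepl("\\|", gt) & !is.na(gt)) == 0
  n_multi <- sum(!biallelic)
  n_unph <- sum(biallelic & !phased)
  keep <- biallelic & phased
  if (!any(keep))
    stop("no phased biallelic records in ", path)
  if (n_multi + n_unph > 0)
    message("skipped ", n_multi, " multiallelic and ", n_unph,
            " unphased record(s)")
  gt <- gt[keep, , drop = FALSE]
  n <- ncol(gt)
  L <- nrow(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), L, n)
  a2 <- matrix(as.integer(substr(gt, 3, 3)), L, n)
  if (anyNA(a1) || anyNA(a2) || any(a1 > 1) || any(a2 > 1))
    stop("malformed GT field; only 0|0, 0|1, 1|0, 1|1 are supported")
  hap <- matrix(0L, 2 * n, L)
  hap[seq(1, 2 * n, 2), ] <- t(a1)  # maternal-first convention
  hap[seq(2, 2 * n, 2), ] <- t(a2)
  out <- structure(list(hap = hap, freq = colMeans(hap),
                        positions = seq_len(L), n = n),
                   class = "haplotype_panel")
  attr(out, "n_skipped_unphased") <- n_unph
  attr(out, "n_skipped_multiallelic") <- n_multi
  out
}

#' Write phased genotypes to a VCF file
#'
#' Writes a [haplotype_panel] (or one generation of a `fam_sim`) as a
#' minimal phased VCF 4.2 text file. The GT field is phased ("|"), maternal
#' allele first, matching the package-wide maternal-first ordering; this
#' convention and the seed are recorded in the header. Coordinates are
#' 1-based positions on a single abstract contig.
#'
#' @param x A `haplotype_panel`, or a `fam_sim` (then `generation` selects
#'   the population to write).
#' @param path Output file path.
#' @param generation Generation index for a `fam_sim` (default last).
#' @param seed Optional seed to record in the header.
#' @return Invisibly, `path`.
#' @export
write_founder_vcf <- function(x, path, generation = NULL, seed = NULL) {
  if (inherits(x, "fam_sim")) {
    if (is.null(generation)) generation <- x$generations
    g <- x$gen[[generation + 1]]
    mat <- t(g$mat); pat <- t(g$pat)   # loci x individuals
  } else if (inherits(x, "haplotype_panel")) {
    mat <- t(x$hap[seq(1, nrow(x$hap), 2), , drop = FALSE])
    pat <- t(x$hap[seq(2, nrow(x$hap), 2), , drop = FALSE])
  } else stop("`x` must be a haplotype_panel or fam_sim")
  n <- ncol(mat); L <- nrow(mat)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=famvar-", utils::packageVersion("famvar")),
           "##phasing=full;GT maternal allele first",
           if (!is.null(seed)) paste0("##famvar_seed=", seed),
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", seq_len(n))),
                 collapse = "\t"))
  gtm <- matrix(paste(mat, pat, sep = "|"), L, n)
  body <- paste("1", seq_len(L), paste0("loc", seq_len(L)), "A", "G",
                ".", "PASS", ".", "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the pedigree and phenotypes of a simulation as TSV
#'
#' Deterministic column order (`id`, `father`, `mother`, `sex`,
#' `generation`, `phenotype`) with header comment lines carrying the
#' package version and the seed, so a run is reproducible end-to-end from
#' (config, seed).
#'
#' @param sim A `fam_sim`.
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return Invisibly, `path`.
#' @export
write_pedigree_tsv <- function(sim, path, seed = NULL) {
  stopifnot(inherits(sim, "fam_sim"))
  ped <- pedigree(sim)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# famvar ", utils::packageVersion("famvar")),
    if (!is.null(seed)) paste0("# seed: ", seed),
    paste0("# scenario: ", sim$scenario$id, "; n: ", sim$n,
           "; generations: ", sim$generations,
           "; rho_y: ", sim$rho_y)), con)
  utils::write.table(ped, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
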