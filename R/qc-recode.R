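# Quality control and VCF-style allele recoding.
#
# Threshold semantics: "below 80%", "under 95%" and "heterozygosity below
# 0.095" are strict -- a marker sitting exactly on the boundary is kept.
# Allele frequencies count each non-missing genotype as two observations.

#' QC thresholds
#'
#' @param msat_call_rate_min minimum microsatellite call rate (default 0.80).
#' @param msat_het_min minimum expected heterozygosity (default 0.095, the
#'   He of a biallelic locus at 5% minor allele frequency).
#' @param snp_call_rate_min minimum SNP call rate (default 0.95).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(msat_call_rate_min = 0.80, msat_het_min = 0.095,
                          snp_call_rate_min = 0.95) {
  v <- c(msat_call_rate_min, msat_het_min, snp_call_rate_min)
  if (any(v < 0 | v > 1)) stop_msg("thresholds must lie in [0, 1]")
  structure(list(msat_call_rate_min = msat_call_rate_min,
                 msat_het_min = msat_het_min,
                 snp_call_rate_min = snp_call_rate_min),
            class = "qc_thresholds")
}

#' Expected heterozygosity
#'
#' He = 1 - sum(p^2) over allele frequencies. For a biallelic locus at 5%
#' minor allele frequency this equals 0.095, the QC floor.
#'
#' @param freqs numeric allele frequencies summing to 1.
#' @return He in `[0, 1 - 1/k]`.
#' @export
expected_heterozygosity <- function(freqs) {
  if (any(freqs < 0)) stop_msg("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop_msg("frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Empirical allele frequencies at one locus
#'
#' @param x an [msat_geno]; @param locus locus id or index.
#' @return Named numeric vector of frequencies (names = allele length bp,
#'   ascending), from non-missing genotypes (two observations each).
#' @export
msat_allele_freqs <- function(x, locus) {
  if (is.character(locus)) locus <- match(locus, x$loci$id)
  obs <- c(x$a1[, locus], x$a2[, locus])
  obs <- obs[!is.na(obs)]
  if (!length(obs)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(obs)
  stats::setNames(as.numeric(tab) / length(obs), names(tab))
}

#' Filter microsatellite loci on call rate and heterozygosity
#'
#' A locus is kept iff call rate >= `msat_call_rate_min` AND He >=
#' `msat_het_min` (strict removal below the thresholds). A locus with zero
#' non-missing calls is excluded with reason `"no data"`.
#'
#' @param x an [msat_geno].
#' @param thresholds a [qc_thresholds].
#' @return List: `kept` (the filtered [msat_geno]) and `report`
#'   (data.frame: locus, call_rate, het, kept, reason).
#' @export
filter_microsatellites <- function(x, thresholds = qc_thresholds()) {
  L <- nrow(x$loci)
  if (L < 1L) stop_msg("no loci to filter")
  report <- data.frame(locus = x$loci$id, call_rate = NA_real_,
                       het = NA_real_, kept = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    cr <- mean(!is.na(x$a1[, l]))
    report$call_rate[l] <- cr
    if (cr == 0) { report$reason[l] <- "no data"; next }
    he <- expected_heterozygosity(msat_allele_freqs(x, l))
    report$het[l] <- he
    if (cr < thresholds$msat_call_rate_min) {
      report$reason[l] <- sprintf("call rate %.3f < %.2f", cr,
                                  thresholds$msat_call_rate_min)
    } else if (he < thresholds$msat_het_min) {
      report$reason[l] <- sprintf("He %.4f < %.3f", he, thresholds$msat_het_min)
    } else {
      report$kept[l] <- TRUE
    }
  }
  list(kept = x[, which(report$kept)], report = report)
}

#' Filter SNPs on call rate (no MAF filter)
#'
#' A SNP is kept iff its call rate >= `snp_call_rate_min`. No minor-allele-
#' frequency filter is applied: monomorphic SNPs are retained so that
#' haplotype diversity is preserved for imputation.
#'
#' @param x a [snp_matrix].
#' @param thresholds a [qc_thresholds].
#' @return List: `kept` (filtered [snp_matrix]) and `report` (data.frame:
#'   snp_id, call_rate, kept).
#' @export
filter_snps <- function(x, thresholds = qc_thresholds()) {
  if (nrow(x$map) < 1L) stop_msg("no SNPs to filter")
  cr <- colMeans(!is.na(x$geno))
  keep <- cr >= thresholds$snp_call_rate_min
  list(kept = x[, which(keep)],
       report = data.frame(snp_id = x$map$snp_id, call_rate = unname(cr),
                           kept = unname(keep), stringsAsFactors = FALSE))
}

#' Recode microsatellite alleles to consecutive integer codes
#'
#' The most common allele in the population becomes the reference code 0;
#' the remaining alleles get consecutive codes 1..n-1 in ascending allele
#' length. Frequency ties for the most common allele are broken toward the
#' shorter allele (deterministic and sample-order independent).
#'
#' @param freqs named allele frequencies as from [msat_allele_freqs()].
#' @return Named integer vector: allele length (bp) -> code; bijective.
#' @export
recode_alleles <- function(freqs) {
  if (!length(freqs)) stop_msg("no observed alleles to recode")
  lens <- as.integer(names(freqs))
  ref <- lens[order(-freqs, lens)][1L]
  rest <- sort(lens[lens != ref])
  stats::setNames(seq_len(length(freqs)) - 1L, c(ref, rest))
}

#' Code maps for every locus of a genotype set
#'
#' One recoding pass over the full dataset (codes are population-specific
#' and fixed before any cross-validation masking).
#'
#' @param x an [msat_geno].
#' @return Named list (by locus id) of code maps from [recode_alleles()].
#' @export
build_code_maps <- function(x) {
  out <- lapply(seq_len(nrow(x$loci)),
                function(l) recode_alleles(msat_allele_freqs(x, l)))
  names(out) <- x$loci$id
  out
}

#' Apply / invert a code map on genotypes
#'
#' `encode_genotypes` maps allele lengths to codes; `decode_genotypes` is
#' its inverse, so decode(encode(x)) is the identity on observed genotypes.
#'
#' @param x an [msat_geno].
#' @param code_maps list of code maps as from [build_code_maps()].
#' @return Matrices of the same shape with codes (or an [msat_geno] for
#'   decode).
#' @export
encode_genotypes <- function(x, code_maps) {
  L <- nrow(x$loci)
  c1 <- c2 <- matrix(NA_integer_, length(x$samples), L,
                     dimnames = list(x$samples, x$loci$id))
  for (l in seq_len(L)) {
    cmap <- code_maps[[x$loci$id[l]]]
    c1[, l] <- unname(cmap[as.character(x$a1[, l])])
    c2[, l] <- unname(cmap[as.character(x$a2[, l])])
  }
  list(c1 = pmin(c1, c2), c2 = pmax(c1, c2))
}

#' @rdname encode_genotypes
#' @param codes a list with `c1`, `c2` matrices from [encode_genotypes()].
#' @export
decode_genotypes <- function(codes, x, code_maps) {
  L <- nrow(x$loci)
  a1 <- a2 <- matrix(NA_integer_, length(x$samples), L)
  for (l in seq_len(L)) {
    cmap <- code_maps[[x$loci$id[l]]]
    lens <- as.integer(names(cmap))[order(cmap)]
    a1[, l] <- lens[codes$c1[, l] + 1L]
    a2[, l] <- lens[codes$c2[, l] + 1L]
  }
  msat_geno(x$samples, x$loci, a1, a2)
}

#' Write a QC report as TSV
#'
#' @param report a QC report data.frame; @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
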