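# Exclusion-based parentage verification: Mendelian compatibility of
# microsatellite genotypes between a real-typed parent and an imputed
# offspring, with the >= 17-of-19 confirmation rule, plus an opposing-
# homozygote conflict check on the low-density SNP panel.

#' Mendelian compatibility of one marker
#'
#' TRUE iff the parent's and offspring's allele multisets share at least one
#' allele (so transmission is possible). A missing genotype on either side
#' is non-excluding: the marker returns `NA` and is not counted among the
#' markers tested.
#'
#' @param p1,p2 parent allele pair; @param o1,o2 offspring allele pair.
#'   Vectors are scored elementwise (one element per locus).
#' @return Logical vector (`NA` = not tested).
#' @export
marker_compatible <- function(p1, p2, o1, o2) {
  out <- (p1 == o1) | (p1 == o2) | (p2 == o1) | (p2 == o2)
  out[is.na(p1) | is.na(o1)] <- NA
  out
}

#' Confirmation threshold for L available markers
#'
#' The 17-of-19 rule scaled proportionally: `ceiling(17/19 * L)`.
#'
#' @param n_loci L, the number of loci available.
#' @param base_threshold,base_loci the reference rule (17 of 19).
#' @return Integer threshold.
#' @export
confirmation_threshold <- function(n_loci, base_threshold = 17L,
                                   base_loci = 19L) {
  as.integer(ceiling(base_threshold / base_loci * n_loci))
}

#' Count compatible markers for one parent-offspring pair
#'
#' @param parent_gt,offspring_gt two-column matrices (loci x 2) of allele
#'   pairs (bp); typically the parent's real genotypes and the offspring's
#'   imputed genotypes.
#' @param threshold compatible-marker count needed to confirm; defaults to
#'   [confirmation_threshold()] of the full locus count.
#' @return List of class `pair_result`: `compatible_markers`,
#'   `markers_tested`, `threshold`, `decision` in
#'   `{"confirmed", "conflict", "undetermined"}` (undetermined when fewer
#'   markers could be tested than the threshold requires).
#' @export
count_compatible <- function(parent_gt, offspring_gt, threshold = NULL) {
  parent_gt <- as.matrix(parent_gt); offspring_gt <- as.matrix(offspring_gt)
  stopifnot(nrow(parent_gt) == nrow(offspring_gt))
  if (is.null(threshold)) threshold <- confirmation_threshold(nrow(parent_gt))
  comp <- marker_compatible(parent_gt[, 1L], parent_gt[, 2L],
                            offspring_gt[, 1L], offspring_gt[, 2L])
  tested <- sum(!is.na(comp))
  n_comp <- sum(comp, na.rm = TRUE)
  decision <- if (tested < threshold) "undetermined"
  else if (n_comp >= threshold) "confirmed" else "conflict"
  structure(list(compatible_markers = n_comp, markers_tested = tested,
                 threshold = as.integer(threshold), decision = decision),
            class = "pair_result")
}

#' Opposing-homozygote conflict check on a SNP panel
#'
#' The rate of SNPs at which one individual is homozygous reference (0) and
#' the other homozygous alternate (2), over the SNPs where both are typed.
#' Under true parentage (absent genotyping error) the rate is exactly 0.
#'
#' @param parent_snp,offspring_snp genotype vectors in `{0,1,2,NA}` over
#'   the panel SNPs.
#' @param tau conflict threshold on the rate (default 0.01).
#' @param min_snps minimum jointly typed SNPs for a decision (default 50).
#' @return List: `oh_rate`, `n_tested`, `n_opposing`, `decision` in
#'   `{"confirmed", "conflict", "undetermined"}`.
#' @export
snp_window_conflicts <- function(parent_snp, offspring_snp, tau = 0.01,
                                 min_snps = 50L) {
  ok <- !is.na(parent_snp) & !is.na(offspring_snp)
  opp <- (parent_snp == 0L & offspring_snp == 2L) |
    (parent_snp == 2L & offspring_snp == 0L)
  n <- sum(ok); n_opp <- sum(opp & ok)
  if (n < min_snps)
    return(list(oh_rate = NA_real_, n_tested = n, n_opposing = n_opp,
                decision = "undetermined"))
  rate <- n_opp / n
  list(oh_rate = rate, n_tested = n, n_opposing = n_opp,
       decision = if (rate > tau) "conflict" else "confirmed")
}

#' Cohort-level conflict rate
#'
#' @param decisions character vector of pair decisions.
#' @return Percentage: `100 * conflicts / pairs analyzed` (undetermined
#'   pairs are excluded from the denominator).
#' @export
cohort_conflict_rate <- function(decisions) {
  analyzed <- decisions[decisions != "undetermined"]
  if (!length(analyzed)) stop_msg("no analyzed pairs")
  100 * sum(analyzed == "conflict") / length(analyzed)
}

#' Verify all recorded parent-offspring pairs of a cohort
#'
#' For every recorded parental link: (i) count Mendelian-compatible
#' microsatellites between the parent's real genotypes and the offspring's
#' imputed genotypes, confirming at the >= 17-of-19 rule; (ii) run the
#' opposing-homozygote check on the low-density SNP panel.
#'
#' @param pedigree the recorded `pedigree_df`.
#' @param parent_msat an [msat_geno] with the parents' real genotypes.
#' @param offspring_msat an [msat_geno] with the offspring's (imputed)
#'   genotypes.
#' @param snp a [snp_matrix] (for the opposing-homozygote check); `NULL`
#'   skips it.
#' @param panel_snp_ids SNP ids of the low-density panel (defaults to all
#'   SNPs of `snp`).
#' @param msat_threshold see [count_compatible()].
#' @param tau,min_snps see [snp_window_conflicts()].
#' @return A data.frame of class `parentage_report`: one row per pair with
#'   compatible/tested counts, decisions from both checks, and the
#'   opposing-homozygote rate.
#' @export
check_parentage <- function(pedigree, parent_msat, offspring_msat,
                            snp = NULL, panel_snp_ids = NULL,
                            msat_threshold = NULL, tau = 0.01,
                            min_snps = 50L) {
  pairs <- ped_pairs(pedigree)
  keep <- pairs$parent %in% parent_msat$samples &
    pairs$offspring %in% offspring_msat$samples
  if (!all(keep)) {
    miss <- unique(c(setdiff(pairs$parent, parent_msat$samples),
                     setdiff(pairs$offspring, offspring_msat$samples)))
    warning(sprintf("%d pair(s) dropped; ids without genotypes: %s",
                    sum(!keep), paste(utils::head(miss, 5L), collapse = ", ")))
    pairs <- pairs[keep, , drop = FALSE]
  }
  L <- nrow(offspring_msat$loci)
  pcol <- if (!is.null(snp) && is.null(panel_snp_ids)) seq_len(nrow(snp$map))
  else if (!is.null(snp)) match(panel_snp_ids, snp$map$snp_id)
  out <- pairs
  out$markers_tested <- out$compatible_markers <- NA_integer_
  out$msat_decision <- out$snp_decision <- NA_character_
  out$oh_rate <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    pi <- match(pairs$parent[r], parent_msat$samples)
    oi <- match(pairs$offspring[r], offspring_msat$samples)
    li <- match(offspring_msat$loci$id, parent_msat$loci$id)
    res <- count_compatible(
      cbind(parent_msat$a1[pi, li], parent_msat$a2[pi, li]),
      cbind(offspring_msat$a1[oi, ], offspring_msat$a2[oi, ]),
      msat_threshold)
    out$markers_tested[r] <- res$markers_tested
    out$compatible_markers[r] <- res$compatible_markers
    out$msat_decision[r] <- res$decision
    if (!is.null(snp)) {
      ps <- match(pairs$parent[r], snp$samples)
      os <- match(pairs$offspring[r], snp$samples)
      if (!is.na(ps) && !is.na(os)) {
        sc <- snp_window_conflicts(snp$geno[ps, pcol], snp$geno[os, pcol],
                                   tau, min_snps)
        out$snp_decision[r] <- sc$decision
        out$oh_rate[r] <- sc$oh_rate
      }
    }
  }
  class(out) <- c("parentage_report", "data.frame")
  out
}

#' Summarize a parentage report
#'
#' @param report a `parentage_report`.
#' @return List with pair counts, the SNP-based and microsatellite-based
#'   conflict rates (percent), and the fraction of pairs confirmed at the
#'   marker threshold.
#' @export
summarize_parentage <- function(report) {
  list(n_pairs = nrow(report),
       snp_conflict_rate = if (any(!is.na(report$snp_decision)))
         cohort_conflict_rate(report$snp_decision[!is.na(report$snp_decision)])
       else NA_real_,
       msat_conflict_rate = cohort_conflict_rate(report$msat_decision),
       pct_confirmed_msat = 100 * mean(report$msat_decision == "confirmed"),
       n_undetermined = sum(report$msat_decision == "undetermined"))
}
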