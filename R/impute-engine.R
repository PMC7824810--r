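# Li-Stephens haplotype-copying imputation of a microsatellite from its
# flanking SNP window, plus the naive and random null imputers.
#
# A target haplotype is modeled as an imperfect mosaic of the reference
# haplotypes. The switch probability between adjacent sites is
#   rho_j = 1 - exp(-4 * Ne * r_j / H)
# with r_j the Haldane recombination fraction of the inter-site gap and H
# the panel size; emissions allow a copying error eps. The STR allele
# posterior is the state posterior at the (silent) focal site, grouped by
# the STR allele each reference haplotype carries.

#' Haplotype-copying model parameters
#'
#' @param n_e effective population size entering the switch-rate scaling
#'   (default 214).
#' @param error_rate eps, the allelic copying-error rate (in `(0, 0.5)`).
#' @param max_ref_haplotypes cap H_max on the reference panel; larger panels
#'   are subsampled with `seed` (bounds the O(H^2) diploid cost).
#' @param cM_per_mb genetic map density used to convert bp gaps to
#'   recombination fractions.
#' @param seed seed for panel subsampling.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(n_e = 214, error_rate = 1e-3,
                       max_ref_haplotypes = 200L, cM_per_mb = 1, seed = 1L) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop_msg("error_rate must lie in (0, 0.5)")
  if (n_e <= 0) stop_msg("n_e must be > 0")
  structure(list(n_e = n_e, error_rate = error_rate,
                 max_ref_haplotypes = as.integer(max_ref_haplotypes),
                 cM_per_mb = cM_per_mb, seed = as.integer(seed)),
            class = "hmm_params")
}

#' Build a reference panel for one window
#'
#' @param haps binary matrix (H haplotypes x window SNPs).
#' @param str_alleles length-H vector: the STR allele (bp) carried by each
#'   reference haplotype at the focal locus.
#' @param pos window SNP positions (bp, ascending).
#' @param focal_pos the microsatellite position (bp).
#' @return A list of class `ref_panel`.
#' @export
ref_panel <- function(haps, str_alleles, pos, focal_pos) {
  haps <- as.matrix(haps); storage.mode(haps) <- "integer"
  if (nrow(haps) < 1L) stop_msg("reference panel is empty")
  if (ncol(haps) != length(pos)) stop_msg("haplotype length != SNP count")
  if (length(str_alleles) != nrow(haps))
    stop_msg("need one STR allele per reference haplotype")
  if (is.unsorted(pos)) stop_msg("window positions must be ascending")
  structure(list(haps = haps, str_alleles = as.integer(str_alleles),
                 pos = as.numeric(pos), focal_pos = as.numeric(focal_pos)),
            class = "ref_panel")
}

#' Subsample a reference panel to at most H_max haplotypes
#'
#' @param panel a [ref_panel]; @param params an [hmm_params].
#' @return The (possibly) subsampled panel; deterministic given the seed.
#' @export
subsample_panel <- function(panel, params) {
  H <- nrow(panel$haps)
  if (H <= params$max_ref_haplotypes) return(panel)
  had <- exists(".Random.seed", envir = globalenv())
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(derive_seed(params$seed, "panel_subsample"))
  keep <- sort(sample.int(H, params$max_ref_haplotypes))
  ref_panel(panel$haps[keep, , drop = FALSE], panel$str_alleles[keep],
            panel$pos, panel$focal_pos)
}

# Switch probabilities: rho between all adjacent window SNPs, plus the two
# half-gaps flanking the focal site. Haldane: r = 0.5 (1 - exp(-2 d_M)).
switch_probs <- function(panel, params) {
  H <- nrow(panel$haps)
  hald <- function(d_bp) {
    d_m <- pmax(d_bp, 0) / 1e6 * params$cM_per_mb / 100
    r <- 0.5 * (1 - exp(-2 * d_m))
    1 - exp(-4 * params$n_e * r / H)
  }
  pos <- panel$pos
  k <- sum(pos < panel$focal_pos)
  list(rho = if (length(pos) > 1L) hald(diff(pos)) else numeric(0),
       rho_left = if (k >= 1L) hald(panel$focal_pos - pos[k]) else 0,
       rho_right = if (k < length(pos)) hald(pos[k + 1L] - panel$focal_pos) else 0,
       k = k)
}

# Group a state posterior by the STR allele each haplotype carries.
allele_posterior <- function(state_post, str_alleles) {
  agg <- rowsum(state_post, str_alleles)
  stats::setNames(as.numeric(agg), rownames(agg))
}

#' Haploid Li-Stephens imputation
#'
#' Forward-backward posterior over reference haplotypes at the focal
#' position for one phased target haplotype; the STR allele posterior sums
#' state posteriors by carried allele.
#'
#' @param panel a [ref_panel].
#' @param target_hap target haplotype over the window SNPs (`{0,1}`, `NA`
#'   missing).
#' @param params an [hmm_params].
#' @return List: `allele_post` (named, sums to 1), `state_post`.
#' @export
ls_impute_haploid <- function(panel, target_hap, params = hmm_params()) {
  if (ncol(panel$haps) == 0L)
    stop_msg("refusing to impute from an empty SNP window")
  if (all(is.na(target_hap)))
    warning("target haplotype all-missing; posterior falls back to the panel prior")
  sw <- switch_probs(panel, params)
  post <- .ls_fb_focal_cpp(panel$haps, as.integer(target_hap), sw$rho,
                           sw$rho_left, sw$rho_right, sw$k,
                           params$error_rate)
  list(allele_post = allele_posterior(post, panel$str_alleles),
       state_post = as.numeric(post))
}

# Best unordered genotype from two per-copy allele posteriors.
# Tie-break: lexicographically smallest pair by bp length.
best_genotype <- function(p1, p2) {
  alle <- as.integer(names(p1))
  A <- length(alle)
  joint <- outer(p1, p2) + outer(p2, p1)   # unordered: both orders
  diag(joint) <- diag(outer(p1, p2))
  best <- which(joint == max(joint), arr.ind = TRUE)
  pair <- t(apply(best, 1L, function(ij) sort(alle[ij])))
  pair <- pair[order(pair[, 1L], pair[, 2L]), , drop = FALSE]
  pair[1L, ]
}

imputed_call <- function(p1, p2, locus = NA, sample = NA) {
  stopifnot(identical(names(p1), names(p2)))
  list(locus = locus, sample = sample, p1 = p1, p2 = p2,
       dosage = p1 + p2, best = best_genotype(p1, p2))
}

#' Impute a phased diploid target with two haploid runs
#'
#' @param panel a [ref_panel]; subsampled to `max_ref_haplotypes` first.
#' @param hap1,hap2 the target's two phased haplotypes over the window SNPs.
#' @param params an [hmm_params].
#' @return An imputed call: per-copy allele posteriors `p1`/`p2`, per-allele
#'   expected `dosage`, and the `best` unordered genotype (bp pair).
#' @export
ls_impute_phased <- function(panel, hap1, hap2, params = hmm_params()) {
  panel <- subsample_panel(panel, params)
  r1 <- ls_impute_haploid(panel, hap1, params)
  r2 <- ls_impute_haploid(panel, hap2, params)
  imputed_call(r1$allele_post, r2$allele_post)
}

#' Diploid Li-Stephens imputation of an unphased target
#'
#' HMM over ordered pairs of reference haplotypes; the emission compares the
#' pair's summed SNP dosage with the observed genotype (error `eps`).
#'
#' @param panel a [ref_panel]; panels larger than `max_ref_haplotypes` are
#'   subsampled (seeded).
#' @param target_geno unphased genotypes in `{0,1,2}` (`NA` missing) over
#'   the window SNPs.
#' @param params an [hmm_params].
#' @return An imputed call as in [ls_impute_phased()].
#' @export
ls_impute_diploid <- function(panel, target_geno, params = hmm_params()) {
  if (ncol(panel$haps) == 0L)
    stop_msg("refusing to impute from an empty SNP window")
  panel <- subsample_panel(panel, params)
  if (all(is.na(target_geno)))
    warning("target genotypes all-missing; posterior falls back to the panel prior")
  sw <- switch_probs(panel, params)
  post <- .ls_fb_focal_diploid_cpp(panel$haps, as.integer(target_geno),
                                   sw$rho, sw$rho_left, sw$rho_right, sw$k,
                                   params$error_rate)
  p1 <- allele_posterior(rowSums(post), panel$str_alleles)
  p2 <- allele_posterior(colSums(post), panel$str_alleles)
  out <- imputed_call(p1, p2)
  out$pair_post <- post
  out
}

#' Naive null imputer
#'
#' Every sample receives the homozygote of the most common allele (ties
#' toward the shorter allele, as in [recode_alleles()]).
#'
#' @param freqs named allele frequencies ([msat_allele_freqs()]).
#' @return The imputed genotype, an integer pair `(m, m)`.
#' @export
naive_impute <- function(freqs) {
  if (!length(freqs)) stop_msg("no allele frequencies available")
  lens <- as.integer(names(freqs))
  m <- lens[order(-freqs, lens)][1L]
  c(m, m)
}

#' Random null imputer
#'
#' Draws, for each of `n` samples, one genotype uniformly (with
#' replacement) from the list of observed non-missing genotypes, so allele
#' frequencies enter indirectly through the empirical genotype list.
#'
#' @param observed two-column matrix of observed genotypes (rows =
#'   non-missing genotypes, allele lengths in bp).
#' @param n number of genotypes to draw.
#' @return An `n` x 2 matrix of imputed genotypes.
#' @export
random_impute <- function(observed, n) {
  observed <- as.matrix(observed)
  observed <- observed[!is.na(observed[, 1L]), , drop = FALSE]
  if (!nrow(observed)) stop_msg("no observed genotypes to draw from")
  observed[sample.int(nrow(observed), n, replace = TRUE), , drop = FALSE]
}
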