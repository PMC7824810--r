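# Masking cross-validation over the window-length sweep, and the accuracy
# metrics: genotype concordance, genotype dosage (length r2), allelic
# dosage (allelic r2), allele-frequency correlation, and the naive/random
# null-model expectations.
#
# Undefined metric values (zero variance, no scored pairs) propagate as NA
# and are excluded from marker averages with counts reported -- never
# silently coerced to 0.

#' Build a 10-fold masking plan
#'
#' Default mode partitions the samples into `k` disjoint validation sets of
#' size floor(n/k) or ceiling(n/k), so every sample is imputed exactly once
#' and the whole population is covered. `method = "bootstrap"` instead
#' draws, independently per round, a random 10% (n/k) of the samples
#' without replacement within the round.
#'
#' @param sample_ids character vector of samples.
#' @param k number of folds (default 10).
#' @param seed RNG seed; the same seed yields the identical plan.
#' @param method `"partition"` (default) or `"bootstrap"`.
#' @return A list of class `fold_plan`: `validation` (list of k id vectors),
#'   `k`, `seed`, `method`.
#' @export
make_folds <- function(sample_ids, k = 10L, seed = 1L,
                       method = c("partition", "bootstrap")) {
  method <- match.arg(method)
  n <- length(sample_ids)
  if (k > n) stop_msg("k = %d folds exceed n = %d samples", k, n)
  set.seed(seed)
  validation <- if (method == "partition") {
    perm <- sample(sample_ids)
    split(perm, rep_len(seq_len(k), n)[order(seq_len(n))])  # balanced sizes
  } else {
    m <- max(1L, round(n / k))
    lapply(seq_len(k), function(i) sample(sample_ids, m))
  }
  structure(list(validation = unname(validation), k = as.integer(k),
                 seed = as.integer(seed), method = method),
            class = "fold_plan")
}

#' Per-sample genotype concordance
#'
#' Score in `{0, 0.5, 1}`: the size of the maximum multiset intersection of
#' the two unordered allele pairs, divided by 2. Either genotype missing
#' gives `NA` (excluded from averages, counted in reports).
#'
#' @param t1,t2 true allele pair(s); @param i1,i2 imputed allele pair(s).
#'   Vectors are scored elementwise.
#' @return Numeric vector of scores.
#' @export
genotype_concordance <- function(t1, t2, i1, i2) {
  # for 2-element multisets the intersection size is the better of the two
  # pairings
  m1 <- (t1 == i1) + (t2 == i2)
  m2 <- (t1 == i2) + (t2 == i1)
  pmax(m1, m2) / 2
}

#' Marker-level concordance
#'
#' @param scores per-sample scores from [genotype_concordance()].
#' @return Their mean over non-missing entries; `NA` if none scored.
#' @export
marker_concordance <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' Genotype dosage accuracy (length r2)
#'
#' The per-sample dosage is the sum of the two allele lengths (bp); the
#' metric is the squared Pearson correlation between true and imputed
#' dosage vectors (the raw correlation is also returned). Zero variance in
#' either vector gives `NA`.
#'
#' @param t1,t2,i1,i2 as in [genotype_concordance()].
#' @return List: `r2`, `r`, `n` (pairs scored).
#' @export
length_r2 <- function(t1, t2, i1, i2) {
  td <- t1 + t2; id <- i1 + i2
  ok <- !is.na(td) & !is.na(id)
  if (sum(ok) < 2L || stats::sd(td[ok]) == 0 || stats::sd(id[ok]) == 0)
    return(list(r2 = NA_real_, r = NA_real_, n = sum(ok)))
  r <- stats::cor(td[ok], id[ok])
  list(r2 = r^2, r = r, n = sum(ok))
}

#' Allelic dosage accuracy (allelic r2)
#'
#' For each allele length `a` of the locus, the per-sample copy count (0, 1
#' or 2) is compared between truth and imputation by squared Pearson
#' correlation. The marker summary is the unweighted mean over alleles with
#' a defined r2, plus the min and max.
#'
#' @param t1,t2,i1,i2 as in [genotype_concordance()].
#' @param alleles allele lengths to evaluate; defaults to those observed in
#'   the truth.
#' @return List: `per_allele` (named vector), `mean`, `min`, `max`,
#'   `n_defined`, `n_undefined`.
#' @export
allelic_r2 <- function(t1, t2, i1, i2, alleles = NULL) {
  ok <- !is.na(t1) & !is.na(i1)
  t1 <- t1[ok]; t2 <- t2[ok]; i1 <- i1[ok]; i2 <- i2[ok]
  if (is.null(alleles)) alleles <- sort(unique(c(t1, t2)))
  per <- vapply(alleles, function(a) {
    tc <- (t1 == a) + (t2 == a)
    ic <- (i1 == a) + (i2 == a)
    if (length(tc) < 2L || stats::sd(tc) == 0 || stats::sd(ic) == 0)
      return(NA_real_)
    stats::cor(tc, ic)^2
  }, 0)
  names(per) <- alleles
  def <- per[!is.na(per)]
  list(per_allele = per,
       mean = if (length(def)) mean(def) else NA_real_,
       min = if (length(def)) min(def) else NA_real_,
       max = if (length(def)) max(def) else NA_real_,
       n_defined = length(def), n_undefined = sum(is.na(per)))
}

#' Correlation between true and imputed allele frequencies
#'
#' @param freq_true,freq_imp named frequency vectors (names = allele length
#'   bp); the union of alleles is used, absent alleles count 0.
#' @return Pearson correlation `r`, or `NA` with fewer than 2 distinct
#'   alleles or zero variance.
#' @export
allele_freq_correlation <- function(freq_true, freq_imp) {
  alle <- union(names(freq_true), names(freq_imp))
  if (length(alle) < 2L) return(NA_real_)
  x <- ifelse(alle %in% names(freq_true), freq_true[alle], 0)
  y <- ifelse(alle %in% names(freq_imp), freq_imp[alle], 0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Null-model concordance expectations
#'
#' For the naive imputer (most-common-allele homozygote) the expected
#' concordance is exactly the empirical frequency of the most common allele
#' (each genotype contributes copies-of-m / 2). For the random imputer it
#' is the double sum over empirical genotype frequencies of the pairwise
#' concordance.
#'
#' @param genotypes two-column matrix of observed genotypes (allele lengths,
#'   bp; rows with `NA` are dropped).
#' @return List: `naive`, `random`.
#' @export
null_expectations <- function(genotypes) {
  g <- as.matrix(genotypes)
  g <- g[!is.na(g[, 1L]) & !is.na(g[, 2L]), , drop = FALSE]
  if (!nrow(g)) stop_msg("no observed genotypes")
  freqs <- table(c(g[, 1L], g[, 2L])) / (2 * nrow(g))
  lens <- as.integer(names(freqs))
  m <- lens[order(-as.numeric(freqs), lens)][1L]
  e_naive <- as.numeric(freqs[as.character(m)])
  # enumerate distinct genotypes with frequencies
  key <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  tab <- table(key) / nrow(g)
  uniq <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  ua <- matrix(as.integer(uniq), ncol = 2L)
  f <- as.numeric(tab)
  e_random <- 0
  for (a in seq_len(nrow(ua))) for (b in seq_len(nrow(ua)))
    e_random <- e_random + f[a] * f[b] *
      genotype_concordance(ua[a, 1L], ua[a, 2L], ua[b, 1L], ua[b, 2L])
  list(naive = e_naive, random = e_random)
}

#' Run the masking cross-validation sweep over window lengths
#'
#' For each window length and fold, the validation samples' microsatellite
#' genotypes are masked, a reference panel is built from the training
#' fold's haplotypes (samples with a missing observed genotype at the locus
#' are left out of the panel), every validation sample is imputed with the
#' haplotype-copying engine, and the naive/random null imputers are scored
#' on the same masked sets. Metrics are aggregated per marker and then
#' averaged over markers.
#'
#' @param cohort a `phased_cohort` ([simulate_cohort()]); the observed
#'   genotypes (`msat_obs`) are the data being masked and scored.
#' @param flank_mb vector of window flank lengths (Mb).
#' @param k folds (default 10).
#' @param seed root seed for the fold plan and the random imputer.
#' @param params an [hmm_params].
#' @param engine `"phased"` (two haploid runs on the known target phase;
#'   default) or `"diploid"` (unphased-genotype HMM over haplotype pairs).
#' @param method fold construction, see [make_folds()].
#' @param loci optional locus id subset.
#' @param verbose print per-window progress.
#' @return A `cv_report`: `per_locus` data.frame, `summary` per window
#'   length, `folds`, and the call parameters.
#' @export
run_cv_sweep <- function(cohort, flank_mb = c(0.5, 1, 2), k = 10L, seed = 1L,
                         params = hmm_params(), engine = c("phased", "diploid"),
                         method = "partition", loci = NULL, verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(cohort, "phased_cohort"))
  obs <- cohort$msat_obs %||% cohort$msat_true
  samples <- cohort$snp$samples
  n <- length(samples)
  folds <- make_folds(samples, k, derive_seed(seed, "folds"), method)
  loci_df <- cohort$loci
  if (!is.null(loci)) loci_df <- loci_df[loci_df$id %in% loci, , drop = FALSE]
  map <- cohort$snp$map
  rows <- list()
  imputed <- list()
  for (W in flank_mb) {
    impA <- impB <- matrix(NA_integer_, n, nrow(loci_df),
                           dimnames = list(samples, loci_df$id))
    for (l in seq_len(nrow(loci_df))) {
      lid <- loci_df$id[l]
      l0 <- match(lid, obs$loci$id)
      win <- suppressWarnings(select_window(loci_df[l, ], map, W))
      if (win$count == 0L) {
        warning(sprintf("locus %s skipped at %g Mb: empty window", lid, W))
        next
      }
      cols <- win$snp_idx
      imp1 <- imp2 <- nv1 <- nv2 <- rd1 <- rd2 <- rep(NA_integer_, n)
      for (f in seq_len(folds$k)) {
        val <- match(folds$validation[[f]], samples)
        train <- setdiff(seq_len(n), val)
        tr_ok <- train[!is.na(obs$a1[train, l0])]
        if (!length(tr_ok)) next
        haps <- rbind(cohort$snp$hap1[tr_ok, cols, drop = FALSE],
                      cohort$snp$hap2[tr_ok, cols, drop = FALSE])
        alle <- c(cohort$msat_true$a1[tr_ok, l0], cohort$msat_true$a2[tr_ok, l0])
        panel <- subsample_panel(
          ref_panel(haps, alle, map$pos[cols], loci_df$pos_bp[l]), params)
        for (s in val) {
          call <- if (engine == "phased")
            ls_impute_phased(panel, cohort$snp$hap1[s, cols],
                             cohort$snp$hap2[s, cols], params)
          else
            ls_impute_diploid(panel, cohort$snp$geno[s, cols], params)
          imp1[s] <- call$best[1L]; imp2[s] <- call$best[2L]
        }
        # null imputers on the same masked set, trained on the same fold
        tr_gt <- cbind(obs$a1[tr_ok, l0], obs$a2[tr_ok, l0])
        fr <- table(c(tr_gt)) / (2 * nrow(tr_gt))
        m <- naive_impute(stats::setNames(as.numeric(fr), names(fr)))
        nv1[val] <- m[1L]; nv2[val] <- m[2L]
        set.seed(derive_seed(seed, sprintf("random_%g_%s_%d", W, lid, f)))
        rg <- random_impute(tr_gt, length(val))
        rd1[val] <- rg[, 1L]; rd2[val] <- rg[, 2L]
      }
      t1 <- obs$a1[, l0]; t2 <- obs$a2[, l0]
      scored <- !is.na(t1) & !is.na(imp1)
      conc <- marker_concordance(genotype_concordance(t1, t2, imp1, imp2))
      lr <- length_r2(t1, t2, imp1, imp2)
      ar <- allelic_r2(t1, t2, imp1, imp2)
      fc <- allele_freq_correlation(
        freq_from_pairs(t1, t2), freq_from_pairs(imp1[scored], imp2[scored]))
      nulls <- null_expectations(cbind(t1, t2))
      rows[[length(rows) + 1L]] <- data.frame(
        flank_mb = W, locus = lid, chrom = loci_df$chrom[l],
        pos_bp = loci_df$pos_bp[l], snps_window = win$count,
        n_scored = sum(scored), n_missing_truth = sum(is.na(t1)),
        conc = conc, length_r2 = lr$r2, length_r = lr$r,
        allelic_r2 = ar$mean, allelic_r2_min = ar$min,
        allelic_r2_max = ar$max, n_alleles_defined = ar$n_defined,
        freq_cor = fc,
        naive_conc = marker_concordance(genotype_concordance(t1, t2, nv1, nv2)),
        random_conc = marker_concordance(genotype_concordance(t1, t2, rd1, rd2)),
        e_naive = nulls$naive, e_random = nulls$random,
        stringsAsFactors = FALSE)
      impA[, l] <- imp1; impB[, l] <- imp2
    }
    imputed[[as.character(W)]] <- msat_geno(samples, loci_df, impA, impB)
    if (verbose)
      message(sprintf("window %g Mb done (%d loci)", W, nrow(loci_df)))
  }
  per_locus <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_locus, per_locus$flank_mb),
                                   summarize_window))
  rownames(summary) <- NULL
  structure(list(per_locus = per_locus, summary = summary, folds = folds,
                 imputed = imputed, flank_mb = flank_mb, engine = engine,
                 seed = seed, hmm = params),
            class = "cv_report")
}

freq_from_pairs <- function(a1, a2) {
  v <- c(a1, a2); v <- v[!is.na(v)]
  if (!length(v)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(v)
  stats::setNames(as.numeric(tab) / length(v), names(tab))
}

summarize_window <- function(d) {
  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(flank_mb = d$flank_mb[1L],
             n_loci = nrow(d),
             snps_window = avg(d$snps_window),
             conc = avg(d$conc),
             length_r2 = avg(d$length_r2),
             allelic_r2 = avg(d$allelic_r2),
             freq_cor = avg(d$freq_cor),
             naive_conc = avg(d$naive_conc),
             random_conc = avg(d$random_conc),
             e_naive = avg(d$e_naive),
             e_random = avg(d$e_random),
             n_undefined_length_r2 = sum(is.na(d$length_r2)),
             n_undefined_allelic_r2 = sum(is.na(d$allelic_r2)))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: masking cross-validation sweep\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write per-window metric tables
#'
#' One TSV per window length mirroring the standard per-marker metric table
#' (CHR, Position, Microsatellite, Conc., GD, AD, Min AD, Max AD, Naive
#' Conc., Random Conc.) plus a sweep summary TSV.
#'
#' @param report a `cv_report`; @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_metrics_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (W in unique(report$per_locus$flank_mb)) {
    d <- report$per_locus[report$per_locus$flank_mb == W, ]
    out <- data.frame(CHR = d$chrom, Position = d$pos_bp,
                      Microsatellite = d$locus,
                      Conc. = round(d$conc, 2), GD = round(d$length_r2, 2),
                      AD = round(d$allelic_r2, 2),
                      `Min AD` = round(d$allelic_r2_min, 2),
                      `Max AD` = round(d$allelic_r2_max, 2),
                      `Naive Conc.` = round(d$naive_conc, 2),
                      `Random Conc.` = round(d$random_conc, 2),
                      check.names = FALSE)
    p <- file.path(dir, sprintf("metrics_%gMb.tsv", W))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "sweep_summary.tsv")
  utils::write.table(report$summary, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p))
}
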