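test_that("fold plans partition the cohort with balanced sizes", {
  ids <- sprintf("S%03d", 1:100)
  fp <- make_folds(ids, 10, seed = 4)
  expect_length(fp$validation, 10L)
  expect_true(all(lengths(fp$validation) == 10L))
  expect_setequal(unlist(fp$validation), ids)          # disjoint cover
  fp2 <- make_folds(ids, 10, seed = 4)
  expect_identical(fp$validation, fp2$validation)      # same seed, same plan

  fp95 <- make_folds(ids[1:95], 10, seed = 1)
  expect_equal(sort(lengths(fp95$validation)), rep(c(9L, 10L), each = 5))
  expect_setequal(unlist(fp95$validation), ids[1:95])

  boot <- make_folds(ids, 10, seed = 2, method = "bootstrap")
  expect_true(all(lengths(boot$validation) == 10L))
  expect_true(all(unlist(lapply(boot$validation, anyDuplicated)) == 0L))
  expect_error(make_folds(ids[1:5], 10), "exceed")
})

test_that("genotype concordance is the multiset intersection over two", {
  expect_equal(genotype_concordance(1, 2, 2, 1), 1)     # unordered
  expect_equal(genotype_concordance(1, 2, 3, 4), 0)
  expect_equal(genotype_concordance(1, 1, 1, 2), 0.5)   # copy-aware
  expect_equal(genotype_concordance(1, 2, 1, 1), 0.5)
  expect_equal(genotype_concordance(1, 1, 2, 2), 0)
  # vectorized and NA-propagating
  expect_equal(genotype_concordance(c(1, NA), c(2, NA), c(1, 1), c(2, 1)),
               c(1, NA))
  expect_equal(marker_concordance(c(1, 0.5, 0)), 0.5)
  expect_equal(marker_concordance(rep(1, 5)), 1)
  expect_true(is.na(marker_concordance(NA_real_)))
})

test_that("length r2 is the squared Pearson correlation of allele-length sums", {
  t1 <- c(104L, 106L, 110L, 104L); t2 <- c(104L, 108L, 110L, 104L)
  expect_equal(length_r2(t1, t2, t1, t2)$r2, 1)
  expect_true(is.na(length_r2(t1, t2, rep(104L, 4), rep(104L, 4))$r2))
  # dosage sums (208, 214, 220, 208) vs (208, 214, 214, 208): r2 = 9/11
  i2 <- c(104L, 108L, 104L, 104L)
  res <- length_r2(t1, t2, t1, i2)
  expect_equal(res$r2, 9 / 11)
  expect_equal(res$n, 4L)
})

test_that("allelic r2 summarizes per-allele copy-count correlations", {
  t1 <- c(1L, 1L, 2L, 3L, 1L); t2 <- c(1L, 2L, 3L, 3L, 3L)
  expect_equal(allelic_r2(t1, t2, t1, t2)$mean, 1)
  # allele 2 systematically imputed as allele 1
  i1 <- c(1L, 1L, 1L, 3L, 1L); i2 <- c(1L, 1L, 3L, 3L, 3L)
  res <- allelic_r2(t1, t2, i1, i2)
  expect_equal(unname(res$per_allele["1"]), 121 / 196)  # hand Pearson
  expect_true(is.na(res$per_allele["2"]))               # zero imputed variance
  expect_equal(unname(res$per_allele["3"]), 1)
  expect_equal(res$mean, (121 / 196 + 1) / 2)
  expect_equal(res$n_defined, 2L)
  expect_lt(res$mean, 1)
  # marker mean lies within [min, max]
  expect_gte(res$mean, res$min)
  expect_lte(res$mean, res$max)
})

test_that("allele-frequency correlation compares aligned frequency vectors", {
  f <- c(`100` = 0.5, `102` = 0.3, `104` = 0.2)
  expect_equal(allele_freq_correlation(f, f), 1)
  g <- c(`100` = 0.48, `102` = 0.33, `104` = 0.19)
  expect_equal(allele_freq_correlation(f, g), 0.985547590187474)
  # a degenerate naive-style frequency vector correlates below 1
  naive <- c(`100` = 1)
  expect_lt(allele_freq_correlation(f, naive), 1)
  expect_true(is.na(allele_freq_correlation(c(`100` = 1), c(`100` = 1))))
})

test_that("null expectations: closed form for naive, enumeration for random", {
  mono <- cbind(rep(100L, 5), rep(100L, 5))
  e <- null_expectations(mono)
  expect_equal(e$naive, 1)
  expect_equal(e$random, 1)
  # equally frequent (a,a), (a,b), (b,b): naive 0.5, random 5/9
  g <- cbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  e2 <- null_expectations(g)
  expect_equal(e2$naive, 0.5)
  expect_equal(e2$random, 5 / 9)
})

test_that("the naive expectation equals the most-common-allele frequency exactly", {
  set.seed(42)
  for (i in 1:100) {
    alle <- sample(100:140, sample(2:8, 1))
    g <- random_genotype_matrix(sample(5:60, 1), alle)
    e <- null_expectations(g)
    expect_equal(e$naive, oracle_naive_expectation(g), tolerance = 1e-12)
    expect_equal(e$random, oracle_random_expectation(g), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo null imputers converge to the analytic expectations", {
  set.seed(9)
  g <- random_genotype_matrix(40, c(100L, 102L, 104L, 110L))
  e <- null_expectations(g)
  freqs <- table(c(g)) / (2 * nrow(g))
  n_draw <- 10000L
  idx <- sample.int(nrow(g), n_draw, replace = TRUE)
  nv <- naive_impute(stats::setNames(as.numeric(freqs), names(freqs)))
  c_naive <- marker_concordance(genotype_concordance(
    g[idx, 1], g[idx, 2], rep(nv[1], n_draw), rep(nv[2], n_draw)))
  rd <- random_impute(g, n_draw)
  c_random <- marker_concordance(genotype_concordance(
    g[idx, 1], g[idx, 2], rd[, 1], rd[, 2]))
  expect_lt(abs(c_naive - e$naive), 0.01)
  expect_lt(abs(c_random - e$random), 0.015)
})

test_that("metrics are invariant under allele recoding (they use bp lengths)", {
  set.seed(3)
  t1 <- sample(c(100L, 102L, 104L), 30, TRUE)
  t2 <- sample(c(100L, 102L, 104L), 30, TRUE)
  i1 <- sample(c(100L, 102L, 104L), 30, TRUE)
  i2 <- sample(c(100L, 102L, 104L), 30, TRUE)
  shift <- function(x) x + 0L  # recoding to codes must not be needed at all
  expect_equal(marker_concordance(genotype_concordance(t1, t2, i1, i2)),
               marker_concordance(genotype_concordance(shift(t1), shift(t2),
                                                       shift(i1), shift(i2))))
  expect_equal(allelic_r2(t1, t2, i1, i2)$mean,
               allelic_r2(t2, t1, i2, i1)$mean)  # pair order irrelevant
})

test_that("the CV sweep reaches perfect concordance in the perfect-LD regime", {
  co <- simulate_cohort(perfect_ld_params(n_lineages = 6L))
  rep <- run_cv_sweep(co, flank_mb = 2, k = 5, seed = 2,
                      params = hmm_params(max_ref_haplotypes = 500L))
  expect_equal(rep$summary$conc, 1.0)
  expect_equal(rep$summary$length_r2, 1.0)
  expect_equal(rep$summary$freq_cor, 1.0)
  # the copying imputer beats both null expectations
  expect_gt(rep$summary$conc, rep$summary$e_naive)
  expect_gt(rep$summary$conc, rep$summary$e_random)
})

test_that("wider windows do not hurt accuracy on informative cohorts", {
  concs <- sapply(1:3, function(s) {
    co <- simulate_cohort(tiny_params(n_founders = 60L,
                                      offspring_per_generation = 60L,
                                      str_mutation_rate = 1e-3,
                                      n_lineages = 12L, seed = s))
    rep <- run_cv_sweep(co, flank_mb = c(0.5, 2), k = 5, seed = s)
    rep$summary$conc
  })
  # mean over seeds: accuracy at 0.5 Mb <= accuracy at 2 Mb
  expect_lte(mean(concs[1, ]), mean(concs[2, ]) + 1e-9)
})

test_that("imputation never reads the validation sample's own genotype (canary)", {
  co <- simulate_cohort(tiny_params(n_str_loci = 2L))
  rep1 <- run_cv_sweep(co, flank_mb = 2, k = 5, seed = 6)
  poisoned <- co
  victim <- rep1$folds$validation[[1]][1]
  vi <- match(victim, co$msat_obs$samples)
  poisoned$msat_obs$a1[vi, 1] <- poisoned$msat_obs$a2[vi, 1] <- 9999L
  poisoned$msat_true$a1[vi, 1] <- poisoned$msat_true$a2[vi, 1] <- 9999L
  rep2 <- run_cv_sweep(poisoned, flank_mb = 2, k = 5, seed = 6)
  # the poisoned sample's imputed genotype is untouched by its own truth
  expect_equal(rep2$imputed[["2"]]$a1[vi, 1], rep1$imputed[["2"]]$a1[vi, 1])
  expect_equal(rep2$imputed[["2"]]$a2[vi, 1], rep1$imputed[["2"]]$a2[vi, 1])
})

test_that("metric tables are written in the per-marker report shape", {
  co <- simulate_cohort(tiny_params(n_str_loci = 2L))
  rep <- run_cv_sweep(co, flank_mb = c(1, 2), k = 5, seed = 2)
  dir <- withr::local_tempdir()
  write_metrics_tables(rep, dir)
  tab <- utils::read.table(file.path(dir, "metrics_2Mb.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  expect_equal(names(tab), c("CHR", "Position", "Microsatellite", "Conc.",
                             "GD", "AD", "Min AD", "Max AD", "Naive Conc.",
                             "Random Conc."))
  expect_equal(nrow(tab), 2L)
  expect_true(file.exists(file.path(dir, "metrics_1Mb.tsv")))
  expect_true(file.exists(file.path(dir, "sweep_summary.tsv")))
})
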