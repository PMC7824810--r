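test_that("a single-haplotype panel yields a degenerate posterior", {
  panel <- ref_panel(matrix(c(0L, 1L, 0L), 1), 110L,
                     c(1e6, 2e6, 3e6), 2.5e6)
  res <- ls_impute_haploid(panel, c(0L, 1L, 0L))
  expect_equal(res$allele_post, c(`110` = 1))
})

test_that("a tag SNP in perfect LD concentrates the posterior on the tagged allele", {
  panel <- tag_snp_panel()
  res0 <- ls_impute_haploid(panel, c(0L, 0L, 0L, 0L, 0L))
  res1 <- ls_impute_haploid(panel, c(0L, 0L, 1L, 0L, 0L))
  expect_gt(res0$allele_post["110"], 0.99)
  expect_gt(res1$allele_post["120"], 0.99)
})

test_that("haploid forward-backward matches the exhaustive path-sum oracle", {
  set.seed(2024)
  params <- hmm_params()
  for (case in 1:40) {
    H <- sample(2:5, 1); S <- sample(1:4, 1)
    ref <- matrix(rbinom(H * S, 1, 0.5), H, S)
    pos <- sort(sample(1e6:9e6, S))
    focal <- runif(1, 5e5, 9.5e6)
    panel <- ref_panel(ref, sample(c(100L, 102L, 104L), H, replace = TRUE),
                       pos, focal)
    target <- rbinom(S, 1, 0.5)
    target[runif(S) < 0.2] <- NA  # some missing sites (possibly all of them)
    res <- suppressWarnings(ls_impute_haploid(panel, target, params))
    sw <- msatimpute:::switch_probs(panel, params)
    oracle <- oracle_ls_posterior(ref, target, sw$rho, sw$rho_left,
                                  sw$rho_right, sw$k, params$error_rate)
    expect_lt(max(abs(res$state_post - oracle)), 1e-10)
    expect_equal(sum(res$state_post), 1, tolerance = 1e-9)
    expect_true(all(res$state_post >= 0))
  }
})

test_that("the diploid chain matches two haploid runs in the factorizing regime", {
  # perfect LD, phase-unambiguous targets, eps small: the pair posterior
  # factorizes over copies
  panel <- tag_snp_panel(n_per_group = 3L)
  params <- hmm_params(error_rate = 1e-6)
  hap_a <- c(0L, 0L, 0L, 0L, 0L)  # carries 110
  hap_b <- c(0L, 0L, 1L, 0L, 0L)  # carries 120
  dip <- ls_impute_diploid(panel, hap_a + hap_b, params)
  hp <- ls_impute_phased(panel, hap_a, hap_b, params)
  expect_equal(sort(dip$best), sort(hp$best))
  expect_equal(sort(dip$best), c(110L, 120L))
  joint <- sort(dip$p1 + dip$p2, decreasing = TRUE)
  expect_equal(unname(joint[1] + joint[2]), 2, tolerance = 1e-4)
  # homozygous target in perfect LD: the haplotype's allele, twice
  dip0 <- ls_impute_diploid(panel, hap_a + hap_a, params)
  expect_equal(dip0$best, c(110L, 110L))
})

test_that("an uninformative panel returns the panel allele frequencies", {
  ref <- matrix(0L, 6, 4)  # all SNPs monomorphic
  alle <- c(100L, 100L, 100L, 102L, 102L, 104L)
  panel <- ref_panel(ref, alle, c(1e6, 2e6, 3e6, 4e6), 2.5e6)
  res <- ls_impute_haploid(panel, c(0L, 0L, 0L, 0L))
  expect_equal(res$allele_post,
               c(`100` = 0.5, `102` = 1 / 3, `104` = 1 / 6))
  dip <- ls_impute_diploid(panel, c(0L, 0L, 0L, 0L))
  expect_equal(dip$p1, c(`100` = 0.5, `102` = 1 / 3, `104` = 1 / 6),
               tolerance = 1e-9)
})

test_that("degenerate inputs are refused or flagged", {
  empty <- ref_panel(matrix(integer(0), 2, 0), c(100L, 102L), numeric(0), 1e6)
  expect_error(ls_impute_haploid(empty, integer(0)), "empty SNP window")
  panel <- tag_snp_panel()
  expect_warning(res <- ls_impute_haploid(panel, rep(NA_integer_, 5)),
                 "all-missing")
  expect_equal(unname(res$allele_post), c(0.5, 0.5))
  expect_error(ref_panel(matrix(0L, 2, 2), 100L, c(1, 2), 1.5),
               "one STR allele per")
})

test_that("oversized panels are subsampled deterministically", {
  set.seed(5)
  H <- 300L
  ref <- matrix(rbinom(H * 3, 1, 0.5), H, 3)
  panel <- ref_panel(ref, sample(c(100L, 102L), H, TRUE), c(1e6, 2e6, 3e6), 1.5e6)
  params <- hmm_params(max_ref_haplotypes = 50L, seed = 9L)
  a <- subsample_panel(panel, params)
  b <- subsample_panel(panel, params)
  expect_equal(nrow(a$haps), 50L)
  expect_identical(a$haps, b$haps)
  expect_identical(a$str_alleles, b$str_alleles)
})

test_that("the naive imputer returns the most-common-allele homozygote", {
  expect_equal(naive_impute(c(`104` = 0.6, `110` = 0.4)), c(104L, 104L))
  expect_equal(naive_impute(c(`110` = 0.5, `104` = 0.5)), c(104L, 104L))
  expect_error(naive_impute(numeric(0)), "no allele frequencies")
})

test_that("the random imputer draws from the empirical genotype list", {
  obs <- cbind(c(104L, 104L, 110L), c(110L, 104L, 110L))
  set.seed(7)
  a <- random_impute(obs, 100L)
  set.seed(7)
  b <- random_impute(obs, 100L)
  expect_identical(a, b)
  drawn <- unique(paste(a[, 1], a[, 2]))
  expect_true(all(drawn %in% paste(obs[, 1], obs[, 2])))
  one <- random_impute(cbind(104L, 110L), 5L)
  expect_true(all(one[, 1] == 104L & one[, 2] == 110L))
  expect_error(random_impute(cbind(NA_integer_, NA_integer_), 1L),
               "no observed genotypes")
})

test_that("best-genotype ties break toward the shortest allele pair", {
  p <- c(`100` = 0.5, `102` = 0.5)
  expect_equal(msatimpute:::best_genotype(p, p), c(100L, 102L))
  # exact tie between (100,100) and (100,102): lexicographically smallest wins
  expect_equal(msatimpute:::best_genotype(p, c(`100` = 1, `102` = 0)),
               c(100L, 100L))
  q <- c(`100` = 1, `102` = 0)
  expect_equal(msatimpute:::best_genotype(q, q), c(100L, 100L))
})
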