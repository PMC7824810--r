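test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(tiny_params(genotyping_missing_rate = 0.05,
                                   misassignment_rate = 0.05))
  b <- simulate_cohort(tiny_params(genotyping_missing_rate = 0.05,
                                   misassignment_rate = 0.05))
  expect_identical(a$snp$hap1, b$snp$hap1)
  expect_identical(a$msat_true$a1, b$msat_true$a1)
  expect_identical(a$msat_obs$a1, b$msat_obs$a1)
  expect_identical(a$pedigree_recorded, b$pedigree_recorded)
  c <- simulate_cohort(tiny_params(seed = 99L))
  expect_false(identical(a$snp$hap1, c$snp$hap1))
})

test_that("a single ancestral lineage gives identical founders and monomorphic loci", {
  co <- simulate_cohort(tiny_params(n_lineages = 1L))
  founders <- co$pedigree_true$id[co$pedigree_true$gen == 0]
  idx <- match(founders, co$snp$samples)
  expect_true(all(co$snp$hap1[idx, ] == rep(co$snp$hap1[idx[1], ],
                                            each = length(idx))))
  # mutation off: every locus monomorphic across all generations
  for (l in seq_len(nrow(co$loci)))
    expect_length(unique(c(co$msat_true$a1[, l], co$msat_true$a2[, l])), 1L)
})

test_that("founding allele count is capped by the lineage count (pigeonhole)", {
  sc <- make_ancestral_haplotypes(tiny_params(n_lineages = 20L,
                                              str_allele_counts = 25L))
  expect_lte(max(apply(sc$founding_allele, 2, function(x) length(unique(x)))),
             20L)
  # and with mutation off, no run can ever exceed K distinct alleles
  co <- simulate_cohort(tiny_params(n_lineages = 5L, str_allele_counts = 25L))
  for (l in seq_len(nrow(co$loci)))
    expect_lte(length(unique(c(co$msat_true$a1[, l], co$msat_true$a2[, l]))), 5L)
})

test_that("without recombination each gamete equals one parental haplotype", {
  co <- simulate_cohort(tiny_params(recomb_rate_cM_per_mb = 0))
  ped <- co$pedigree_true
  kids <- which(!is.na(ped$sire))
  for (i in kids[seq_len(min(10, length(kids)))]) {
    r <- match(ped$sire[i], co$snp$samples)
    for (l in seq_len(nrow(co$loci))) {
      cols <- which(co$snp$map$chrom == co$loci$chrom[l])
      kid <- co$snp$hap1[i, cols]
      expect_true(identical(kid, co$snp$hap1[r, cols]) ||
                    identical(kid, co$snp$hap2[r, cols]))
    }
  }
})

test_that("without mutation every offspring STR allele exists in its parents", {
  co <- simulate_cohort(tiny_params())
  ped <- co$pedigree_true
  kids <- which(!is.na(ped$sire))
  si <- match(ped$sire[kids], co$snp$samples)
  di <- match(ped$dam[kids], co$snp$samples)
  for (l in seq_len(nrow(co$loci))) {
    from_sire <- co$msat_true$a1[kids, l] == co$msat_true$a1[si, l] |
      co$msat_true$a1[kids, l] == co$msat_true$a2[si, l]
    from_dam <- co$msat_true$a2[kids, l] == co$msat_true$a1[di, l] |
      co$msat_true$a2[kids, l] == co$msat_true$a2[di, l]
    expect_true(all(from_sire) && all(from_dam))
  }
})

test_that("crossover counts follow the Haldane Poisson mean", {
  # 100 Mb at 1 cM/Mb: Poisson(1) crossovers per meiosis
  set.seed(123)
  pos <- sort(runif(50, 1, 1e8))
  hA <- rep(0L, 50); hB <- rep(1L, 50)
  n <- 10000L
  counts <- vapply(seq_len(n), function(i)
    meiosis_gamete(hA, hB, pos, 1e8, 1)$n_cross, 0L)
  expect_lt(abs(mean(counts) - 1.0), 0.05)  # 5 sd of the Monte-Carlo mean
  expect_lt(abs(var(counts) - 1.0), 0.15)   # Poisson: variance equals mean
})

test_that("STR alleles are tagged by their local ancestral lineage (perfect-LD regime)", {
  p <- tiny_params()
  sc <- make_ancestral_haplotypes(p)
  co <- drop_gametes(sim_pedigree(p), sc)
  for (l in seq_len(nrow(co$loci))) {
    expect_equal(unname(co$msat_true$a1[, l]),
                 unname(sc$founding_allele[co$lineage1[, l], l]))
    expect_equal(unname(co$msat_true$a2[, l]),
                 unname(sc$founding_allele[co$lineage2[, l], l]))
  }
})

test_that("founder SNP frequencies converge to the lineage-mixture expectation", {
  p <- sim_params(n_founders = 2000L, n_generations = 1L, n_str_loci = 4L,
                  seed = 3L)
  sc <- make_ancestral_haplotypes(p)
  co <- drop_gametes(sim_pedigree(p), sc)
  founder_freq <- colMeans(rbind(co$snp$hap1, co$snp$hap2))
  mixture <- colMeans(sc$anc_hap)  # uniform lineage weights
  expect_lt(max(abs(founder_freq - mixture)), 0.05)
})

test_that("realized SNP counts per window match the Poisson expectation", {
  sc <- make_ancestral_haplotypes(sim_params())
  counts <- vapply(seq_len(nrow(sc$loci)), function(l)
    select_window(sc$loci[l, ], sc$map, 2)$count, 0L)
  # E[count] = 2 * W * density = 76; mean over 19 loci, Poisson spread
  expect_lt(abs(mean(counts) - 76), 10)
})

test_that("misassignment injection rewires the recorded pedigree only", {
  co0 <- simulate_cohort(tiny_params())
  expect_identical(co0$pedigree_recorded$sire, co0$pedigree_true$sire)
  expect_equal(nrow(co0$misassigned), 0L)

  p <- sim_params(n_founders = 200L, n_generations = 4L,
                  offspring_per_generation = 200L, n_sires = 10L,
                  n_str_loci = 2L, misassignment_rate = 0.0166,
                  genotyping_missing_rate = 0.1, seed = 21L)
  co <- simulate_cohort(p)
  n_links <- sum(!is.na(co$pedigree_true$sire)) +
    sum(!is.na(co$pedigree_true$dam))
  n_mis <- nrow(co$misassigned)
  # ~1.66% of links in expectation (e.g. ~24 of 1450); binomial 3-sigma band
  expect_lt(abs(n_mis - 0.0166 * n_links),
            3 * sqrt(n_links * 0.0166 * 0.9834) + 1)
  # rewired links differ from truth; all others match
  for (r in seq_len(min(10L, n_mis))) {
    m <- co$misassigned[r, ]
    expect_false(m$recorded_parent == m$true_parent)
    expect_equal(co$pedigree_recorded[[m$role]][
      match(m$offspring, co$pedigree_recorded$id)], m$recorded_parent)
  }
  # masked genotypes are missing in the observed copy, intact in the truth
  masked <- is.na(co$msat_obs$a1) & !is.na(co$msat_true$a1)
  expect_gt(sum(masked), 0)
  expect_false(anyNA(co$msat_true$a1))
})
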