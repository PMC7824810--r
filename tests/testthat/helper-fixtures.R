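# Shared fixtures and independent oracles.

# Small, fast simulation profiles -----------------------------------------

tiny_params <- function(...) {
  defaults <- list(n_founders = 40L, n_generations = 3L,
                   offspring_per_generation = 40L, n_sires = 5L,
                   n_lineages = 8L, chrom_length_mb = 6, n_str_loci = 3L,
                   str_mutation_rate = 0, genotyping_missing_rate = 0,
                   misassignment_rate = 0, seed = 11L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# Haplotype-block world: no recombination, no founder mosaic switching, no
# mutation -- every haplotype is one intact ancestral lineage, so the STR
# allele is perfectly determined by the flanking SNPs.
perfect_ld_params <- function(...) {
  tiny_params(recomb_rate_cM_per_mb = 0, founder_switch_per_mb = 0,
              str_mutation_rate = 0, ...)
}

# Exhaustive path-sum oracle for the haploid copying model ------------------
#
# Enumerates every state path over the chain of window SNPs with the silent
# focal site inserted after the first k SNPs, multiplying explicit
# transition-matrix entries and emissions. Independent of the
# forward-backward recursion it checks.
oracle_ls_posterior <- function(ref, target, rho, rho_left, rho_right, k, eps) {
  H <- nrow(ref); S <- ncol(ref)
  sites <- S + 1L
  Tm <- function(r) (1 - r) * diag(H) + r / H
  rhos <- c(if (k > 1L) rho[seq_len(k - 1L)],
            if (k > 0L) rho_left,
            if (k < S) rho_right,
            if (k < S && S - k > 1L) rho[(k + 1L):(S - 1L)])
  snp_of_site <- append(seq_len(S), NA_integer_, after = k)
  emis <- matrix(1, H, sites)
  for (s in seq_len(sites)) {
    j <- snp_of_site[s]
    if (!is.na(j) && !is.na(target[j]))
      emis[, s] <- ifelse(ref[, j] == target[j], 1 - eps, eps)
  }
  Ts <- lapply(rhos, Tm)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), sites)))
  post <- numeric(H)
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    p <- (1 / H) * emis[pth[1L], 1L]
    if (sites > 1L)
      for (s in 2:sites)
        p <- p * Ts[[s - 1L]][pth[s - 1L], pth[s]] * emis[pth[s], s]
    post[pth[k + 1L]] <- post[pth[k + 1L]] + p
  }
  post / sum(post)
}

# Random-imputer expectation by exhaustive pair enumeration over the
# observed genotype list (the random imputer draws uniformly from it).
oracle_random_expectation <- function(genotypes) {
  g <- as.matrix(genotypes)
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  n <- nrow(g)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    total <- total + genotype_concordance(g[i, 1L], g[i, 2L], g[j, 1L], g[j, 2L])
  total / n^2
}

# Most-common-allele frequency computed the long way: mean over genotypes of
# copies-of-m / 2 (the analytic identity the naive expectation relies on).
oracle_naive_expectation <- function(genotypes) {
  g <- as.matrix(genotypes)
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  freqs <- table(c(g)) / (2 * nrow(g))
  lens <- as.integer(names(freqs))
  m <- lens[order(-as.numeric(freqs), lens)][1L]
  mean(((g[, 1L] == m) + (g[, 2L] == m)) / 2)
}

# A hand-buildable reference panel where one tag SNP determines the STR
# allele (perfect LD).
tag_snp_panel <- function(n_per_group = 4L, n_snps = 5L, tag = 3L,
                          alleles = c(110L, 120L)) {
  base <- matrix(0L, 2L * n_per_group, n_snps)
  base[seq_len(n_per_group), tag] <- 0L
  base[n_per_group + seq_len(n_per_group), tag] <- 1L
  pos <- seq(1e6, by = 1e4, length.out = n_snps)  # tight map: low switch rate
  ref_panel(base, rep(alleles, each = n_per_group), pos,
            focal_pos = pos[tag] + 5e3)
}

random_genotype_matrix <- function(n, alleles) {
  cbind(sample(alleles, n, replace = TRUE), sample(alleles, n, replace = TRUE))
}
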