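# Pedigreed cohort simulator with linked STR + SNP variation.
#
# The generator follows a founder-mosaic model: K ancestral haplotype
# lineages are simulated once per run; every founder haplotype is a coarse
# mosaic of those lineages, and each lineage carries one founding STR allele
# per locus. STR alleles are therefore tagged by their flanking haplotype
# background -- exactly the LD that haplotype-copying imputation exploits.
# Gene dropping through a discrete-generation pedigree uses Haldane
# crossovers (Poisson, no interference) and a stepwise mutation model for
# the STRs.

# Allele-count spectrum and ladder starts of the 19-marker ISAG ovine
# parentage panel (used as the default simulated locus spectrum).
.isag_allele_counts <- c(13L, 9L, 14L, 14L, 6L, 11L, 12L, 8L, 2L, 8L, 19L,
                         18L, 12L, 9L, 16L, 25L, 17L, 17L, 12L)
.isag_base_lengths <- c(104L, 134L, 194L, 87L, 135L, 126L, 190L, 268L, 168L,
                        81L, 205L, 167L, 237L, 119L, 183L, 76L, 263L, 146L,
                        126L)

#' Simulation parameters for the synthetic cohort
#'
#' Defaults emulate a commercial dairy-sheep breeding nucleus genotyped on a
#' medium-density chip: 19 independent STR loci (one per 10-Mb chromosome,
#' locus at the midpoint) with the allele-count spectrum of the ISAG ovine
#' parentage panel, SNP density 19 per Mb, four discrete generations of 500
#' individuals with ram-heavy mating (25 sires per generation), stepwise STR
#' mutation at 1e-3 per meiosis, and a 1.66% rate of injected pedigree
#' misassignments.
#'
#' @param n_founders founders in generation 0.
#' @param n_generations total discrete generations (founders included).
#' @param offspring_per_generation individuals born per later generation.
#' @param n_sires breeding males used per generation.
#' @param n_lineages K, number of ancestral haplotype lineages.
#' @param chrom_length_mb chromosome length (Mb); one chromosome per STR locus.
#' @param snp_density_per_mb expected SNPs per Mb (Poisson placement).
#' @param n_str_loci number of STR loci (= chromosomes).
#' @param str_allele_counts founding allele count requested per locus
#'   (recycled/truncated to `n_str_loci`).
#' @param str_base_lengths shortest allele length (bp) per locus.
#' @param str_motif_bp repeat-unit size (bp); stepwise mutations move one unit.
#' @param str_mutation_rate stepwise mutation probability per meiosis.
#' @param recomb_rate_cM_per_mb genetic map density (Haldane, no interference).
#' @param founder_switch_per_mb lineage-switch rate of the founder mosaic
#'   (controls LD decay between STR alleles and flanking SNPs).
#' @param genotyping_missing_rate probability a recorded STR genotype is
#'   masked to missing (whole-genotype).
#' @param misassignment_rate fraction of recorded parent links rewired to a
#'   wrong parent.
#' @param seed root seed; all stages derive named substreams from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_founders = 500L,
                       n_generations = 4L,
                       offspring_per_generation = n_founders,
                       n_sires = 25L,
                       n_lineages = 20L,
                       chrom_length_mb = 10,
                       snp_density_per_mb = 19,
                       n_str_loci = 19L,
                       str_allele_counts = NULL,
                       str_base_lengths = NULL,
                       str_motif_bp = 2L,
                       str_mutation_rate = 1e-3,
                       recomb_rate_cM_per_mb = 1,
                       founder_switch_per_mb = 0.05,
                       genotyping_missing_rate = 0.02,
                       misassignment_rate = 0.0166,
                       seed = 42L) {
  if (is.null(str_allele_counts))
    str_allele_counts <- rep_len(.isag_allele_counts, n_str_loci)
  else str_allele_counts <- rep_len(as.integer(str_allele_counts), n_str_loci)
  if (is.null(str_base_lengths))
    str_base_lengths <- rep_len(.isag_base_lengths, n_str_loci)
  else str_base_lengths <- rep_len(as.integer(str_base_lengths), n_str_loci)
  p <- list(n_founders = as.integer(n_founders),
            n_generations = as.integer(n_generations),
            offspring_per_generation = as.integer(offspring_per_generation),
            n_sires = as.integer(n_sires),
            n_lineages = as.integer(n_lineages),
            chrom_length_mb = chrom_length_mb,
            snp_density_per_mb = snp_density_per_mb,
            n_str_loci = as.integer(n_str_loci),
            str_allele_counts = str_allele_counts,
            str_base_lengths = str_base_lengths,
            str_motif_bp = as.integer(str_motif_bp),
            str_mutation_rate = str_mutation_rate,
            recomb_rate_cM_per_mb = recomb_rate_cM_per_mb,
            founder_switch_per_mb = founder_switch_per_mb,
            genotyping_missing_rate = genotyping_missing_rate,
            misassignment_rate = misassignment_rate,
            seed = as.integer(seed))
  rates <- c(p$str_mutation_rate, p$genotyping_missing_rate, p$misassignment_rate)
  if (any(rates < 0 | rates > 1)) stop_msg("rates must lie in [0, 1]")
  if (p$n_lineages < 1L) stop_msg("n_lineages must be >= 1")
  if (p$snp_density_per_mb <= 0) stop_msg("snp_density_per_mb must be > 0")
  class(p) <- "sim_params"
  p
}

#' Build the ancestral haplotype pool and marker maps
#'
#' Simulates the SNP map (Poisson-placed SNPs, one chromosome per STR locus
#' with the STR at the midpoint), K ancestral binary haplotypes, and the
#' founding STR allele carried by each lineage at each locus. When the
#' requested founding allele count exceeds K, only K alleles can be realized
#' (one per lineage); the remainder can only arise later via mutation.
#'
#' @param params a [sim_params] object.
#' @return A list (`sim_scaffold`) with `map`, `loci`, `anc_hap` (K x S
#'   binary matrix), `founding_allele` (K x L matrix of bp lengths), and
#'   `chrom_cols` (per-chromosome column ranges into the SNP map).
#' @export
make_ancestral_haplotypes <- function(params) {
  set.seed(derive_seed(params$seed, "scaffold"))
  L <- params$n_str_loci
  len_bp <- round(params$chrom_length_mb * 1e6)
  chroms <- as.character(seq_len(L))
  map_list <- vector("list", L)
  loci <- data.frame(id = sprintf("STR%02d", seq_len(L)), chrom = chroms,
                     pos_bp = rep(as.integer(round(len_bp / 2)), L),
                     stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    n_snp <- stats::rpois(1L, params$snp_density_per_mb * params$chrom_length_mb)
    pos <- sort(unique(as.integer(ceiling(stats::runif(n_snp, 0, len_bp)))))
    pos <- setdiff(pos, loci$pos_bp[l])  # a SNP cannot sit on the STR itself
    map_list[[l]] <- data.frame(
      snp_id = sprintf("snp_%s_%d", chroms[l], seq_along(pos)),
      chrom = chroms[l], pos = pos, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_list)
  S <- nrow(map)
  K <- params$n_lineages
  min_chr <- min(vapply(map_list, nrow, 0L))
  if (log2(K) > min_chr)
    stop_msg("n_lineages = %d exceeds the 2^%d haplotypes distinguishable on the sparsest chromosome", K, min_chr)
  anc <- matrix(stats::rbinom(K * S, 1L, 0.5), K, S)
  founding <- matrix(NA_integer_, K, L)
  for (l in seq_len(L)) {
    a_req <- params$str_allele_counts[l]
    ladder <- params$str_base_lengths[l] +
      params$str_motif_bp * (seq_len(a_req) - 1L)
    if (K >= a_req) {
      assign <- c(seq_len(a_req), sample.int(a_req, K - a_req, replace = TRUE))
      assign <- sample(assign)          # every requested allele realized
    } else {
      assign <- sample.int(a_req, K)    # at most K founding alleles (pigeonhole)
    }
    founding[, l] <- ladder[assign]
  }
  ends <- cumsum(vapply(map_list, nrow, 0L))
  chrom_cols <- cbind(start = c(1L, utils::head(ends, -1L) + 1L), end = ends)
  structure(list(map = map, loci = loci, anc_hap = anc,
                 founding_allele = founding, chrom_cols = chrom_cols,
                 params = params),
            class = "sim_scaffold")
}

#' Simulate a discrete-generation pedigree with ram-heavy mating
#'
#' Generation 0 holds the founders (half male, half female); each later
#' generation draws, per offspring, a sire from at most `n_sires` breeding
#' males and a dam at random from the previous generation's females.
#'
#' @param params a [sim_params] object.
#' @return A `pedigree_df` with extra columns `sex` ("M"/"F") and `gen`.
#' @export
sim_pedigree <- function(params) {
  set.seed(derive_seed(params$seed, "pedigree"))
  nf <- params$n_founders
  id <- sprintf("I%05d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  gen <- rep(0L, nf)
  sire <- dam <- rep(NA_character_, nf)
  next_id <- nf + 1L
  for (g in seq_len(params$n_generations - 1L)) {
    prev <- which(gen == g - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop_msg("generation %d has no breeding pair", g - 1L)
    sires <- if (length(males) > params$n_sires)
      sample(males, params$n_sires) else males
    n_off <- params$offspring_per_generation
    off_id <- sprintf("I%05d", seq.int(next_id, length.out = n_off))
    next_id <- next_id + n_off
    id <- c(id, off_id)
    sire <- c(sire, sample(sires, n_off, replace = TRUE))
    dam <- c(dam, sample(females, n_off, replace = TRUE))
    sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
    gen <- c(gen, rep(g, n_off))
  }
  out <- data.frame(id = id, sire = sire, dam = dam, sex = sex, gen = gen,
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree_df", "data.frame")
  out
}

#' Draw one gamete from a pair of parental haplotypes
#'
#' Crossover count is Poisson(length_cM / 100) (Haldane map, no
#' interference) with breakpoints uniform on the chromosome; the gamete is
#' the corresponding mosaic of the two parental haplotypes.
#'
#' @param hapA,hapB parental haplotype vectors over the chromosome's SNPs.
#' @param pos SNP positions (bp).
#' @param chrom_len_bp chromosome length (bp).
#' @param cM_per_mb genetic map density.
#' @param extra_pos optional extra position (the STR) whose source haplotype
#'   is also reported.
#' @return List: `hap` (gamete SNP vector), `n_cross` (crossover count),
#'   `extra_src` (1 or 2: which parental haplotype covers `extra_pos`).
#' @export
meiosis_gamete <- function(hapA, hapB, pos, chrom_len_bp, cM_per_mb,
                           extra_pos = NULL) {
  len_cM <- chrom_len_bp / 1e6 * cM_per_mb
  k <- stats::rpois(1L, len_cM / 100)
  start <- sample.int(2L, 1L)
  if (k == 0L) {
    hap <- if (start == 1L) hapA else hapB
    return(list(hap = hap, n_cross = 0L,
                extra_src = if (is.null(extra_pos)) NA_integer_ else start))
  }
  bp <- sort(stats::runif(k, 0, chrom_len_bp))
  src <- (findInterval(pos, bp) + start) %% 2L  # 1 -> hapA, 0 -> hapB
  hap <- ifelse(src == 1L, hapA, hapB)
  extra_src <- if (is.null(extra_pos)) NA_integer_ else {
    s <- (findInterval(extra_pos, bp) + start) %% 2L
    if (s == 1L) 1L else 2L
  }
  list(hap = hap, n_cross = k,
       extra_src = if (is.null(extra_pos)) NA_integer_ else extra_src)
}

# One founder haplotype for one chromosome: a coarse lineage mosaic.
# Returns list(hap, lineage_at_extra).
founder_mosaic <- function(scaffold, chrom_idx, extra_pos) {
  p <- scaffold$params
  cols <- seq.int(scaffold$chrom_cols[chrom_idx, "start"],
                  scaffold$chrom_cols[chrom_idx, "end"])
  pos <- scaffold$map$pos[cols]
  len_bp <- round(p$chrom_length_mb * 1e6)
  k <- stats::rpois(1L, p$founder_switch_per_mb * p$chrom_length_mb)
  K <- p$n_lineages
  if (k == 0L) {
    lin <- sample.int(K, 1L)
    return(list(hap = scaffold$anc_hap[lin, cols], lineage = lin))
  }
  bp <- sort(stats::runif(k, 0, len_bp))
  seg_lin <- sample.int(K, k + 1L, replace = TRUE)
  seg <- findInterval(pos, bp) + 1L
  hap <- scaffold$anc_hap[cbind(seg_lin[seg], cols)]
  list(hap = hap, lineage = seg_lin[findInterval(extra_pos, bp) + 1L])
}

#' Gene-drop SNP haplotypes and STR alleles through a pedigree
#'
#' Founders receive lineage-mosaic haplotype pairs; each offspring haplotype
#' is a recombinant gamete of its parent's pair ([meiosis_gamete()]). STR
#' alleles travel with the haplotype segment covering the locus and mutate
#' stepwise (one repeat unit up or down, equal probability) at
#' `str_mutation_rate` per meiosis. An individual with an unknown parent
#' draws that gamete from a fresh founder mosaic.
#'
#' @param pedigree a pedigree with `sex`/`gen` columns ([sim_pedigree()]).
#' @param scaffold a `sim_scaffold` from [make_ancestral_haplotypes()].
#' @return A `phased_cohort` list: `snp` (phased [snp_matrix]), `msat_true`
#'   (an [msat_geno]; allele 1 rides haplotype 1), `lineage1`/`lineage2`
#'   (ancestral-lineage label at each STR per haplotype), `pedigree_true`,
#'   `loci`, `params`.
#' @export
drop_gametes <- function(pedigree, scaffold) {
  p <- scaffold$params
  set.seed(derive_seed(p$seed, "gametes"))
  ped <- as_pedigree(pedigree)  # topological order
  extra <- pedigree[match(ped$id, pedigree$id), c("sex", "gen")]
  n <- nrow(ped); S <- nrow(scaffold$map); L <- p$n_str_loci
  len_bp <- round(p$chrom_length_mb * 1e6)
  hap1 <- hap2 <- matrix(NA_integer_, n, S)
  a1 <- a2 <- lin1 <- lin2 <- matrix(NA_integer_, n, L)
  row_of <- seq_len(n); names(row_of) <- ped$id
  motif <- p$str_motif_bp; mu <- p$str_mutation_rate

  draw_founder_gamete <- function(l, cols) {
    fm <- founder_mosaic(scaffold, l, scaffold$loci$pos_bp[l])
    list(hap = fm$hap, allele = scaffold$founding_allele[fm$lineage, l],
         lin = fm$lineage)
  }

  mutate_str <- function(allele) {
    if (mu > 0 && stats::runif(1L) < mu)
      allele + sample(c(-motif, motif), 1L) else allele
  }

  for (i in seq_len(n)) {
    si <- ped$sire[i]; di <- ped$dam[i]
    for (l in seq_len(L)) {
      cols <- seq.int(scaffold$chrom_cols[l, "start"], scaffold$chrom_cols[l, "end"])
      pos <- scaffold$map$pos[cols]
      # paternal gamete -> haplotype 1
      if (is.na(si)) {
        g <- draw_founder_gamete(l, cols)
        hap1[i, cols] <- g$hap; a1[i, l] <- mutate_str(g$allele); lin1[i, l] <- g$lin
      } else {
        r <- row_of[[si]]
        gm <- meiosis_gamete(hap1[r, cols], hap2[r, cols], pos, len_bp,
                             p$recomb_rate_cM_per_mb, scaffold$loci$pos_bp[l])
        hap1[i, cols] <- gm$hap
        src <- gm$extra_src
        a1[i, l] <- mutate_str(if (src == 1L) a1[r, l] else a2[r, l])
        lin1[i, l] <- if (src == 1L) lin1[r, l] else lin2[r, l]
      }
      # maternal gamete -> haplotype 2
      if (is.na(di)) {
        g <- draw_founder_gamete(l, cols)
        hap2[i, cols] <- g$hap; a2[i, l] <- mutate_str(g$allele); lin2[i, l] <- g$lin
      } else {
        r <- row_of[[di]]
        gm <- meiosis_gamete(hap1[r, cols], hap2[r, cols], pos, len_bp,
                             p$recomb_rate_cM_per_mb, scaffold$loci$pos_bp[l])
        hap2[i, cols] <- gm$hap
        src <- gm$extra_src
        a2[i, l] <- mutate_str(if (src == 1L) a1[r, l] else a2[r, l])
        lin2[i, l] <- if (src == 1L) lin1[r, l] else lin2[r, l]
      }
    }
  }

  snp <- snp_matrix(ped$id, scaffold$map, hap1 + hap2, hap1, hap2)
  msat_true <- structure(
    list(samples = ped$id, loci = scaffold$loci, a1 = a1, a2 = a2),
    class = "msat_geno")  # keep phase alignment: a1 rides hap1 (do not sort)
  dimnames(msat_true$a1) <- dimnames(msat_true$a2) <-
    list(ped$id, scaffold$loci$id)
  ped_out <- cbind(ped, extra)
  class(ped_out) <- c("pedigree_df", "data.frame")
  structure(list(snp = snp, msat_true = msat_true,
                 lineage1 = lin1, lineage2 = lin2,
                 pedigree_true = ped_out, loci = scaffold$loci, params = p),
            class = "phased_cohort")
}

#' Inject pedigree misassignments and genotype missingness
#'
#' A fraction `misassignment_rate` of parent links in the RECORDED pedigree
#' is rewired to a random same-sex individual of the true parent's
#' generation (never the true parent); recorded STR genotypes are masked to
#' missing at `genotyping_missing_rate`. The truth (true pedigree and true
#' genotypes) is kept untouched on the cohort.
#'
#' @param cohort a `phased_cohort` from [drop_gametes()].
#' @param params a [sim_params] (defaults to the cohort's own).
#' @return The cohort with `msat_obs`, `pedigree_recorded`, and a
#'   `misassigned` data.frame (offspring, role, true vs recorded parent).
#' @export
inject_errors <- function(cohort, params = cohort$params) {
  set.seed(derive_seed(params$seed, "errors"))
  ped <- cohort$pedigree_true
  rec <- ped
  mis <- data.frame(offspring = character(), role = character(),
                    true_parent = character(), recorded_parent = character(),
                    stringsAsFactors = FALSE)
  rate <- params$misassignment_rate
  if (rate > 0) {
    for (role in c("sire", "dam")) {
      has <- which(!is.na(ped[[role]]))
      hit <- has[stats::runif(length(has)) < rate]
      for (i in hit) {
        truep <- ped[[role]][i]
        tp <- ped[ped$id == truep, ]
        pool <- ped$id[ped$sex == tp$sex & ped$gen == tp$gen &
                         ped$id != truep & ped$id != ped$id[i]]
        if (!length(pool))
          stop_msg("no eligible substitute parent for %s (%s)", ped$id[i], role)
        sub <- if (length(pool) == 1L) pool else sample(pool, 1L)
        rec[[role]][i] <- sub
        mis <- rbind(mis, data.frame(offspring = ped$id[i], role = role,
                                     true_parent = truep, recorded_parent = sub,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  obs <- msat_geno(cohort$msat_true$samples, cohort$msat_true$loci,
                   cohort$msat_true$a1, cohort$msat_true$a2)
  if (params$genotyping_missing_rate > 0) {
    mask <- matrix(stats::runif(length(obs$a1)) < params$genotyping_missing_rate,
                   nrow(obs$a1), ncol(obs$a1))
    obs$a1[mask] <- NA_integer_
    obs$a2[mask] <- NA_integer_
  }
  cohort$msat_obs <- obs
  cohort$pedigree_recorded <- rec
  cohort$misassigned <- mis
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Composes [make_ancestral_haplotypes()], [sim_pedigree()],
#' [drop_gametes()], and [inject_errors()]. The same seed yields an
#' identical cohort.
#'
#' @param params a [sim_params] object.
#' @return A `phased_cohort` with truth (`msat_true`, `pedigree_true`,
#'   lineage labels) and recorded data (`msat_obs`, `pedigree_recorded`).
#' @export
simulate_cohort <- function(params = sim_params()) {
  scaffold <- make_ancestral_haplotypes(params)
  ped <- sim_pedigree(params)
  cohort <- drop_gametes(ped, scaffold)
  inject_errors(cohort, params)
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("phased_cohort: %d individuals, %d SNPs, %d STR loci, %d generations\n",
              length(x$snp$samples), nrow(x$snp$map), nrow(x$loci),
              max(x$pedigree_true$gen) + 1L))
  invisible(x)
}
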