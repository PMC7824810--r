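# Core data model: microsatellite genotype tables, SNP matrices, pedigrees,
# and the VCF dialect used to carry recoded microsatellite genotypes.
#
# Conventions shared by every stage:
#   * coordinates are 1-based bp; intervals are inclusive on both ends;
#   * a microsatellite genotype is an unordered pair of allele lengths (bp);
#     missingness is whole-genotype (both alleles or neither);
#   * sample identity across files is by string id.

#' Construct a microsatellite genotype set
#'
#' Container for per-sample microsatellite genotypes at a set of loci.
#' Genotypes are unordered pairs of allele lengths in base pairs; internally
#' the pair is stored sorted so that equality is order-invariant. A missing
#' genotype has both alleles `NA` (half-missing calls are rejected, matching
#' how STR callers report).
#'
#' @param samples character vector of sample ids (unique).
#' @param loci data.frame with columns `id`, `chrom`, `pos_bp` (chrom/pos may
#'   be `NA` when no marker map is attached).
#' @param a1,a2 integer matrices (samples x loci) of allele lengths in bp.
#' @return An object of class `msat_geno`.
#' @export
msat_geno <- function(samples, loci, a1, a2) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop_msg("duplicate sample id: %s",
                                       samples[duplicated(samples)][1L])
  stopifnot(is.data.frame(loci), all(c("id", "chrom", "pos_bp") %in% names(loci)))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(samples), nrow(loci))) || !all(dim(a1) == dim(a2)))
    stop_msg("genotype matrices must be %d samples x %d loci",
             length(samples), nrow(loci))
  if (any(is.na(a1) != is.na(a2)))
    stop_msg("half-missing genotype found; missingness must cover both alleles")
  # normalize unordered pairs: a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(samples, loci$id)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "msat_geno")
}

#' @export
print.msat_geno <- function(x, ...) {
  cat(sprintf("msat_geno: %d samples x %d loci, %.1f%% missing\n",
              length(x$samples), nrow(x$loci),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.msat_geno <- function(x) c(length(x$samples), nrow(x$loci))

#' Subset a microsatellite genotype set by sample and/or locus
#'
#' @param x an [msat_geno] object.
#' @param i sample index or ids; @param j locus index or ids.
#' @param ... unused.
#' @return An [msat_geno] restricted to the requested samples/loci.
#' @export
`[.msat_geno` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$loci$id)
  msat_geno(x$samples[i], x$loci[j, , drop = FALSE],
            x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

#' Read a microsatellite genotype table
#'
#' Parses a TSV/CSV table whose first column is `sample_id` and whose
#' remaining columns are marker columns holding `a/b` allele-length pairs in
#' bp (e.g. `"104/110"`) or `"./."` for missing. The locus catalogue is
#' derived from the observed alleles; chromosome/position come from
#' `marker_map` when supplied.
#'
#' @param path path to the table (tab- or comma-separated, with header).
#' @param marker_map optional data.frame with columns `id`, `chrom`,
#'   `pos_bp` (and optionally more) giving map positions per marker.
#' @return An [msat_geno] object.
#' @export
read_microsat_table <- function(path, marker_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "")
  if (ncol(tab) < 2L) stop_msg("%s: need sample_id plus >=1 marker column", path)
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop_msg("%s: duplicate sample id '%s' (row %d)", path,
             ids[duplicated(ids)][1L], which(duplicated(ids))[1L])
  markers <- names(tab)[-1L]
  n <- nrow(tab); L <- length(markers)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    field <- tab[[l + 1L]]
    miss <- field %in% c("./.", ".", "", "NA")
    parts <- strsplit(field[!miss], "/", fixed = TRUE)
    bad <- vapply(parts, length, 0L) != 2L
    if (any(bad))
      stop_msg("%s: malformed genotype '%s' for sample '%s', marker %s",
               path, field[!miss][bad][1L], ids[!miss][bad][1L], markers[l])
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      k <- which(is.na(v[c(TRUE, FALSE)] ) | is.na(v[c(FALSE, TRUE)]))[1L]
      stop_msg("%s: non-integer allele length '%s' for sample '%s', marker %s",
               path, field[!miss][k], ids[!miss][k], markers[l])
    }
    a1[!miss, l] <- v[c(TRUE, FALSE)]
    a2[!miss, l] <- v[c(FALSE, TRUE)]
  }
  loci <- data.frame(id = markers, chrom = NA_character_, pos_bp = NA_integer_,
                     stringsAsFactors = FALSE)
  if (!is.null(marker_map)) {
    m <- match(markers, marker_map$id)
    loci$chrom <- as.character(marker_map$chrom[m])
    loci$pos_bp <- as.integer(marker_map$pos_bp[m])
  }
  msat_geno(ids, loci, a1, a2)
}

#' Write a microsatellite genotype table
#'
#' Inverse of [read_microsat_table()]: emits the `a/b` pair dialect with
#' `"./."` for missing genotypes.
#'
#' @param x an [msat_geno] object.
#' @param path output path (TSV).
#' @export
write_microsat_table <- function(x, path) {
  out <- data.frame(sample_id = x$samples, stringsAsFactors = FALSE)
  for (l in seq_len(nrow(x$loci))) {
    g <- ifelse(is.na(x$a1[, l]), "./.",
                paste0(x$a1[, l], "/", x$a2[, l]))
    out[[x$loci$id[l]]] <- g
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Catalogue of observed alleles per locus
#'
#' @param x an [msat_geno] object.
#' @return Named list: for each locus, the sorted vector of distinct observed
#'   allele lengths (bp).
#' @export
msat_allele_catalog <- function(x) {
  out <- lapply(seq_len(nrow(x$loci)), function(l)
    sort(unique(c(x$a1[, l], x$a2[, l])[!is.na(c(x$a1[, l], x$a2[, l]))])))
  names(out) <- x$loci$id
  out
}

# ---------------------------------------------------------------------------
# SNP matrix

#' Construct a SNP genotype matrix
#'
#' Biallelic SNP genotypes coded as alternate-allele counts `{0,1,2}` with
#' `NA` for missing, plus optional phased haplotypes (`{0,1}` matrices).
#' Positions must be sorted within chromosome.
#'
#' @param samples character sample ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp).
#' @param geno integer matrix (samples x SNPs) in `{0,1,2,NA}`.
#' @param hap1,hap2 optional binary matrices (samples x SNPs) of phased
#'   haplotype alleles; `geno` must equal `hap1 + hap2` where phased.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(samples, map, geno, hap1 = NULL, hap2 = NULL) {
  samples <- as.character(samples)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  geno <- as.matrix(geno); storage.mode(geno) <- "integer"
  if (!all(dim(geno) == c(length(samples), nrow(map))))
    stop_msg("geno must be %d samples x %d SNPs", length(samples), nrow(map))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = FALSE))
      stop_msg("SNP positions not sorted on chromosome %s", ch)
  }
  phased <- !is.null(hap1)
  if (phased) {
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    stopifnot(all(dim(hap1) == dim(geno)), all(dim(hap2) == dim(geno)))
  }
  dimnames(geno) <- list(samples, map$snp_id)
  structure(list(samples = samples, map = map, geno = geno,
                 hap1 = hap1, hap2 = hap2, phased = phased),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d samples x %d SNPs on %d chromosome(s)%s\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chrom)),
              if (x$phased) ", phased" else ""))
  invisible(x)
}

#' Subset a SNP matrix
#'
#' @param x a [snp_matrix]; @param i sample index/ids; @param j SNP index/ids.
#' @param ... unused.
#' @export
`[.snp_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$map))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  snp_matrix(x$samples[i], x$map[j, , drop = FALSE],
             x$geno[i, j, drop = FALSE],
             if (x$phased) x$hap1[i, j, drop = FALSE],
             if (x$phased) x$hap2[i, j, drop = FALSE])
}

# ---------------------------------------------------------------------------
# Pedigree

#' Read and validate a three-column pedigree
#'
#' Whitespace-separated text with columns id, sire, dam; `0` or `.` denotes
#' an unknown parent. Parents that never appear as individuals are auto-added
#' as founders with a warning. The pedigree must be acyclic; rows are
#' returned in a topological order (parents before offspring).
#'
#' @param path path to the pedigree file (a header line `id sire dam` is
#'   optional and detected).
#' @return A data.frame of class `pedigree_df` with character columns `id`,
#'   `sire`, `dam` (`NA` = unknown parent).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "sire", "dam"),
                           comment.char = "#")
  if (nrow(raw) && identical(tolower(raw$id[1L]), "id"))
    raw <- raw[-1L, , drop = FALSE]
  as_pedigree(raw)
}

#' Validate a pedigree data.frame
#'
#' @param df data.frame with columns `id`, `sire`, `dam`; `0`, `.` or `NA`
#'   mean unknown.
#' @return A topologically sorted data.frame of class `pedigree_df`.
#' @export
as_pedigree <- function(df) {
  df <- data.frame(id = as.character(df$id), sire = as.character(df$sire),
                   dam = as.character(df$dam), stringsAsFactors = FALSE)
  df$sire[df$sire %in% c("0", ".", "NA")] <- NA
  df$dam[df$dam %in% c("0", ".", "NA")] <- NA
  if (anyDuplicated(df$id))
    stop_msg("duplicate individual in pedigree: %s", df$id[duplicated(df$id)][1L])
  known_par <- stats::na.omit(unique(c(df$sire, df$dam)))
  orphans <- setdiff(known_par, df$id)
  if (length(orphans)) {
    warning(sprintf("%d parent(s) not listed as individuals; added as founders: %s",
                    length(orphans), paste(utils::head(orphans, 5L), collapse = ", ")))
    df <- rbind(data.frame(id = orphans, sire = NA_character_,
                           dam = NA_character_, stringsAsFactors = FALSE), df)
  }
  ord <- ped_topo_order(df)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree_df", "data.frame")
  out
}

# Kahn topological sort; errors naming an individual on a cycle.
ped_topo_order <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n); names(idx) <- df$id
  si <- unname(idx[df$sire]); di <- unname(idx[df$dam])
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L); ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    bad <- df$id[setdiff(idx, ord)][1L]
    stop_msg("pedigree cycle detected involving individual '%s'", bad)
  }
  ord
}

#' Extract recorded parent-offspring pairs
#'
#' @param ped a `pedigree_df`.
#' @return data.frame with columns `parent`, `offspring`, `role`
#'   (`"sire"`/`"dam"`), one row per known parental link.
#' @export
ped_pairs <- function(ped) {
  s <- !is.na(ped$sire); d <- !is.na(ped$dam)
  out <- rbind(
    data.frame(parent = ped$sire[s], offspring = ped$id[s], role = "sire",
               stringsAsFactors = FALSE),
    data.frame(parent = ped$dam[d], offspring = ped$id[d], role = "dam",
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a pedigree in three-column text form
#'
#' @param ped a `pedigree_df`; @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out[, c("id", "sire", "dam")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Microsatellite VCF dialect
#
# True repeat sequences are unknown from genotype tables, so records use
# symbolic placeholder alleles: REF is "N", ALT alleles are "<Ak>"; the INFO
# key ALEN lists the real allele lengths (bp) in code order (code 0 first).
# Genotypes are the integer codes, unphased ("c1/c2").

#' Write recoded microsatellite genotypes as VCF 4.2
#'
#' One multiallelic record per microsatellite. Allele codes follow the
#' population recoding rule (see [recode_alleles()]): the code map gives
#' allele length -> integer code; code 0 is the REF placeholder.
#'
#' @param x an [msat_geno] with mapped loci (chrom/pos set).
#' @param code_maps named list (by locus id) of named integer vectors mapping
#'   allele length (names, bp) to codes `0..n-1`.
#' @param path output path.
#' @param extra_header character vector of additional `##` header lines.
#' @export
write_msat_vcf <- function(x, code_maps, path, extra_header = character()) {
  loci <- x$loci
  if (anyNA(loci$chrom) || anyNA(loci$pos_bp))
    stop_msg("all loci need chrom and pos_bp to write VCF")
  ord <- order(loci$chrom, loci$pos_bp)
  if (!identical(ord, seq_len(nrow(loci)))) {
    for (ch in unique(loci$chrom))
      if (is.unsorted(loci$pos_bp[loci$chrom == ch]))
        stop_msg("unsorted microsatellite positions on chromosome %s", ch)
    loci <- loci[ord, , drop = FALSE]
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=msatimpute",
    "##INFO=<ID=ALEN,Number=R,Type=Integer,Description=\"Microsatellite allele lengths in bp, in allele-code order\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (allele codes)\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")), con)
  for (r in seq_len(nrow(loci))) {
    lid <- loci$id[r]
    cmap <- code_maps[[lid]]
    if (is.null(cmap)) stop_msg("no code map for locus %s", lid)
    if (!identical(sort(unname(cmap)), seq_along(cmap) - 1L))
      stop_msg("locus %s: codes must be consecutive 0..n-1", lid)
    lens <- as.integer(names(cmap))[order(cmap)]  # lengths in code order
    alt <- if (length(lens) > 1L)
      paste0("<A", seq_len(length(lens) - 1L), ">", collapse = ",") else "."
    l0 <- match(lid, x$loci$id)
    code1 <- cmap[as.character(x$a1[, l0])]
    code2 <- cmap[as.character(x$a2[, l0])]
    gt <- ifelse(is.na(code1), "./.",
                 paste0(pmin(code1, code2), "/", pmax(code1, code2)))
    writeLines(paste(c(loci$chrom[r], loci$pos_bp[r], lid, "N", alt, ".",
                       "PASS", paste0("ALEN=", paste(lens, collapse = ",")),
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the microsatellite VCF dialect back
#'
#' Inverse of [write_msat_vcf()]: decodes allele codes to bp lengths via the
#' ALEN INFO key. Unknown INFO keys are an error (the dialect is closed).
#'
#' @param path VCF path.
#' @return List with `geno` (an [msat_geno] in bp lengths) and `code_maps`.
#' @export
read_msat_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_msg("%s: no #CHROM header line", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  L <- length(body)
  loci <- data.frame(id = character(L), chrom = character(L),
                     pos_bp = integer(L), stringsAsFactors = FALSE)
  a1 <- a2 <- matrix(NA_integer_, length(samples), L)
  code_maps <- vector("list", L)
  for (r in seq_len(L)) {
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1L]]
    loci$chrom[r] <- f[1L]; loci$pos_bp[r] <- as.integer(f[2L]); loci$id[r] <- f[3L]
    info <- strsplit(f[8L], ";", fixed = TRUE)[[1L]]
    keys <- sub("=.*$", "", info)
    if (any(keys != "ALEN"))
      stop_msg("%s: unknown INFO key '%s' at record %s", path,
               keys[keys != "ALEN"][1L], f[3L])
    lens <- as.integer(strsplit(sub("^ALEN=", "", info[keys == "ALEN"]),
                                ",", fixed = TRUE)[[1L]])
    cmap <- stats::setNames(seq_along(lens) - 1L, lens)
    code_maps[[r]] <- cmap
    gt <- f[-(1:9)]
    ok <- gt != "./." & gt != "."
    parts <- strsplit(gt[ok], "[/|]")
    c1 <- as.integer(vapply(parts, `[`, "", 1L))
    c2 <- as.integer(vapply(parts, `[`, "", 2L))
    a1[ok, r] <- lens[c1 + 1L]
    a2[ok, r] <- lens[c2 + 1L]
  }
  names(code_maps) <- loci$id
  list(geno = msat_geno(samples, loci, a1, a2), code_maps = code_maps)
}

# ---------------------------------------------------------------------------
# SNP VCF (plain biallelic records, phased GT when haplotypes are present)

#' Write a SNP matrix as VCF 4.2
#'
#' @param x a [snp_matrix]; phased `|`-separated genotypes are written when
#'   haplotypes are present, else unphased counts.
#' @param path output path.
#' @export
write_snp_vcf <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=msatimpute",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")), con)
  n <- length(x$samples)
  for (j in seq_len(nrow(x$map))) {
    if (x$phased) {
      gt <- paste0(x$hap1[, j], "|", x$hap2[, j])
    } else {
      g <- x$geno[, j]
      gt <- c("0/0", "0/1", "1/1")[g + 1L]
    }
    gt[is.na(x$geno[, j])] <- "./."
    writeLines(paste(c(x$map$chrom[j], x$map$pos[j], x$map$snp_id[j],
                       "A", "G", ".", "PASS", ".", "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a biallelic SNP VCF into a [snp_matrix]
#'
#' Accepts phased (`|`) or unphased (`/`) GT fields; phase is retained when
#' every call is phased.
#'
#' @param path VCF path.
#' @return A [snp_matrix].
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]; body <- body[nzchar(body)]
  S <- length(body); n <- length(samples)
  map <- data.frame(snp_id = character(S), chrom = character(S),
                    pos = integer(S), stringsAsFactors = FALSE)
  h1 <- h2 <- matrix(NA_integer_, n, S)
  all_phased <- TRUE
  for (j in seq_len(S)) {
    f <- strsplit(body[j], "\t", fixed = TRUE)[[1L]]
    map$chrom[j] <- f[1L]; map$pos[j] <- as.integer(f[2L]); map$snp_id[j] <- f[3L]
    gt <- f[-(1:9)]
    ok <- gt != "./." & gt != "."
    if (any(ok)) {
      all_phased <- all_phased && all(grepl("|", gt[ok], fixed = TRUE))
      parts <- strsplit(gt[ok], "[/|]")
      h1[ok, j] <- as.integer(vapply(parts, `[`, "", 1L))
      h2[ok, j] <- as.integer(vapply(parts, `[`, "", 2L))
    }
  }
  geno <- h1 + h2
  if (all_phased) snp_matrix(samples, map, geno, h1, h2)
  else snp_matrix(samples, map, geno)
}
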