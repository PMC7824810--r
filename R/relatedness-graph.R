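# Genomic relationship matrix (VanRaden method 1), kinship network with
# centrality summaries, and a pedigree-based effective population size from
# the individual increase in inbreeding.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = ZZ' / (2 * sum p_j (1 - p_j)) with Z the column-centered genotype
#' matrix (M - 2p) and p_j the observed alternate-allele frequencies.
#' Missing genotypes are mean-imputed per SNP before centering; SNPs fixed
#' in the data (p in {0, 1}) contribute nothing and are excluded from both
#' numerator and denominator.
#'
#' @param x a [snp_matrix] or a plain genotype matrix in `{0,1,2,NA}`
#'   (samples x SNPs).
#' @return A list of class `grm`: `G` (symmetric matrix with sample
#'   dimnames), `freq` (per-SNP frequencies used), `n_snps_used`.
#' @export
compute_grm <- function(x) {
  M <- if (inherits(x, "snp_matrix")) x$geno else as.matrix(x)
  p <- colMeans(M, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop_msg("all SNPs monomorphic: GRM denominator is zero")
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(M, 2L, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation leaves a centered 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  structure(list(G = G, freq = p, n_snps_used = sum(keep)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d from %d SNPs; mean diagonal %.3f\n",
              nrow(x$G), ncol(x$G), x$n_snps_used, mean(diag(x$G))))
  invisible(x)
}

#' Build the relationship network at a kinship threshold
#'
#' Edges connect pairs with `G_ij > threshold` (strict); self-edges never
#' occur and individuals without any edge are dropped from the graph (they
#' are unrelated to the main population at this threshold).
#'
#' @param grm a `grm` from [compute_grm()] (or a plain symmetric matrix).
#' @param threshold kinship threshold, commonly 0.2 or 0.5.
#' @return A list of class `relation_graph`: `graph` (igraph), `edges`
#'   (data.frame i, j, g), `threshold`, `n_dropped`.
#' @export
build_relation_graph <- function(grm, threshold = 0.2) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  if (threshold <= 0 || threshold >= 2) stop_msg("threshold must lie in (0, 2)")
  ids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  up <- which(upper.tri(G) & G > threshold, arr.ind = TRUE)
  edges <- data.frame(i = ids[up[, 1L]], j = ids[up[, 2L]],
                      g = G[up], stringsAsFactors = FALSE)
  used <- unique(c(edges$i, edges$j))
  g <- igraph::graph_from_data_frame(edges[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = used))
  structure(list(graph = g, edges = edges, threshold = threshold,
                 n_dropped = nrow(G) - length(used)),
            class = "relation_graph")
}

#' Betweenness and closeness centrality summaries
#'
#' Betweenness is normalized to `[0, 1]` by (n-1)(n-2)/2 per node.
#' Closeness uses the component-scaled form
#' `closeness(v) = (r_v / (n-1)) * (r_v / sum d(v, u))` over the `r_v`
#' nodes reachable from `v`, so both coefficients range between 0 and 1 on
#' disconnected graphs.
#'
#' @param rg a `relation_graph` (or an igraph graph).
#' @return List: `mean_betweenness`, `mean_closeness`, `per_node`
#'   (data.frame id, betweenness, closeness). Means are `NA` on an empty
#'   graph.
#' @export
centrality_summary <- function(rg) {
  g <- if (inherits(rg, "relation_graph")) rg$graph else rg
  n <- igraph::vcount(g)
  if (n == 0L)
    return(list(mean_betweenness = NA_real_, mean_closeness = NA_real_,
                per_node = data.frame(id = character(0), betweenness = numeric(0),
                                      closeness = numeric(0))))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  btw <- if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else btw * 0
  D <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    reach <- d[is.finite(d)]
    r <- length(reach)
    if (r == 0L || sum(reach) == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0)
  per <- data.frame(id = igraph::V(g)$name, betweenness = unname(btw),
                    closeness = clo, stringsAsFactors = FALSE)
  list(mean_betweenness = mean(per$betweenness),
       mean_closeness = mean(per$closeness), per_node = per)
}

#' Pedigree inbreeding coefficients
#'
#' Wright's path/tabular inbreeding: F_i = A(sire, dam) / 2 with A the
#' additive relationship matrix built by the tabular recursion in
#' topological order. Founders (and individuals with an unknown parent)
#' have F = 0.
#'
#' @param ped a `pedigree_df` (topologically sorted; see [as_pedigree()]).
#' @return Named numeric vector of F per individual.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n)
  F <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    F[i] <- if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    A[i, i] <- 1 + F[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      rel <- 0.5 * ((if (!is.na(s)) A[s, prev] else 0) +
                      (if (!is.na(d)) A[d, prev] else 0))
      A[i, prev] <- rel
      A[prev, i] <- rel
    }
  }
  stats::setNames(F, ped$id)
}

#' Equivalent complete generations
#'
#' t_i = 1 + (t_sire + t_dam) / 2, with an unknown parent contributing 0;
#' founders have t = 1.
#'
#' @param ped a `pedigree_df`.
#' @return Named numeric vector of t per individual.
#' @export
equivalent_generations <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  t <- numeric(n)
  for (i in seq_len(n))
    t[i] <- 1 + 0.5 * ((if (is.na(si[i])) 0 else t[si[i]]) +
                         (if (is.na(di[i])) 0 else t[di[i]]))
  stats::setNames(t, ped$id)
}

#' Effective population size from the individual increase in inbreeding
#'
#' For each individual with more than one equivalent generation,
#' `dF_i = 1 - (1 - F_i)^(1 / (t_i - 1))`; the estimate is
#' `Ne = 1 / (2 * mean dF)` over the reference cohort.
#'
#' @param ped a `pedigree_df`.
#' @param reference `"all"` (every individual with t > 1, the default) or a
#'   character vector of ids forming the reference cohort.
#' @return List: `ne` (`NA` with a flag when no inbreeding has accrued),
#'   `mean_delta_f`, `n_reference`, `undefined` (TRUE when Ne is undefined
#'   or infinite).
#' @export
effective_population_size <- function(ped, reference = "all") {
  F <- pedigree_inbreeding(ped)
  t <- equivalent_generations(ped)
  ids <- if (identical(reference, "all")) names(F)[t > 1] else reference
  ids <- intersect(ids, names(F)[t > 1])
  if (!length(ids))
    return(list(ne = NA_real_, mean_delta_f = NA_real_, n_reference = 0L,
                undefined = TRUE))
  dF <- 1 - (1 - F[ids])^(1 / (t[ids] - 1))
  mdF <- mean(dF)
  if (mdF <= 0)
    return(list(ne = NA_real_, mean_delta_f = mdF, n_reference = length(ids),
                undefined = TRUE))
  list(ne = 1 / (2 * mdF), mean_delta_f = mdF, n_reference = length(ids),
       undefined = FALSE)
}

#' Export a GRM
#'
#' Writes the square TSV and/or a long-format (i, j, G_ij) file.
#'
#' @param grm a `grm`; @param square_path,long_path output paths (`NULL`
#'   skips).
#' @export
write_grm <- function(grm, square_path = NULL, long_path = NULL) {
  G <- grm$G
  if (!is.null(square_path))
    utils::write.table(round(G, 6), square_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  if (!is.null(long_path)) {
    up <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
    ids <- rownames(G) %||% as.character(seq_len(nrow(G)))
    utils::write.table(
      data.frame(i = ids[up[, 1L]], j = ids[up[, 2L]], g = round(G[up], 6)),
      long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(grm)
}
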