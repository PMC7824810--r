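# Flanking-window selection: the SNPs within W Mb on EACH side of a
# microsatellite (total span 2W Mb), inclusive at exactly W*1e6 bp.
# A SNP at exactly the microsatellite position is excluded (it would be the
# marker itself).

#' Select the flanking SNP window for one microsatellite
#'
#' @param locus one-row data.frame (or list) with `id`, `chrom`, `pos_bp`.
#' @param snp_map data.frame with `snp_id`, `chrom`, `pos` (a [snp_matrix]
#'   `$map` works directly).
#' @param flank_mb W, the flank length in Mb on each side.
#' @return A `window_spec` list: `locus`, `flank_mb`, `snp_idx` (row indices
#'   into `snp_map`, sorted by position), `snp_id`, `pos`, `count`. A window
#'   holding zero SNPs is returned with a warning; imputation refuses it.
#' @export
select_window <- function(locus, snp_map, flank_mb) {
  if (flank_mb <= 0) stop_msg("flank_mb must be > 0")
  if (inherits(snp_map, "snp_matrix")) snp_map <- snp_map$map
  if (!locus$chrom %in% snp_map$chrom)
    stop_msg("chromosome %s of locus %s absent from SNP map",
             locus$chrom, locus$id)
  w <- flank_mb * 1e6
  sel <- which(snp_map$chrom == locus$chrom &
                 abs(snp_map$pos - locus$pos_bp) <= w &
                 snp_map$pos != locus$pos_bp)
  sel <- sel[order(snp_map$pos[sel])]
  if (!length(sel))
    warning(sprintf("window of %g Mb around %s holds no SNPs", flank_mb,
                    locus$id))
  structure(list(locus = locus$id, chrom = locus$chrom,
                 locus_pos = locus$pos_bp, flank_mb = flank_mb,
                 snp_idx = sel, snp_id = snp_map$snp_id[sel],
                 pos = snp_map$pos[sel], count = length(sel)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("window_spec: %s +/- %g Mb, %d SNPs\n", x$locus, x$flank_mb,
              x$count))
  invisible(x)
}

#' Assemble the low-density SNP panel for a window length
#'
#' The union of all loci's flanking windows, deduplicated: the design of a
#' low-density parentage chip.
#'
#' @param loci data.frame of microsatellite loci (`id`, `chrom`, `pos_bp`).
#' @param snp_map as in [select_window()].
#' @param flank_mb W in Mb.
#' @return List: `panel` (data.frame snp_id, chrom, pos, sorted), and
#'   `membership` (data.frame locus, snp_id), plus the `windows` list.
#' @export
build_panel <- function(loci, snp_map, flank_mb) {
  if (inherits(snp_map, "snp_matrix")) snp_map <- snp_map$map
  windows <- lapply(seq_len(nrow(loci)), function(l)
    select_window(loci[l, ], snp_map, flank_mb))
  names(windows) <- loci$id
  membership <- do.call(rbind, lapply(windows, function(w)
    if (w$count) data.frame(locus = w$locus, snp_id = w$snp_id,
                            stringsAsFactors = FALSE)))
  idx <- sort(unique(unlist(lapply(windows, `[[`, "snp_idx"))))
  panel <- snp_map[idx, c("snp_id", "chrom", "pos")]
  rownames(panel) <- NULL
  list(panel = panel, membership = membership, windows = windows,
       flank_mb = flank_mb)
}

#' Export a SNP panel for chip design
#'
#' Writes both a 3-column TSV (1-based positions) and a BED-like file
#' (0-based half-open); the coordinate convention is labeled in each header.
#'
#' @param panel the `panel` data.frame from [build_panel()].
#' @param tsv_path,bed_path output paths (either may be `NULL` to skip).
#' @export
write_panel <- function(panel, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines("# snp_id\tchrom\tpos (1-based, inclusive)", con)
    utils::write.table(panel, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  if (!is.null(bed_path)) {
    con <- file(bed_path, "w")
    writeLines("# chrom\tstart\tend\tsnp_id (0-based, half-open)", con)
    utils::write.table(
      data.frame(panel$chrom, panel$pos - 1L, panel$pos, panel$snp_id),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(panel)
}
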