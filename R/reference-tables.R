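# Bundled reference tables: the ISAG ovine parentage marker catalogue and
# the published 2-Mb per-marker imputation performance summary used as
# aggregation fixtures.

#' ISAG ovine parentage microsatellite catalogue
#'
#' The 19 ISAG-recommended parentage microsatellites with chromosome,
#' position, allele count, and allele length range as observed in a
#' commercial Assaf population.
#'
#' @return data.frame: id, chrom, pos_bp, n_alleles, range_min_bp,
#'   range_max_bp.
#' @export
isag_marker_catalog <- function() {
  utils::read.table(system.file("extdata", "msat_markers.tsv",
                                package = "msatimpute"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published 2-Mb per-marker imputation performance summary
#'
#' Reference per-marker concordance, genotype dosage, allelic dosage (with
#' min/max), and naive/random null-model concordances at the 2-Mb flanking
#' window, for aggregation checks.
#'
#' @return data.frame: chrom, pos_bp, id, conc, gd, ad, ad_min, ad_max,
#'   naive_conc, random_conc.
#' @export
reference_metrics_2mb <- function() {
  utils::read.table(system.file("extdata", "metrics_2mb_reference.tsv",
                                package = "msatimpute"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
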