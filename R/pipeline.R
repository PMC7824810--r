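# End-to-end orchestration: simulate, evaluate (qc -> recode -> window
# sweep -> CV -> reports), relatedness, panel design, and parentage. Each
# run writes a JSON manifest (inputs, parameters, seeds, version) that is
# sufficient to reproduce it. A thin command-line wrapper over these
# functions ships in inst/cli/msatimpute.R.

#' Load a run configuration
#'
#' YAML file with optional sections `sim`, `qc`, `hmm`, `cv` whose entries
#' override the corresponding parameter constructors. Precedence:
#' `overrides` argument > file > defaults.
#'
#' @param path YAML path (`NULL` for all-defaults).
#' @param overrides named list of `section$key` overrides, e.g.
#'   `list(sim = list(seed = 7))`.
#' @return List with `sim` ([sim_params]), `qc` ([qc_thresholds]), `hmm`
#'   ([hmm_params]), `cv` (list: flank_mb, k, seed, engine, method), and the
#'   raw `echo` of everything that was set.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  file_cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  merged <- utils::modifyList(file_cfg, overrides)
  take <- function(section) merged[[section]] %||% list()
  cv_defaults <- list(flank_mb = c(0.5, 1, 2), k = 10L, seed = 1L,
                      engine = "phased", method = "partition")
  list(sim = do.call(sim_params, take("sim")),
       qc = do.call(qc_thresholds, take("qc")),
       hmm = do.call(hmm_params, take("hmm")),
       cv = utils::modifyList(cv_defaults, take("cv")),
       echo = merged)
}

write_manifest <- function(out_dir, stage, fields) {
  manifest <- c(list(stage = stage,
                     package = "msatimpute",
                     version = as.character(utils::packageVersion("msatimpute")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                fields)
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop_msg("output directory %s exists and is non-empty; use force = TRUE",
             out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

#' Simulate a cohort and write its files
#'
#' Emits the formats the readers consume -- phased SNP VCF, microsatellite
#' genotype TSV (observed, with injected missingness), recorded pedigree
#' text -- plus a truth JSON (true genotypes, true pedigree, injected
#' misassignments) and a manifest echoing all parameters and the seed.
#'
#' @param params a [sim_params].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return The simulated `phased_cohort`, invisibly; files on disk.
#' @export
pipeline_simulate <- function(params = sim_params(), out_dir, force = FALSE) {
  prepare_out_dir(out_dir, force)
  cohort <- simulate_cohort(params)
  write_snp_vcf(cohort$snp, file.path(out_dir, "snp.vcf"))
  write_microsat_table(cohort$msat_obs, file.path(out_dir, "msat_obs.tsv"))
  write_pedigree(cohort$pedigree_recorded, file.path(out_dir, "pedigree.txt"))
  utils::write.table(cohort$loci, file.path(out_dir, "marker_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    msat_true = list(samples = cohort$msat_true$samples,
                     loci = cohort$msat_true$loci$id,
                     a1 = cohort$msat_true$a1, a2 = cohort$msat_true$a2),
    pedigree_true = as.data.frame(cohort$pedigree_true),
    misassigned = cohort$misassigned)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(out_dir, "simulate",
                 list(params = unclass(params), seed = params$seed,
                      n_individuals = length(cohort$snp$samples),
                      n_snps = nrow(cohort$snp$map),
                      n_str_loci = nrow(cohort$loci),
                      n_misassigned = nrow(cohort$misassigned)))
  invisible(cohort)
}

#' Run QC, recoding, and the cross-validated imputation sweep
#'
#' Stages: microsatellite + SNP quality control, population allele recoding
#' (code maps JSON + recoded microsatellite VCF), then the masking CV sweep
#' over the requested window lengths with per-window metric tables and a
#' sweep summary.
#'
#' @param cohort a `phased_cohort`.
#' @param out_dir output directory.
#' @param config a configuration from [load_run_config()].
#' @param force overwrite a non-empty directory.
#' @return The `cv_report`, invisibly; reports on disk.
#' @export
pipeline_evaluate <- function(cohort, out_dir, config = load_run_config(),
                              force = FALSE) {
  prepare_out_dir(out_dir, force)
  qc_m <- filter_microsatellites(cohort$msat_obs, config$qc)
  write_qc_report(qc_m$report, file.path(out_dir, "qc_microsatellites.tsv"))
  qc_s <- filter_snps(cohort$snp, config$qc)
  write_qc_report(qc_s$report, file.path(out_dir, "qc_snps.tsv"))
  kept_loci <- qc_m$report$locus[qc_m$report$kept]
  code_maps <- build_code_maps(qc_m$kept)
  jsonlite::write_json(lapply(code_maps, as.list),
                       file.path(out_dir, "code_maps.json"),
                       auto_unbox = TRUE)
  write_msat_vcf(qc_m$kept, code_maps, file.path(out_dir, "msat_recoded.vcf"))
  cohort$snp <- qc_s$kept
  report <- run_cv_sweep(cohort,
                         flank_mb = config$cv$flank_mb, k = config$cv$k,
                         seed = config$cv$seed, params = config$hmm,
                         engine = config$cv$engine, method = config$cv$method,
                         loci = kept_loci)
  write_metrics_tables(report, out_dir)
  write_manifest(out_dir, "evaluate",
                 list(cv = config$cv, hmm = unclass(config$hmm),
                      qc = unclass(config$qc),
                      loci_kept = kept_loci,
                      snps_kept = sum(qc_s$report$kept)))
  invisible(report)
}

#' Genomic relationships, kinship network, and effective population size
#'
#' @param cohort a `phased_cohort` (or a list with `snp` and
#'   `pedigree_recorded`).
#' @param out_dir output directory.
#' @param thresholds kinship thresholds for the network(s).
#' @param force overwrite a non-empty directory.
#' @return List with the `grm`, per-threshold graphs and centrality
#'   summaries, and the Ne estimate, invisibly.
#' @export
pipeline_relatedness <- function(cohort, out_dir, thresholds = c(0.2, 0.5),
                                 force = FALSE) {
  prepare_out_dir(out_dir, force)
  grm <- compute_grm(cohort$snp)
  write_grm(grm, long_path = file.path(out_dir, "grm_long.tsv"))
  nets <- lapply(thresholds, function(th) {
    rg <- build_relation_graph(grm, th)
    cs <- centrality_summary(rg)
    utils::write.table(rg$edges, file.path(out_dir,
                                           sprintf("edges_%g.tsv", th)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(threshold = th, graph = rg, centrality = cs)
  })
  ne <- effective_population_size(cohort$pedigree_recorded %||%
                                    cohort$pedigree_true)
  jsonlite::write_json(
    list(ne = ne[c("ne", "mean_delta_f", "n_reference", "undefined")],
         centrality = lapply(nets, function(x)
           list(threshold = x$threshold,
                mean_betweenness = x$centrality$mean_betweenness,
                mean_closeness = x$centrality$mean_closeness,
                n_nodes = igraph::vcount(x$graph$graph),
                n_dropped = x$graph$n_dropped))),
    file.path(out_dir, "relatedness_summary.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(out_dir, "relatedness",
                 list(thresholds = thresholds, n_snps = grm$n_snps_used))
  invisible(list(grm = grm, networks = nets, ne = ne))
}

#' Verify recorded parentage from imputed microsatellites and the SNP panel
#'
#' Contrasts the parents' real microsatellite genotypes with the
#' offspring's imputed genotypes (>= 17-of-19 rule) and runs the
#' opposing-homozygote check on the low-density panel SNPs.
#'
#' @param cohort a `phased_cohort`.
#' @param imputed an [msat_geno] of imputed genotypes (e.g.
#'   `cv_report$imputed[["2"]]`).
#' @param out_dir output directory.
#' @param flank_mb window length defining the SNP panel (default 2).
#' @param tau,min_snps see [snp_window_conflicts()].
#' @param force overwrite a non-empty directory.
#' @return The `parentage_report`, invisibly; TSV + summary JSON on disk.
#' @export
pipeline_parentage <- function(cohort, imputed, out_dir, flank_mb = 2,
                               tau = 0.01, min_snps = 50L, force = FALSE) {
  prepare_out_dir(out_dir, force)
  panel <- build_panel(cohort$loci, cohort$snp$map, flank_mb)
  report <- check_parentage(cohort$pedigree_recorded,
                            parent_msat = cohort$msat_obs,
                            offspring_msat = imputed,
                            snp = cohort$snp,
                            panel_snp_ids = panel$panel$snp_id,
                            tau = tau, min_snps = min_snps)
  utils::write.table(as.data.frame(report),
                     file.path(out_dir, "parentage_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summarize_parentage(report),
                       file.path(out_dir, "parentage_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(out_dir, "parentage",
                 list(flank_mb = flank_mb, tau = tau, min_snps = min_snps,
                      n_panel_snps = nrow(panel$panel)))
  invisible(report)
}

# ---------------------------------------------------------------------------
# External-imputer adapter (interface only): users with an external phasing/
# imputation engine can export the merged SNP + microsatellite VCF, run the
# engine themselves, and read its output back through read_msat_vcf().

#' Export the merged SNP + recoded microsatellite VCF for an external imputer
#'
#' Writes one VCF holding both the biallelic SNP records and the
#' multiallelic recoded microsatellite records, position-sorted per
#' chromosome, for users running an external imputation engine.
#'
#' @param cohort a `phased_cohort`.
#' @param code_maps as from [build_code_maps()] (defaults to maps built from
#'   the observed genotypes).
#' @param path output VCF path.
#' @export
export_for_external_imputer <- function(cohort, code_maps = NULL, path) {
  if (is.null(code_maps)) code_maps <- build_code_maps(cohort$msat_obs)
  tmp_snp <- tempfile(fileext = ".vcf"); tmp_ms <- tempfile(fileext = ".vcf")
  on.exit(unlink(c(tmp_snp, tmp_ms)))
  write_snp_vcf(cohort$snp, tmp_snp)
  write_msat_vcf(cohort$msat_obs, code_maps, tmp_ms)
  snp_lines <- readLines(tmp_snp); ms_lines <- readLines(tmp_ms)
  hdr <- unique(c(grep("^##", ms_lines, value = TRUE),
                  grep("^##", snp_lines, value = TRUE)))
  chrom_line <- grep("^#CHROM", snp_lines, value = TRUE)
  body <- c(snp_lines[!grepl("^#", snp_lines)],
            ms_lines[!grepl("^#", ms_lines)])
  key <- do.call(rbind, lapply(strsplit(body, "\t"), `[`, 1:2))
  ord <- order(key[, 1L], as.integer(key[, 2L]))
  writeLines(c(hdr, chrom_line, body[ord]), path)
  invisible(path)
}

#' Read an externally imputed microsatellite VCF back
#'
#' @param path VCF written by the external engine, using the same allele
#'   codes (ALEN INFO) as the export.
#' @return As [read_msat_vcf()].
#' @export
import_external_imputation <- function(path) {
  out <- tryCatch(read_msat_vcf(path), error = function(e)
    stop_msg("external VCF not in the expected microsatellite dialect: %s",
             conditionMessage(e)))
  out
}
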