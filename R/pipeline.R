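# End-to-end driver: config handling and the quantify -> filter -> fit ->
# quartiles stage chain, with per-stage TSV outputs and a JSON run summary.

#' Default pipeline configuration
#'
#' All stage thresholds live here; stage code reads them from the config
#' only, never from literals.
#'
#' @param ... overrides of any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fe_min = 4,
    min_score_frac = 0.85,
    motif_flank = 100L,
    peak_half_width = 50L,
    window_bp = 101L,
    target_fragments = 1e6,
    outlier_fold = 6,
    roadblock_threshold = 2,
    fc_min = 1.5,
    p_max = 0.01,
    promoter_bp = 500L,
    times = default_times(),
    seed = 1L,
    paths = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()] plus `paths`.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full off-rate pipeline on files
#'
#' Stages: read inputs, quantify every sample against the full peak set
#' (midpoint coverage, depth scaling, +/- 50 bp window sums, background
#' normalization), flag outlier samples, filter sites (fold enrichment,
#' motif, -8 bp rule, telomeres), fit the decay model per site, assign
#' residence-time quartiles, and write every intermediate plus a JSON
#' summary. Deterministic given config and inputs.
#'
#' @param config a `pipeline_config` whose `paths` list names `sample_sheet`,
#'   `peaks`, `genome`, `pfm`, `chrom_sizes`, and optionally `telomeres`.
#' @param out_dir output directory.
#' @return invisibly, a list with `sites`, `fits`, `matrix`, `samples`,
#'   `cascade`, `outliers`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  need <- c("sample_sheet", "peaks", "genome", "pfm", "chrom_sizes")
  missing <- setdiff(need, names(p))
  if (length(missing)) stop("config$paths is missing: ", missing[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[divorseq] ", ...)

  log_msg("reading inputs")
  sheet <- utils::read.table(p$sample_sheet, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  peaks <- read_peaks(p$peaks)
  genome <- read_genome(p$genome)
  pwm <- pfm_to_pwm(read_pfm(p$pfm))
  chrom_sizes <- read_chrom_sizes(p$chrom_sizes)
  telomeres <- if (!is.null(p$telomeres)) read_fragments(p$telomeres) else NULL

  log_msg("quantifying ", nrow(sheet), " samples over ", nrow(peaks),
          " peaks")
  q <- quantify_samples(sheet, peaks, chrom_sizes,
                        window_bp = config$window_bp,
                        half_width = config$peak_half_width,
                        target_fragments = config$target_fragments)

  outliers <- flag_outlier_samples(q$matrix, sheet$time_min, sheet$replicate,
                                   fold_threshold = config$outlier_fold)
  if (any(outliers$flagged))
    log_msg("flagged outlier samples: ",
            paste0("t", outliers$time_min[outliers$flagged], "_r",
                   outliers$replicate[outliers$flagged], collapse = ", "))

  log_msg("filtering sites")
  fs <- filter_sites(peaks, genome, pwm, fe_min = config$fe_min,
                     motif_flank = config$motif_flank,
                     min_score_frac = config$min_score_frac,
                     telomere_intervals = telomeres)
  log_msg("site cascade: ", paste(names(fs$cascade), fs$cascade,
                                  sep = "=", collapse = " -> "))

  log_msg("fitting decay model at ", nrow(fs$sites), " sites")
  mat <- q$matrix[fs$sites$id, , drop = FALSE]
  fa <- fit_all_sites(mat, sheet$time_min, sheet$replicate,
                      exclude = outliers$flagged)
  fits <- merge(fa$fits,
                fs$sites[, c("id", "best_midpoint", "best_strand",
                             "best_score_frac", "n_motifs")],
                by.x = "site_id", by.y = "id", sort = FALSE)

  utils::write.table(q$matrix, file.path(out_dir, "binding_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(fs$sites, file.path(out_dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fs$dropped, file.path(out_dir, "dropped_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(outliers, file.path(out_dir, "sample_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_samples = nrow(sheet),
    n_outlier_samples = sum(outliers$flagged),
    cascade = as.list(fs$cascade),
    n_sites_fit = fa$summary$n_sites,
    n_converged = fa$summary$n_converged,
    median_r2 = fa$summary$median_r2,
    min_r2 = fa$summary$min_r2,
    residence_time_range_min = fa$summary$residence_time_range,
    config = config[setdiff(names(config), "paths")])
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sites = fs$sites, dropped = fs$dropped, fits = fits,
                 matrix = q$matrix, samples = q$samples,
                 cascade = fs$cascade, outliers = outliers,
                 summary = summary))
}
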