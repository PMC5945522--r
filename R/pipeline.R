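#' Pipeline configuration
#'
#' Bundles file paths, stage thresholds and the seed for an end-to-end
#' run. Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param outdir output directory for stage results and the manifest.
#' @param counts,metadata,ct optional input TSV paths; when `NULL` the
#'   run starts from a simulated dataset (`sim`).
#' @param sim a [simulation_config()] used when no input files are given.
#' @param min_total low-count filter threshold (summed reads).
#' @param fdr_max,min_mean,pp_min candidate-panel thresholds.
#' @param normalizer_min_reads,normalizer_max_log2_sd,normalizer_fc_low,normalizer_fc_high,normalizer_top_k
#'   endogenous-control selection thresholds.
#' @param max_sv,n_perm,use_sv surrogate-variable settings.
#' @param trend_cases_only run the trend test on cases only as well.
#' @param panel optional explicit miRNA panel for the model comparison;
#'   default is the miRNAs shared by all subtype panels.
#' @param seed integer seed controlling simulation and permutations.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("urimir_run_"),
                            counts = NULL, metadata = NULL, ct = NULL,
                            sim = simulation_config(),
                            min_total = 20,
                            fdr_max = 0.05, min_mean = 300, pp_min = 0.70,
                            normalizer_min_reads = 2,
                            normalizer_max_log2_sd = 12,
                            normalizer_fc_low = -4,
                            normalizer_fc_high = 7,
                            normalizer_top_k = 2,
                            max_sv = 5, n_perm = 100, use_sv = TRUE,
                            trend_cases_only = FALSE,
                            panel = NULL,
                            seed = 1L) {
  stopifnot(min_total >= 0, fdr_max >= 0, fdr_max <= 1,
            min_mean >= 0, pp_min >= 0, pp_min <= 1,
            max_sv >= 0, n_perm >= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate and write the pipeline's input dataset
#'
#' @param config a [pipeline_config()].
#' @return list of written paths (counts, metadata, ct).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  sim$seed <- config$seed
  write_simulated_dataset(sim, file.path(config$outdir, "input"))
}

#' Discovery phase: filtering, batch estimation, DE and PP tracks,
#' candidate panels and endogenous-control selection
#'
#' @param config a [pipeline_config()].
#' @param counts a count matrix.
#' @param meta a [cohort_metadata()] table.
#' @return list with `filtered` counts, `sf`, `sv`, per-subtype `de`,
#'   `pp` and `panels`, the `overlap` report and `normalizers`.
#' @export
run_discovery <- function(config, counts, meta) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- file.path(config$outdir, "discovery")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  filtered <- filter_low_counts(counts, config$min_total)
  stage_log("filter", n_in = nrow(counts), n_kept = nrow(filtered),
            min_total = config$min_total)
  sf <- size_factors(filtered)
  sv <- if (config$use_sv && config$max_sv > 0)
    estimate_sv(filtered, meta, max_sv = config$max_sv,
                n_perm = config$n_perm, seed = config$seed, sf = sf)
  else NULL
  stage_log("surrogate_variables", n_sv = if (is.null(sv)) 0L else sv$n_sv)

  subtypes <- intersect(setdiff(BC_CLASSES, "control"),
                        as.character(unique(meta$class)))
  de <- list(); pp <- list(); panels <- list()
  for (s in subtypes) {
    de[[s]] <- nb_wald_test(filtered, meta, s, sv = sv)
    pp[[s]] <- predictive_power(filtered, meta, s)
    panels[[s]] <- build_panel(de[[s]], pp[[s]],
                               fdr_max = config$fdr_max,
                               min_mean = config$min_mean,
                               pp_min = config$pp_min)
    stage_log("comparison", subtype = s,
              n_de = panels[[s]]$n_de, n_pp = panels[[s]]$n_pp,
              n_overlap = panels[[s]]$n_overlap)
    utils::write.table(de[[s]],
                       file.path(outdir, paste0("de_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pp[[s]],
                       file.path(outdir, paste0("pp_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(panels[[s]]$members,
                       file.path(outdir, paste0("panel_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  overlap <- if (length(panels) >= 2) cross_subtype_overlap(panels) else NULL

  normalizers <- select_normalizers(
    filtered, sf = sf,
    min_reads = config$normalizer_min_reads,
    max_log2_sd = config$normalizer_max_log2_sd,
    fc_low = config$normalizer_fc_low,
    fc_high = config$normalizer_fc_high,
    top_k = config$normalizer_top_k)
  stage_log("normalizers", selected = paste(normalizers$selected,
                                            collapse = ","))
  utils::write.table(normalizers$stats[normalizers$stats$pass, ],
                     file.path(outdir, "normalizers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(filtered = filtered, sf = sf, sv = sv, de = de, pp = pp,
       panels = panels, overlap = overlap, normalizers = normalizers)
}

#' Validation phase: qPCR statistics and model comparison
#'
#' @param config a [pipeline_config()].
#' @param ct a [ct_matrix()].
#' @param meta a [cohort_metadata()] table.
#' @param panels per-subtype [build_panel()] results from discovery (or a
#'   character vector of assay ids used for every subtype).
#' @param controls optional endogenous-control assay ids overriding the
#'   ones designated in `ct`.
#' @return list with `dct`, per-subtype `log2fc` and `association`
#'   tables, `trend` (and `trend_cases` when requested) and the
#'   `model_comparison`.
#' @export
run_validation <- function(config, ct, meta, panels, controls = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- file.path(config$outdir, "validation")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(controls))
    ct <- ct_matrix(unclass(ct), controls = controls,
                    spike_in = attr(ct, "spike_in"))
  if (!is.null(attr(ct, "spike_in"))) {
    qc <- spike_in_qc(ct)
    if (!qc$ok) warning(sprintf(
      "spike-in Ct SD %.2f exceeds the QC threshold", qc$sd))
  }
  dct <- delta_ct(ct)

  subtypes <- intersect(setdiff(BC_CLASSES, "control"),
                        as.character(unique(meta$class)))
  log2fc <- list(); assoc <- list()
  for (s in subtypes) {
    log2fc[[s]] <- ddct_log2fc(dct, meta, s)
    assoc[[s]] <- association_test(dct, meta, s)
    tab <- merge(log2fc[[s]][, c("assay_id", "log2fc")], assoc[[s]],
                 by = "assay_id")
    utils::write.table(tab, file.path(outdir, paste0("qpcr_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  trend <- trend_test(dct, meta)
  utils::write.table(trend, file.path(outdir, "trend.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trend_cases <- if (config$trend_cases_only)
    trend_test(dct, meta, cases_only = TRUE) else NULL

  panel_ids <- config$panel
  if (is.null(panel_ids)) {
    panel_ids <- if (is.character(panels)) panels
    else if (length(panels) >= 2)
      cross_subtype_overlap(panels)$all_way
    else panels[[1]]$members$mirna_id
  }
  panel_ids <- intersect(panel_ids, colnames(dct))
  comparison <- NULL
  if (length(panel_ids) >= 1) {
    comparison <- compare_models(dct, meta, panel_ids)
    stage_log("model_comparison", panel = paste(panel_ids, collapse = ","),
              auc0 = round(comparison$auc0, 3),
              auc1 = round(comparison$auc1, 3),
              delong_p = signif(comparison$delong_p, 3))
    jsonlite::write_json(
      list(panel = panel_ids, auc0 = comparison$auc0, ci0 = comparison$ci0,
           auc1 = comparison$auc1, ci1 = comparison$ci1,
           delong_p = comparison$delong_p, n_cases = comparison$n_cases,
           n_controls = comparison$n_controls),
      file.path(outdir, "model_comparison.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(dct = dct, log2fc = log2fc, association = assoc, trend = trend,
       trend_cases = trend_cases, model_comparison = comparison)
}

#' Run the full pipeline
#'
#' Simulates (or reads) the input dataset, runs the discovery phase on
#' the count matrix, the validation phase on the Ct table, and writes a
#' manifest recording the configuration and seed so the run can be
#' reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @return list with `inputs` (paths), `discovery`, `validation` and the
#'   manifest path.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  external <- !is.null(config$counts)
  if (external) {
    if (is.null(config$metadata) || is.null(config$ct))
      input_error("counts, metadata and ct paths must be given together")
    paths <- list(counts = config$counts, metadata = config$metadata,
                  ct = config$ct)
  } else {
    paths <- run_simulate(config)
  }
  for (p in paths) if (!file.exists(p))
    input_error(sprintf("input file '%s' does not exist", p))

  counts <- read_counts(paths$counts)
  meta <- read_metadata(paths$metadata)
  sim <- config$sim
  controls <- if (external) NULL else sim$planted_stable
  ct <- read_ct(paths$ct,
                controls = controls %||% character(),
                spike_in = if (!external) "UniSp6" else NULL)

  discovery <- run_discovery(config, counts, meta)
  ctrl_ids <- discovery$normalizers$selected
  if (length(ctrl_ids) == 0 || !all(ctrl_ids %in% colnames(ct)))
    ctrl_ids <- attr(ct, "controls")
  validation <- run_validation(config, ct, meta, discovery$panels,
                               controls = ctrl_ids)

  manifest <- list(
    package_version = as.character(utils::packageVersion("urimir")),
    seed = config$seed,
    inputs = paths,
    thresholds = config[c("min_total", "fdr_max", "min_mean", "pp_min",
                          "normalizer_min_reads", "normalizer_max_log2_sd",
                          "normalizer_fc_low", "normalizer_fc_high",
                          "normalizer_top_k", "max_sv", "n_perm",
                          "use_sv")],
    simulated = !external)
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  list(inputs = paths, discovery = discovery, validation = validation,
       manifest = manifest_path)
}

stage_log <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  message(msg)
}
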