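#' Pipeline configuration
#'
#' Collects every stage's options in one validated list; round-trips
#' through YAML so a run is fully described by a single text file.
#' Defaults equal the analysis settings the pipeline targets (QC defaults,
#' alpha 0.05, times 0/4/24 h, 8 animals per group).
#'
#' @param rcc_dir Directory of RCC lane files (NULL when a run set is
#'   passed to [run_pipeline()] directly).
#' @param codeset_path Codeset TSV (NULL = packaged panel).
#' @param design_path Study-design CSV.
#' @param out_dir Output directory.
#' @param thresholds [qc_thresholds()] or a named list of overrides.
#' @param drop_qc_failures Drop QC-failing lanes before normalization?
#' @param background_method Background rule (see [background_cutoff()]).
#' @param model [model_spec()] or a named list of overrides.
#' @param seed Integer seed recorded with the run.
#' @return A list of class `ncountr_pipeline_config`.
#' @export
pipeline_config <- function(rcc_dir = NULL, codeset_path = NULL,
                            design_path = NULL, out_dir = "ncountr_out",
                            thresholds = qc_thresholds(),
                            drop_qc_failures = FALSE,
                            background_method = "max_plus_2sd",
                            model = model_spec(), seed = 1) {
  if (!inherits(thresholds, "ncountr_qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  }
  if (!inherits(model, "ncountr_model_spec")) {
    model <- do.call(model_spec, as.list(model))
  }
  structure(list(rcc_dir = rcc_dir, codeset_path = codeset_path,
                 design_path = design_path, out_dir = out_dir,
                 thresholds = thresholds,
                 drop_qc_failures = isTRUE(drop_qc_failures),
                 background_method = background_method,
                 model = model, seed = as.integer(seed)),
            class = "ncountr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()]'s fields
#'   (`thresholds` and `model` as nested maps).
#' @return A `ncountr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

fmt9 <- function(x) {
  if (is.numeric(x)) signif(x, 9) else x
}

write_csv_stable <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' QC, normalization and per-gene modelling in sequence, writing
#' `qc_report.csv`, `factors.csv`, `normalized.tsv`, `lsmeans.csv`,
#' `contrasts.csv` and `run_log.txt` under the configured output
#' directory. Numeric output is fixed at 9 significant digits so reruns on
#' identical input are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param runset Optional in-memory `ncountr_runset`; otherwise lanes are
#'   read from `config$rcc_dir`.
#' @return Invisibly, a list with the QC report, expression object and
#'   differential-expression result.
#' @export
run_pipeline <- function(config = pipeline_config(), runset = NULL) {
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  if (is.null(runset)) {
    if (is.null(config$rcc_dir) || is.null(config$design_path)) {
      stop_ncountr("config needs rcc_dir and design_path (or pass a runset)",
                   "ncountr_validation_error")
    }
    codeset <- if (is.null(config$codeset_path)) default_codeset() else
      load_codeset(config$codeset_path)
    files <- sort(list.files(config$rcc_dir, pattern = "\\.[Rr][Cc][Cc]$",
                             full.names = TRUE))
    lanes <- lapply(files, read_rcc)
    runset <- assemble_runset(lanes, codeset, read_design(config$design_path))
    say("stage=load lanes=", length(lanes))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  th <- config$thresholds
  say("stage=qc fov_min=", th$fov_pct_min, " bd=[",
      th$binding_density_min, ",", th$binding_density_max,
      "] linearity_min=", th$linearity_min, " lod_sd=", th$lod_sd_multiplier)
  qc <- run_qc(runset, th)
  write_csv_stable(qc, file.path(config$out_dir, "qc_report.csv"))
  say("stage=qc lanes=", nrow(qc), " passed=", sum(qc$overall_pass))

  em <- normalize_runset(runset, th,
                         drop_qc_failures = config$drop_qc_failures,
                         background_method = config$background_method)
  write_csv_stable(em$factors, file.path(config$out_dir, "factors.csv"))
  wide <- expr_values(em, c("endogenous", "reference"), "wide")
  norm_out <- dplyr::mutate(wide, dplyr::across(dplyr::where(is.numeric),
                                                fmt9))
  utils::write.table(norm_out, file.path(config$out_dir, "normalized.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("stage=normalize samples=", dplyr::n_distinct(em$values$sample_id))

  de <- fit_all_genes(em, spec = config$model)
  write_csv_stable(de$lsmeans, file.path(config$out_dir, "lsmeans.csv"))
  write_csv_stable(de$contrasts, file.path(config$out_dir, "contrasts.csv"))
  say("stage=fit genes=", length(de$fits), " skipped=", nrow(de$skipped),
      " alpha=", config$model$alpha)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(qc = qc, expr = em, de = de))
}

#' Write a run set to disk as RCC files plus design and codeset tables
#'
#' @param runset A `ncountr_runset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the RCC file paths.
#' @export
write_runset <- function(runset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(runset$design$sample_id, function(sid) {
    lane <- list(
      sample_id = sid,
      attributes = runset$lane_attrs[runset$lane_attrs$sample_id == sid,
                                     -1],
      counts = runset$counts[runset$counts$sample_id == sid,
                             c("name", "count")]
    )
    class(lane) <- "ncountr_lane"
    p <- file.path(dir, paste0(sid, ".rcc"))
    write_rcc(lane, runset$codeset, p)
    p
  }, "")
  utils::write.csv(runset$design, file.path(dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(runset$codeset, file.path(dir, "codeset.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(unname(paths))
}
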