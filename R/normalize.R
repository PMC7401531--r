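#' Background cutoff from negative-control counts
#'
#' The default rule subtracts the highest negative control plus two sample
#' standard deviations of the negatives; `mean_plus_2sd` substitutes the
#' negative-control mean for the maximum.
#'
#' @param neg_counts Numeric vector of negative-control counts (>= 2).
#' @param method `"max_plus_2sd"` (default) or `"mean_plus_2sd"`.
#' @param sd_multiplier SD multiplier (default 2).
#' @return The cutoff as a single number.
#' @export
#' @examples
#' background_cutoff(c(4, 6, 8))  # 8 + 2*2 = 12
background_cutoff <- function(neg_counts,
                              method = c("max_plus_2sd", "mean_plus_2sd"),
                              sd_multiplier = 2) {
  method <- match.arg(method)
  if (length(neg_counts) < 2) {
    stop_ncountr("need >= 2 negative-control counts",
                 "ncountr_insufficient_data_error")
  }
  base <- if (method == "max_plus_2sd") max(neg_counts) else mean(neg_counts)
  base + sd_multiplier * stats::sd(neg_counts)
}

expr_stages <- c("raw", "background_subtracted", "positive_normalized",
                 "fully_normalized")

# Build the raw-stage expression object from a run set. Gene probes
# (endogenous + reference) populate `values`; control counts are kept
# aside for factor computation.
expr_from_runset <- function(runset) {
  gene_names <- probes_of_class_multi(runset$codeset,
                                      c("endogenous", "reference"))
  classes <- stats::setNames(as.character(runset$codeset$probe_class),
                             runset$codeset$name)
  values <- runset$counts |>
    dplyr::filter(.data$name %in% gene_names) |>
    dplyr::mutate(probe_class = unname(classes[.data$name])) |>
    dplyr::rename(value = "count")
  controls <- runset$counts |>
    dplyr::filter(!.data$name %in% gene_names) |>
    dplyr::mutate(probe_class = unname(classes[.data$name]))
  factors <- tibble::tibble(sample_id = runset$design$sample_id,
                            background_cutoff = NA_real_,
                            positive_factor = NA_real_,
                            reference_factor = NA_real_)
  structure(list(values = values, controls = controls,
                 codeset = runset$codeset, design = runset$design,
                 stage = "raw", factors = factors),
            class = "ncountr_expr")
}

require_stage <- function(em, stage) {
  if (!identical(em$stage, stage)) {
    stop_ncountr(paste0("pipeline order violation: expected stage '", stage,
                        "', got '", em$stage, "'"),
                 "ncountr_pipeline_order_error")
  }
}

#' Subtract per-lane background from gene counts
#'
#' Replaces each gene-probe count by max(0, count - cutoff). Cutoffs
#' default to [background_cutoff()] of each lane's negative controls.
#' Spike-in controls are not background-subtracted.
#'
#' @param em A raw-stage `ncountr_expr` (from [normalize_runset()]'s
#'   internals or [expr_values()] workflows).
#' @param cutoffs Optional tibble (`sample_id`, `background_cutoff`)
#'   overriding the computed cutoffs.
#' @param method Passed to [background_cutoff()].
#' @return The expression object at stage `background_subtracted`.
#' @export
subtract_background <- function(em, cutoffs = NULL,
                                method = c("max_plus_2sd", "mean_plus_2sd")) {
  require_stage(em, "raw")
  method <- match.arg(method)
  if (is.null(cutoffs)) {
    cutoffs <- em$controls |>
      dplyr::filter(.data$probe_class == "negative") |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(background_cutoff =
                         background_cutoff(.data$count, method = method),
                       .groups = "drop")
  }
  em$values <- em$values |>
    dplyr::left_join(cutoffs, by = "sample_id") |>
    dplyr::mutate(value = pmax(0, .data$value - .data$background_cutoff)) |>
    dplyr::select(-"background_cutoff")
  em$factors$background_cutoff <-
    cutoffs$background_cutoff[match(em$factors$sample_id, cutoffs$sample_id)]
  em$stage <- "background_subtracted"
  em
}

#' Positive-control normalization factors
#'
#' Per-lane factor = (arithmetic mean over lanes of the per-lane geometric
#' mean of raw positive-control counts) / (this lane's geometric mean).
#'
#' @param x A `ncountr_runset` or `ncountr_expr`.
#' @return Tibble `sample_id`, `positive_factor`.
#' @export
positive_factors <- function(x) {
  controls <- if (inherits(x, "ncountr_runset")) {
    classes <- stats::setNames(as.character(x$codeset$probe_class),
                               x$codeset$name)
    dplyr::mutate(x$counts, probe_class = unname(classes[.data$name]))
  } else {
    x$controls
  }
  pos <- dplyr::filter(controls, .data$probe_class == "positive")
  zero <- dplyr::filter(pos, .data$count <= 0)
  if (nrow(zero) > 0) {
    stop_ncountr(paste0("zero positive-control count: lane ",
                        zero$sample_id[1], ", probe ", zero$name[1]),
                 "ncountr_value_error")
  }
  g <- pos |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(g = geo_mean(.data$count), .groups = "drop")
  tibble::tibble(sample_id = g$sample_id,
                 positive_factor = mean(g$g) / g$g)
}

apply_positive_normalization <- function(em) {
  require_stage(em, "background_subtracted")
  pf <- positive_factors(em)
  em$values <- em$values |>
    dplyr::left_join(pf, by = "sample_id") |>
    dplyr::mutate(value = .data$value * .data$positive_factor) |>
    dplyr::select(-"positive_factor")
  em$factors$positive_factor <-
    pf$positive_factor[match(em$factors$sample_id, pf$sample_id)]
  em$stage <- "positive_normalized"
  em
}

#' Reference-gene (biological) normalization factors
#'
#' Same mean-of-geometric-means construction as [positive_factors()],
#' computed on the reference genes (GAPDH, GUSB, YWHAZ in the packaged
#' panel) at the positive-normalized stage.
#'
#' @param em A `ncountr_expr` at stage `positive_normalized`.
#' @param reference_genes Reference probe names; defaults to the codeset's
#'   `reference` class.
#' @return Tibble `sample_id`, `reference_factor`.
#' @export
reference_factors <- function(em, reference_genes = NULL) {
  require_stage(em, "positive_normalized")
  reference_genes <- reference_genes %||%
    probes_of_class(em$codeset, "reference")
  ref <- dplyr::filter(em$values, .data$name %in% reference_genes)
  bad <- dplyr::filter(ref, .data$value <= 0)
  if (nrow(bad) > 0) {
    stop_ncountr(paste0("nonpositive reference value: lane ",
                        bad$sample_id[1], ", gene ", bad$name[1],
                        " (lane unnormalizable)"),
                 "ncountr_value_error")
  }
  g <- ref |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(g = geo_mean(.data$value), .groups = "drop")
  tibble::tibble(sample_id = g$sample_id,
                 reference_factor = mean(g$g) / g$g)
}

apply_reference_normalization <- function(em, reference_genes = NULL) {
  rf <- reference_factors(em, reference_genes)
  em$values <- em$values |>
    dplyr::left_join(rf, by = "sample_id") |>
    dplyr::mutate(value = .data$value * .data$reference_factor) |>
    dplyr::select(-"reference_factor")
  em$factors$reference_factor <-
    rf$reference_factor[match(em$factors$sample_id, rf$sample_id)]
  em$stage <- "fully_normalized"
  em
}

#' Run the three-step normalization pipeline
#'
#' Background minimisation, then positive-control normalization, then
#' reference-gene normalization, in that fixed order. Optionally drops
#' lanes failing QC first.
#'
#' @param runset A `ncountr_runset`.
#' @param thresholds [qc_thresholds()], used only when
#'   `drop_qc_failures = TRUE`.
#' @param drop_qc_failures Drop lanes with `overall_pass = FALSE`?
#' @param background_method Passed to [background_cutoff()].
#' @return A `ncountr_expr` at stage `fully_normalized` with per-lane
#'   factors recorded.
#' @export
normalize_runset <- function(runset, thresholds = qc_thresholds(),
                             drop_qc_failures = FALSE,
                             background_method = c("max_plus_2sd",
                                                   "mean_plus_2sd")) {
  background_method <- match.arg(background_method)
  if (drop_qc_failures) {
    qc <- run_qc(runset, thresholds)
    keep <- qc$sample_id[qc$overall_pass]
    if (length(keep) == 0) {
      stop_ncountr("no lanes remain after dropping QC failures",
                   "ncountr_pipeline_error")
    }
    runset$design <- dplyr::filter(runset$design, .data$sample_id %in% keep)
    runset$lane_attrs <- dplyr::filter(runset$lane_attrs,
                                       .data$sample_id %in% keep)
    runset$counts <- dplyr::filter(runset$counts, .data$sample_id %in% keep)
  }
  expr_from_runset(runset) |>
    subtract_background(method = background_method) |>
    apply_positive_normalization() |>
    apply_reference_normalization()
}

#' Extract normalized values
#'
#' @param em A `ncountr_expr`.
#' @param classes Probe classes to keep (default endogenous genes only).
#' @param format `"long"` (sample_id, gene, value) or `"wide"` (genes in
#'   rows, one column per sample).
#' @return A tibble.
#' @export
expr_values <- function(em, classes = "endogenous",
                        format = c("long", "wide")) {
  format <- match.arg(format)
  v <- em$values |>
    dplyr::filter(.data$probe_class %in% classes) |>
    dplyr::transmute(sample_id = .data$sample_id, gene = .data$name,
                     value = .data$value)
  if (format == "long") return(v)
  tidyr::pivot_wider(v, names_from = "sample_id", values_from = "value")
}

#' @export
print.ncountr_expr <- function(x, ...) {
  cat("<ncountr_expr> stage:", x$stage, "-",
      dplyr::n_distinct(x$values$name), "genes x",
      dplyr::n_distinct(x$values$sample_id), "samples\n")
  invisible(x)
}
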