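#' Lane QC thresholds
#'
#' The four default lane quality-control settings: imaging (percentage of
#' requested fields of view scanned; lanes strictly below 75 fail), binding
#' density (inclusive range 0.1-2.25 probe spots per square micron),
#' positive-control linearity (squared correlation of log2 counts against
#' log2 spike-in concentration; strictly below 0.95 fails) and limit of
#' detection (POS_E must strictly exceed mean + 2 SD of the negative
#' controls).
#'
#' @param fov_pct_min Minimum percentage of fields of view counted.
#' @param binding_density_min,binding_density_max Inclusive density bounds.
#' @param linearity_min Minimum positive-control r-squared.
#' @param lod_sd_multiplier SD multiplier k in the mean + k*SD LOD cutoff.
#' @return A list of class `ncountr_qc_thresholds`.
#' @export
qc_thresholds <- function(fov_pct_min = 75,
                          binding_density_min = 0.1,
                          binding_density_max = 2.25,
                          linearity_min = 0.95,
                          lod_sd_multiplier = 2) {
  stopifnot(fov_pct_min > 0, fov_pct_min <= 100,
            binding_density_min < binding_density_max,
            linearity_min > 0, linearity_min <= 1,
            lod_sd_multiplier >= 0)
  structure(list(fov_pct_min = fov_pct_min,
                 binding_density_min = binding_density_min,
                 binding_density_max = binding_density_max,
                 linearity_min = linearity_min,
                 lod_sd_multiplier = lod_sd_multiplier),
            class = "ncountr_qc_thresholds")
}

#' Imaging QC
#'
#' @param attrs One-row lane-attributes tibble (`fov_requested`,
#'   `fov_counted`).
#' @param thresholds [qc_thresholds()].
#' @return Tibble with `fov_pct` and `fov_pass`.
#' @export
imaging_qc <- function(attrs, thresholds = qc_thresholds()) {
  if (any(attrs$fov_requested <= 0)) {
    stop_ncountr("fov_requested must be positive", "ncountr_value_error")
  }
  fov_pct <- 100 * attrs$fov_counted / attrs$fov_requested
  tibble::tibble(fov_pct = fov_pct,
                 fov_pass = fov_pct >= thresholds$fov_pct_min)
}

#' Binding-density QC
#' @inheritParams imaging_qc
#' @return Tibble with `binding_density` and `bd_pass`.
#' @export
binding_density_qc <- function(attrs, thresholds = qc_thresholds()) {
  bd <- attrs$binding_density
  tibble::tibble(binding_density = bd,
                 bd_pass = bd >= thresholds$binding_density_min &
                   bd <= thresholds$binding_density_max)
}

#' Positive-control linearity QC
#'
#' Squared Pearson correlation between log2(count + 1) and log2
#' concentration over the positive-control ladder.
#'
#' @param lane A `ncountr_lane`, or a named count vector.
#' @param codeset Codeset tibble (supplies positive probes and
#'   concentrations).
#' @inheritParams imaging_qc
#' @return Tibble with `linearity_r2` and `linearity_pass`.
#' @export
linearity_qc <- function(lane, codeset, thresholds = qc_thresholds()) {
  counts <- lane_count_vector(lane)
  pos <- codeset[codeset$probe_class == "positive", ]
  pos <- pos[pos$name %in% names(counts), ]
  if (nrow(pos) < 3 || dplyr::n_distinct(pos$concentration_fM) < 3) {
    stop_ncountr("need >= 3 positive probes with distinct concentrations",
                 "ncountr_insufficient_data_error")
  }
  x <- log2(pos$concentration_fM)
  y <- log2(counts[pos$name] + 1)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  tibble::tibble(linearity_r2 = r2,
                 linearity_pass = r2 >= thresholds$linearity_min)
}

#' Limit-of-detection QC
#'
#' POS_E (spiked at 0.5 fM, the nominal limit of detection) must strictly
#' exceed mean + k*SD of the negative-control counts (sample SD).
#'
#' @inheritParams linearity_qc
#' @return Tibble with `lod_margin` (POS_E count minus cutoff) and
#'   `lod_pass`.
#' @export
lod_qc <- function(lane, codeset, thresholds = qc_thresholds()) {
  counts <- lane_count_vector(lane)
  negs <- intersect(probes_of_class(codeset, "negative"), names(counts))
  if (length(negs) < 2) {
    stop_ncountr("need >= 2 negative-control probes",
                 "ncountr_insufficient_data_error")
  }
  if (!"POS_E" %in% names(counts)) {
    stop_ncountr("POS_E probe absent from lane",
                 "ncountr_insufficient_data_error")
  }
  neg <- counts[negs]
  cutoff <- mean(neg) + thresholds$lod_sd_multiplier * stats::sd(neg)
  margin <- unname(counts[["POS_E"]] - cutoff)
  tibble::tibble(lod_margin = margin, lod_pass = margin > 0)
}

lane_count_vector <- function(lane) {
  if (inherits(lane, "ncountr_lane")) {
    stats::setNames(as.numeric(lane$counts$count), lane$counts$name)
  } else if (is.numeric(lane) && !is.null(names(lane))) {
    lane
  } else {
    stop_ncountr("lane must be an ncountr_lane or a named count vector",
                 "ncountr_value_error")
  }
}

#' Run all four lane QC checks over a run set
#'
#' Lanes failing any check are flagged, never removed here; dropping
#' failures is a normalization option.
#'
#' @param runset A `ncountr_runset`.
#' @param thresholds [qc_thresholds()].
#' @return A tibble of class `ncountr_qc_report`, one row per lane:
#'   metric values, the four pass flags and `overall_pass` (their
#'   conjunction).
#' @export
run_qc <- function(runset, thresholds = qc_thresholds()) {
  if (nrow(runset$design) == 0) {
    out <- tibble::tibble(sample_id = character(), fov_pct = numeric(),
                          fov_pass = logical(), binding_density = numeric(),
                          bd_pass = logical(), linearity_r2 = numeric(),
                          linearity_pass = logical(), lod_margin = numeric(),
                          lod_pass = logical(), overall_pass = logical())
    class(out) <- c("ncountr_qc_report", class(out))
    return(out)
  }
  rows <- purrr::map_dfr(runset$design$sample_id, function(sid) {
    attrs <- runset$lane_attrs[runset$lane_attrs$sample_id == sid, ]
    cnt <- runset$counts[runset$counts$sample_id == sid, ]
    vec <- stats::setNames(cnt$count, cnt$name)
    res <- tryCatch(
      dplyr::bind_cols(
        imaging_qc(attrs, thresholds),
        binding_density_qc(attrs, thresholds),
        linearity_qc(vec, runset$codeset, thresholds),
        lod_qc(vec, runset$codeset, thresholds)
      ),
      ncountr_error = function(e) {
        stop_ncountr(paste0("lane ", sid, ": ", conditionMessage(e)),
                     class(e)[1])
      }
    )
    dplyr::mutate(res, sample_id = sid, .before = 1)
  })
  out <- dplyr::mutate(rows,
                       overall_pass = .data$fov_pass & .data$bd_pass &
                         .data$linearity_pass & .data$lod_pass)
  class(out) <- c("ncountr_qc_report", class(out))
  out
}

#' @export
#' @method autoplot ncountr_qc_report
autoplot.ncountr_qc_report <- function(object, ...) {
  long <- object |>
    dplyr::select("sample_id", "fov_pct", "binding_density",
                  "linearity_r2", "lod_margin", "overall_pass") |>
    tidyr::pivot_longer(cols = c("fov_pct", "binding_density",
                                 "linearity_r2", "lod_margin"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$value,
                                     colour = .data$overall_pass)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "lane passes") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
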