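#' Read a study-design table
#'
#' @param path CSV with header `sample_id,animal_id,group,time_h`, or a data
#'   frame with those columns.
#' @return A validated design tibble; `group` is a factor with levels
#'   `control`, `treatment`.
#' @export
read_design <- function(path) {
  d <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  need <- c("sample_id", "animal_id", "group", "time_h")
  if (!all(need %in% names(d))) {
    stop_ncountr(paste0("design table needs columns ",
                        paste(need, collapse = ", ")),
                 "ncountr_format_error")
  }
  d <- dplyr::mutate(d,
                     group = factor(as.character(.data$group),
                                    levels = c("control", "treatment")),
                     time_h = as.numeric(.data$time_h))
  if (anyNA(d$group)) {
    stop_ncountr("group must be 'control' or 'treatment'",
                 "ncountr_value_error")
  }
  if (anyDuplicated(d[c("animal_id", "time_h")])) {
    stop_ncountr("duplicate (animal_id, time_h) pairs in design",
                 "ncountr_consistency_error")
  }
  multi <- d |>
    dplyr::distinct(.data$animal_id, .data$group) |>
    dplyr::count(.data$animal_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_ncountr(paste0("animal(s) assigned to more than one group: ",
                        paste(multi$animal_id, collapse = ", ")),
                 "ncountr_consistency_error")
  }
  d
}

#' Assemble lanes, codeset and design into a run set
#'
#' Joins a collection of RCC lanes to the study design and codeset,
#' validating congruence: every lane must have a design row and must count
#' only codeset probes. Lanes are ordered deterministically by
#' (animal_id, time_h), so the result does not depend on input lane order.
#'
#' @param lanes List of `ncountr_lane` objects.
#' @param codeset Codeset tibble.
#' @param design Design tibble (see [read_design()]).
#' @return A list of class `ncountr_runset`: `codeset`, `design` (lane
#'   order), `lane_attrs` (one row per lane) and `counts` (long tibble
#'   `sample_id`, `name`, `count`).
#' @export
assemble_runset <- function(lanes, codeset, design) {
  design <- read_design(design)
  ids <- vapply(lanes, function(l) l$sample_id, "")
  if (anyDuplicated(ids)) {
    stop_ncountr("duplicate lane sample_ids", "ncountr_consistency_error")
  }
  orphans <- setdiff(ids, design$sample_id)
  if (length(orphans) > 0) {
    stop_ncountr(paste0("lane sample_id(s) absent from design: ",
                        paste(sort(orphans), collapse = ", ")),
                 "ncountr_join_error")
  }
  for (l in lanes) {
    unknown <- setdiff(l$counts$name, codeset$name)
    if (length(unknown) > 0) {
      stop_ncountr(paste0("lane ", l$sample_id, " counts unknown probe(s): ",
                          paste(unknown, collapse = ", ")),
                   "ncountr_consistency_error")
    }
  }

  design_used <- design |>
    dplyr::filter(.data$sample_id %in% ids) |>
    dplyr::arrange(.data$animal_id, .data$time_h)
  ord <- match(design_used$sample_id, ids)

  counts <- purrr::map_dfr(lanes[ord], function(l) {
    tibble::tibble(sample_id = l$sample_id, name = l$counts$name,
                   count = as.numeric(l$counts$count))
  })
  lane_attrs <- purrr::map_dfr(lanes[ord], function(l) {
    dplyr::mutate(l$attributes, sample_id = l$sample_id, .before = 1)
  })

  structure(list(codeset = codeset, design = design_used,
                 lane_attrs = lane_attrs, counts = counts),
            class = "ncountr_runset")
}

#' Counts as a probes-by-samples matrix
#' @param runset A `ncountr_runset`.
#' @param classes Probe classes to include (default all).
#' @return Numeric matrix, rows = probes (codeset order), cols = samples
#'   (design order).
#' @export
counts_matrix <- function(runset,
                          classes = c("endogenous", "reference",
                                      "positive", "negative")) {
  keep <- probes_of_class_multi(runset$codeset, classes)
  wide <- runset$counts |>
    dplyr::filter(.data$name %in% keep) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$name
  m[keep, runset$design$sample_id, drop = FALSE]
}

probes_of_class_multi <- function(codeset, classes) {
  codeset$name[as.character(codeset$probe_class) %in% classes]
}

#' @export
print.ncountr_runset <- function(x, ...) {
  cat("<ncountr_runset>", nrow(x$design), "lanes,",
      nrow(x$codeset), "probes,",
      dplyr::n_distinct(x$design$animal_id), "animals\n")
  invisible(x)
}
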