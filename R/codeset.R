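#' Load a codeset table
#'
#' Reads a delimited probe-panel table into a validated codeset tibble. The
#' table must carry columns `name`, `category` (or `probe_class`),
#' `accession`, `target_start`, `target_end` and, for spike-in positives,
#' `concentration_fM`. Categories containing "Reference" map to probe class
#' `reference`, "Positive"/"Negative control" to `positive`/`negative`, and
#' everything else (the cytokine and neuroactive-ligand panels) to
#' `endogenous`.
#'
#' @param path Path to a TSV/CSV file, or a data frame already in memory.
#' @param sep Field separator when `path` is a file (default tab).
#' @return A tibble of class `ncountr_codeset` with columns `name`,
#'   `probe_class`, `category`, `accession`, `target_start`, `target_end`,
#'   `concentration_fM`.
#' @export
#' @examples
#' cs <- default_codeset()
#' dplyr::count(cs, probe_class)
load_codeset <- function(path, sep = "\t") {
  tab <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    tibble::as_tibble(utils::read.delim(path, sep = sep,
                                        stringsAsFactors = FALSE,
                                        na.strings = character()))
  }
  need <- c("name", "accession", "target_start", "target_end")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop_ncountr(paste0("codeset table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "ncountr_format_error")
  }
  if (!"category" %in% names(tab)) tab$category <- tab$probe_class
  if (!"concentration_fM" %in% names(tab)) tab$concentration_fM <- 0

  if (anyDuplicated(tab$name)) {
    dups <- unique(tab$name[duplicated(tab$name)])
    stop_ncountr(paste0("duplicate probe name(s): ",
                        paste(dups, collapse = ", ")),
                 "ncountr_consistency_error")
  }
  tab$target_start <- suppressWarnings(as.integer(tab$target_start))
  tab$target_end <- suppressWarnings(as.integer(tab$target_end))
  if (anyNA(tab$target_start) || anyNA(tab$target_end)) {
    stop_ncountr("malformed target interval (non-integer start/end)",
                 "ncountr_value_error")
  }
  bad <- tab$target_end < tab$target_start
  if (any(bad)) {
    stop_ncountr(paste0("target_end < target_start for: ",
                        paste(tab$name[bad], collapse = ", ")),
                 "ncountr_value_error")
  }

  cs <- tab |>
    dplyr::mutate(probe_class = probe_class_from_category(.data$category)) |>
    dplyr::select("name", "probe_class", "category", "accession",
                  "target_start", "target_end", "concentration_fM")

  bad_conc <- (cs$probe_class == "positive") != (cs$concentration_fM > 0)
  if (any(bad_conc)) {
    stop_ncountr(paste0("concentration_fM must be > 0 exactly for positive ",
                        "probes; offending: ",
                        paste(cs$name[bad_conc], collapse = ", ")),
                 "ncountr_value_error")
  }
  class(cs) <- c("ncountr_codeset", class(cs))
  cs
}

probe_class_from_category <- function(category) {
  cls <- dplyr::case_when(
    grepl("reference", category, ignore.case = TRUE) ~ "reference",
    grepl("positive", category, ignore.case = TRUE) ~ "positive",
    grepl("negative", category, ignore.case = TRUE) ~ "negative",
    category %in% c("endogenous", "Endogenous") ~ "endogenous",
    TRUE ~ "endogenous"
  )
  factor(cls, levels = c("endogenous", "reference", "positive", "negative"))
}

#' The packaged probe panel
#'
#' The 15-gene bovine leukocyte panel (12 genes of interest across
#' pro-inflammatory cytokine, anti-inflammatory cytokine and neuroactive
#' ligand-receptor categories, plus the GAPDH/GUSB/YWHAZ reference trio)
#' together with the six-probe positive-control ladder (128, 32, 8, 2, 0.5,
#' 0.125 fM; POS_E at 0.5 fM is the nominal limit of detection) and six
#' negative-control probes.
#'
#' @return A `ncountr_codeset` tibble of 27 probes.
#' @export
default_codeset <- function() {
  load_codeset(system.file("extdata", "codeset_table1.tsv",
                           package = "ncountr", mustWork = TRUE))
}

#' Probe names of a given class
#' @param codeset A codeset tibble.
#' @param class_ One of "endogenous", "reference", "positive", "negative".
#' @return Character vector of probe names, in codeset order.
#' @export
probes_of_class <- function(codeset, class_) {
  codeset$name[codeset$probe_class == class_]
}
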