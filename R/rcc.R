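#' Read an RCC lane file
#'
#' Parses one nCounter reporter code count (RCC) export: a sectioned CSV
#' dialect with `<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>` and
#' `<Code_Summary>` blocks. The `Code_Summary` table holds one
#' (CodeClass, Name, Accession, Count) row per probe.
#'
#' @param input Path to an RCC file, or a character vector of its lines
#'   (a single string with embedded newlines is also accepted).
#' @return A list of class `ncountr_lane` with elements `sample_id`,
#'   `attributes` (one-row tibble: `lane_id`, `fov_requested`,
#'   `fov_counted`, `binding_density`, `cartridge_id`) and `counts`
#'   (tibble: `code_class`, `name`, `accession`, `count`).
#' @export
read_rcc <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) &&
               file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)

  section <- function(tag) {
    open <- which(lines == paste0("<", tag, ">"))
    close <- which(lines == paste0("</", tag, ">"))
    if (length(open) != 1 || length(close) != 1 || close < open) {
      stop_ncountr(paste0("RCC stream is missing section ", tag),
                   "ncountr_format_error")
    }
    list(body = lines[seq(open + 1, length.out = max(0, close - open - 1))],
         start = open)
  }

  kv <- function(body) {
    parts <- strsplit(body, ",", fixed = TRUE)
    keys <- vapply(parts, `[`, "", 1)
    vals <- vapply(parts, function(p) {
      if (length(p) >= 2) paste(p[-1], collapse = ",") else ""
    }, "")
    stats::setNames(vals, keys)
  }

  section("Header")  # presence required; content not interpreted
  samp <- kv(section("Sample_Attributes")$body)
  lane_sec <- section("Lane_Attributes")
  lane <- kv(lane_sec$body)
  code <- section("Code_Summary")

  if (length(code$body) < 1 ||
      code$body[1] != "CodeClass,Name,Accession,Count") {
    stop_ncountr("Code_Summary lacks the CodeClass,Name,Accession,Count header",
                 "ncountr_format_error")
  }
  rows <- strsplit(code$body[-1], ",", fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  bad_shape <- which(lengths(rows) != 4)
  if (length(bad_shape) > 0) {
    stop_ncountr(paste0("malformed Code_Summary row at line ",
                        code$start + 1 + bad_shape[1]),
                 "ncountr_format_error")
  }
  count_chr <- vapply(rows, `[`, "", 4)
  count_num <- suppressWarnings(as.numeric(count_chr))
  bad <- which(is.na(count_num) | count_num != floor(count_num) |
                 count_num < 0)
  if (length(bad) > 0) {
    stop_ncountr(paste0("non-integer count '", count_chr[bad[1]],
                        "' at line ", code$start + 1 + bad[1]),
                 "ncountr_value_error")
  }

  attributes <- tibble::tibble(
    lane_id = unname(lane["ID"]),
    fov_requested = as.integer(lane["FovCount"]),
    fov_counted = as.integer(lane["FovCounted"]),
    binding_density = as.numeric(lane["BindingDensity"]),
    cartridge_id = unname(lane["CartridgeID"])
  )
  if (!is.na(attributes$fov_counted) && !is.na(attributes$fov_requested) &&
      attributes$fov_counted > attributes$fov_requested) {
    stop_ncountr("FovCounted exceeds FovCount", "ncountr_value_error")
  }

  structure(
    list(
      sample_id = unname(samp["ID"]),
      attributes = attributes,
      counts = tibble::tibble(
        code_class = vapply(rows, `[`, "", 1),
        name = vapply(rows, `[`, "", 2),
        accession = vapply(rows, `[`, "", 3),
        count = as.integer(count_num)
      )
    ),
    class = "ncountr_lane"
  )
}

rcc_code_class <- function(probe_class) {
  c(endogenous = "Endogenous", reference = "Housekeeping",
    positive = "Positive", negative = "Negative")[as.character(probe_class)]
}

#' Write an RCC lane file
#'
#' Serializes a lane back to RCC text. Probe rows follow codeset order, so
#' output is byte-deterministic for a fixed input and round-trips through
#' [read_rcc()].
#'
#' @param lane A `ncountr_lane` (or a compatible list).
#' @param codeset Codeset tibble governing probe order and code classes.
#' @param path Optional file path; when given the text is also written there.
#' @return The RCC text as a single string, invisibly when `path` is given.
#' @export
write_rcc <- function(lane, codeset, path = NULL) {
  unknown <- setdiff(lane$counts$name, codeset$name)
  if (length(unknown) > 0) {
    stop_ncountr(paste0("lane references probe(s) absent from codeset: ",
                        paste(unknown, collapse = ", ")),
                 "ncountr_consistency_error")
  }
  cnt <- stats::setNames(lane$counts$count, lane$counts$name)
  at <- lane$attributes
  body <- vapply(seq_len(nrow(codeset)), function(i) {
    nm <- codeset$name[i]
    paste(rcc_code_class(codeset$probe_class[i]), nm, codeset$accession[i],
          if (nm %in% names(cnt)) cnt[[nm]] else 0L, sep = ",")
  }, "")
  txt <- paste(c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", lane$sample_id),
    "Owner,", "Comments,", "Date,", "GeneRLF,ncountr_panel", "SystemAPF,n.a.",
    "</Sample_Attributes>",
    "<Lane_Attributes>", paste0("ID,", at$lane_id),
    paste0("FovCount,", at$fov_requested),
    paste0("FovCounted,", at$fov_counted),
    "ScannerID,SCN01", "StagePosition,1",
    paste0("BindingDensity,", format(at$binding_density, digits = 15,
                                     scientific = FALSE, trim = TRUE)),
    paste0("CartridgeID,", at$cartridge_id),
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count", body,
    "</Code_Summary>", ""
  ), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @export
print.ncountr_lane <- function(x, ...) {
  cat("<ncountr_lane> sample", x$sample_id, "-", nrow(x$counts), "probes\n")
  print(x$attributes)
  invisible(x)
}
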