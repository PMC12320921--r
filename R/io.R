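# Delimited-text readers/writers for matrices, labels, panels, behavior.

#' Read a square connectivity matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited square numeric text, with an
#' optional first header row of region labels.  Labels can also be supplied
#' separately (one per line) via `labels_file`, which takes precedence.
#'
#' @param file Path to the matrix file.
#' @param modality `"SC"` or `"FC"`.
#' @param labels_file Optional path to a region-label file, one label per
#'   line.
#' @param subject_id,timepoint Scan identifiers attached to the result.
#' @return A [connectome_matrix()].
#' @export
read_connectome_matrix <- function(file, modality = c("SC", "FC"),
                                   labels_file = NULL,
                                   subject_id = NA_character_,
                                   timepoint = 1L) {
  modality <- match.arg(modality)
  first <- readLines(file, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- utils::read.table(file, header = has_header, sep = sep,
                           check.names = FALSE)
  w <- as.matrix(tab)
  storage.mode(w) <- "double"
  labels <- if (!is.null(labels_file)) {
    trimws(readLines(labels_file))
  } else if (has_header) {
    colnames(tab)
  } else {
    NULL
  }
  rownames(w) <- NULL
  connectome_matrix(w, labels, modality, subject_id, timepoint)
}

#' Write a connectome matrix as delimited text
#'
#' @param m A `connectome_matrix`.
#' @param file Output path.
#' @param sep Field separator (default comma).
#' @param header Write the region labels as a first header row?
#' @export
write_connectome_matrix <- function(m, file, sep = ",", header = TRUE) {
  utils::write.table(m$weights, file, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(file)
}

#' Write a cohort panel as CSV
#'
#' Columns: `subject_id`, `timepoint`, then one column per region.
#' @param panel A `cohort_panel`.
#' @param file Output path.
#' @export
write_cohort_panel <- function(panel, file) {
  df <- data.frame(subject_id = panel$subject_ids,
                   timepoint = panel$condition,
                   panel$values, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a cohort panel from CSV
#'
#' Expects the layout written by [write_cohort_panel()].
#' @param file Input path.
#' @param metric_name Label for the panel.
#' @return A `cohort_panel`.
#' @export
read_cohort_panel <- function(file, metric_name = "metric") {
  df <- utils::read.csv(file, check.names = FALSE)
  stopifnot(all(c("subject_id", "timepoint") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "timepoint")),
                       drop = FALSE])
  storage.mode(vals) <- "double"
  build_cohort_panel(vals, df$subject_id, df$timepoint, metric_name)
}

#' Read a behavior table from CSV
#'
#' Expected columns: `subject_id`, `timepoint`, `age`, plus score columns
#' (typically `sustained`, `selective`, `executive`; optional raw-count
#' columns are passed through untouched).
#' @param file Input path.
#' @return A data frame of class `behavior_table`.
#' @export
read_behavior_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  stopifnot(all(c("subject_id", "timepoint") %in% names(df)))
  as_behavior_table(df)
}

#' @rdname read_behavior_table
#' @param df Data frame with at least `subject_id` and `timepoint` columns.
#' @export
as_behavior_table <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  df$timepoint <- as.integer(df$timepoint)
  if ("selective" %in% names(df)) {
    bad <- df$selective[!is.na(df$selective)]
    if (any(bad < 0 | bad > 18)) {
      stop("selective attention scores must lie in [0, 18]", call. = FALSE)
    }
  }
  if ("executive" %in% names(df)) {
    bad <- df$executive[!is.na(df$executive)]
    if (any(bad > 0)) {
      stop("executive attention scores must be <= 0", call. = FALSE)
    }
  }
  class(df) <- c("behavior_table", "data.frame")
  df
}

# Align a behavior table to a panel's canonical row order; errors if any
# (subject, timepoint) scan is missing from the table.
align_behavior <- function(panel, behaviors) {
  key_b <- paste(behaviors$subject_id, behaviors$timepoint, sep = "\r")
  key_p <- paste(panel$subject_ids, panel$condition, sep = "\r")
  idx <- match(key_p, key_b)
  if (anyNA(idx)) {
    stop(sprintf("behavior table is missing scan(s): %s",
                 paste(utils::head(gsub("\r", " t", key_p[is.na(idx)]), 5),
                       collapse = ", ")), call. = FALSE)
  }
  behaviors[idx, , drop = FALSE]
}
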