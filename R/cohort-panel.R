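# CohortPanel: the stacked scans x regions matrix fed to PLS ("X").

#' Build a paired two-condition cohort panel
#'
#' Stacks per-scan regional metric vectors into the canonical PLS input: all
#' condition-1 (timepoint 1) rows first, then all condition-2 rows, with the
#' same subject order in both blocks.  Every subject must contribute exactly
#' one scan per condition; scalar metrics (e.g. the modularity statistic Q)
#' are allowed as one-column panels.
#'
#' @param values Numeric matrix (scans x regions) or vector of per-scan
#'   scalar values, one row/element per scan in the order of `subject_ids`.
#' @param subject_ids Subject identifier per scan.
#' @param timepoints Timepoint per scan (1 or 2).
#' @param metric_name Label for the stacked metric.
#' @return A `cohort_panel`: list with `values` (S x N matrix in canonical
#'   order), `subject_ids`, `condition`, `metric_name`.
#' @export
#' @examples
#' v <- matrix(rnorm(8), 4, 2)
#' build_cohort_panel(v, c("a", "b", "a", "b"), c(1, 1, 2, 2), "degree")
build_cohort_panel <- function(values, subject_ids, timepoints,
                               metric_name = "metric") {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, ncol = 1,
                     dimnames = list(NULL, metric_name))
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or vector", call. = FALSE)
  }
  s <- nrow(values)
  subject_ids <- as.character(subject_ids)
  timepoints <- as.integer(timepoints)
  if (length(subject_ids) != s || length(timepoints) != s) {
    stop("`subject_ids` and `timepoints` must have one entry per scan",
         call. = FALSE)
  }
  if (!all(timepoints %in% c(1L, 2L))) {
    stop("timepoints must be 1 or 2", call. = FALSE)
  }
  key <- paste(subject_ids, timepoints, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, timepoint) scans in input", call. = FALSE)
  }
  subs <- unique(subject_ids)
  has1 <- subs %in% subject_ids[timepoints == 1L]
  has2 <- subs %in% subject_ids[timepoints == 2L]
  unpaired <- subs[!(has1 & has2)]
  if (length(unpaired) > 0) {
    stop(sprintf("subject(s) missing a timepoint: %s",
                 paste(unpaired, collapse = ", ")), call. = FALSE)
  }
  i1 <- match(paste(subs, 1L, sep = "\r"), key)
  i2 <- match(paste(subs, 2L, sep = "\r"), key)
  ord <- c(i1, i2)
  out <- values[ord, , drop = FALSE]
  rownames(out) <- paste(subject_ids[ord], timepoints[ord], sep = "_t")
  structure(
    list(values = out,
         subject_ids = subject_ids[ord],
         condition = timepoints[ord],
         metric_name = metric_name),
    class = "cohort_panel"
  )
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat(sprintf("<cohort_panel> %s: %d scans (%d subjects x 2 conditions) x %d regions\n",
              x$metric_name, nrow(x$values),
              length(unique(x$subject_ids)), ncol(x$values)))
  invisible(x)
}

# Number of paired subjects in a panel.
panel_n_subjects <- function(panel) nrow(panel$values) / 2L

# Row indices of the two condition blocks.
panel_blocks <- function(panel) {
  n <- panel_n_subjects(panel)
  list(`1` = seq_len(n), `2` = n + seq_len(n))
}

# Rebuild a panel from a vector of subject indices (used by bootstrap and
# split-half resampling: both timepoints of a subject move together).
panel_subset_subjects <- function(panel, subject_idx) {
  n <- panel_n_subjects(panel)
  rows <- c(subject_idx, n + subject_idx)
  structure(
    list(values = panel$values[rows, , drop = FALSE],
         subject_ids = panel$subject_ids[rows],
         condition = panel$condition[rows],
         metric_name = panel$metric_name),
    class = "cohort_panel"
  )
}

# Replace the panel's value rows by a permutation of the full stack,
# keeping the condition/subject frame fixed (PLS permutation scheme).
panel_permute_rows <- function(panel, perm) {
  panel$values <- panel$values[perm, , drop = FALSE]
  panel
}
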