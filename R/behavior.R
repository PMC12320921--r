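# Attention-task scoring and behavior-table harmonization.

#' Score the sustained attention tasks
#'
#' Each modality (visual, auditory) is scored as correct responses minus
#' errors minus prompts; the total sustained attention score is the mean of
#' the two modality scores.  Each modality presents 30 targets, so correct
#' counts above 30 are rejected.
#'
#' @param visual,auditory Length-3 numeric vectors `(correct, errors,
#'   prompts)` of non-negative counts.
#' @return List with `visual`, `auditory`, `total`.
#' @export
#' @examples
#' score_sustained(c(25, 2, 1), c(20, 0, 0))  # visual 22, auditory 20, total 21
score_sustained <- function(visual, auditory) {
  for (counts in list(visual, auditory)) {
    if (length(counts) != 3 || any(counts < 0)) {
      stop("each modality needs 3 non-negative counts (correct, errors, prompts)",
           call. = FALSE)
    }
    if (counts[1] > 30) {
      stop("correct responses cannot exceed the 30 targets", call. = FALSE)
    }
  }
  v <- visual[1] - visual[2] - visual[3]
  a <- auditory[1] - auditory[2] - auditory[3]
  list(visual = v, auditory = a, total = (v + a) / 2)
}

#' Score the selective attention task
#'
#' The score is the number of correctly identified targets in the visual
#' search (18 targets available).
#'
#' @param found Count of correctly identified targets, 0-18.
#' @return The score (identity on the count).
#' @export
score_selective <- function(found) {
  if (found < 0 || found > 18) {
    stop("selective attention: found targets must be in [0, 18] (18 targets)",
         call. = FALSE)
  }
  found
}

#' Score the executive attention task
#'
#' The score is the total number of incorrect or incomplete trials,
#' negated so that more positive values reflect better attention.  Three
#' stages of 20 trials bound the count at 60.
#'
#' @param incorrect_or_incomplete Count of incorrect or incomplete trials,
#'   0-60.
#' @return The negated count (always <= 0).
#' @export
score_executive <- function(incorrect_or_incomplete) {
  if (incorrect_or_incomplete < 0 || incorrect_or_incomplete > 60) {
    stop("executive attention: trial count must be in [0, 60]",
         call. = FALSE)
  }
  -incorrect_or_incomplete
}

#' Harmonize a behavior table: sustained outliers and missing executive
#'
#' Applies the cohort's harmonization rules: a participant whose visual or
#' auditory sustained score lies more than 3 sample standard deviations
#' from that modality's mean has their total sustained score recomputed
#' from the other modality alone; missing executive scores are imputed with
#' the mean of the observed scores.  Every substitution is recorded in a
#' change log attached as the `"changes"` attribute (and reported via
#' messages).
#'
#' @param table Data frame with `sustained_visual`, `sustained_auditory`,
#'   `sustained` (total) and/or `executive` columns.
#' @param sd_threshold Outlier threshold in sample SD units (default 3).
#' @return The harmonized table, with a `changes` attribute (data frame of
#'   row, column, old, new).
#' @export
harmonize_behavior <- function(table, sd_threshold = 3) {
  if (nrow(table) < 2) {
    stop("harmonization needs at least 2 rows for SD computation",
         call. = FALSE)
  }
  changes <- data.frame(row = integer(0), column = character(0),
                        old = numeric(0), new = numeric(0))
  note <- function(row, column, old, new) {
    changes[nrow(changes) + 1L, ] <<- list(row, column, old, new)
    message(sprintf("harmonize_behavior: row %d %s %.3g -> %.3g",
                    row, column, old, new))
  }
  mods <- c(visual = "sustained_visual", auditory = "sustained_auditory")
  if (all(mods %in% names(table)) && "sustained" %in% names(table)) {
    for (k in seq_along(mods)) {
      x <- table[[mods[k]]]
      mu <- mean(x, na.rm = TRUE)
      sdv <- stats::sd(x, na.rm = TRUE)
      if (is.na(sdv) || sdv == 0) next
      out_rows <- which(!is.na(x) & abs(x - mu) > sd_threshold * sdv)
      other <- table[[mods[-k]]]
      for (i in out_rows) {
        note(i, "sustained", table$sustained[i], other[i])
        table$sustained[i] <- other[i]
      }
    }
  }
  if ("executive" %in% names(table)) {
    x <- table$executive
    if (all(is.na(x))) {
      stop("all executive scores missing: cannot impute", call. = FALSE)
    }
    mu <- mean(x, na.rm = TRUE)
    for (i in which(is.na(x))) {
      note(i, "executive", NA_real_, mu)
      table$executive[i] <- mu
    }
  }
  attr(table, "changes") <- changes
  table
}
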