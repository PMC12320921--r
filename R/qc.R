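# Cohort-level QC statistics: fingerprinting, QC-FC, exclusion ledger, PCA.

#' Connectome fingerprint match rate
#'
#' For each scan, its vectorized upper-triangle FC is Pearson-correlated
#' with every other scan; the scan "matches" when the most-correlated other
#' scan belongs to the same subject.  The rate is matches divided by the
#' total number of scans: scans without a same-subject partner stay in the
#' denominator and can never match, so they act as potential false matches.
#'
#' @param fc_scans List of FC `connectome_matrix` objects with subject ids
#'   and timepoints (each (subject, timepoint) pair must be unique).
#' @return Match rate in \[0, 1\].
#' @export
fingerprint_match_rate <- function(fc_scans) {
  if (length(fc_scans) < 2) {
    stop("fingerprinting needs at least 2 scans", call. = FALSE)
  }
  subj <- vapply(fc_scans, function(m) as.character(m$subject_id), "")
  tp <- vapply(fc_scans, function(m) m$timepoint, 0L)
  if (anyDuplicated(paste(subj, tp, sep = "\r"))) {
    stop("duplicate (subject, timepoint) scans", call. = FALSE)
  }
  vecs <- vapply(fc_scans, function(m) upper_tri_vec(m$weights),
                 numeric(length(upper_tri_vec(fc_scans[[1]]$weights))))
  cc <- stats::cor(vecs)
  diag(cc) <- -Inf
  best <- apply(cc, 2, which.max)
  mean(subj[best] == subj)
}

#' QC-FC: edgewise correlation of connectivity with head motion
#'
#' Pearson-correlates each FC edge with a per-scan motion summary (mean
#' framewise displacement) across scans, and reports the fraction of edges
#' with an uncorrected two-sided p below `alpha` plus the median edge-motion
#' correlation.  Zero-variance edges yield undefined correlations, reported
#' as missing and excluded from the median but kept in the fraction's
#' denominator.
#'
#' @param panel Scans x edges numeric matrix of FC edge values.
#' @param motion Per-scan motion values (length = rows of `panel`).
#' @param alpha Uncorrected two-sided significance level (default 0.05).
#' @return List with `fraction_significant`, `median_correlation`,
#'   `correlations`, `p_values`.
#' @export
qcfc_summary <- function(panel, motion, alpha = 0.05) {
  panel <- as.matrix(panel)
  if (nrow(panel) != length(motion)) {
    stop("`motion` length must equal the number of scans", call. = FALSE)
  }
  if (stats::sd(motion) == 0) {
    stop("zero-variance motion summary", call. = FALSE)
  }
  n <- length(motion)
  r <- suppressWarnings(as.numeric(stats::cor(motion, panel)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- NA_real_
  list(fraction_significant = sum(p < alpha, na.rm = TRUE) / ncol(panel),
       median_correlation = stats::median(r, na.rm = TRUE),
       correlations = r, p_values = p)
}

#' Sequential scan-exclusion ledger
#'
#' Tracks a QC flow: an initial scan count and an ordered list of labelled
#' exclusion stages, each subtracting from the running total.
#'
#' @param initial Initial number of scans.
#' @param stages Named numeric vector (or data frame with `label` and
#'   `excluded` columns) of per-stage exclusion counts, in order.
#' @return An `exclusion_ledger`: list with `initial`, `stages` (data frame
#'   with running `remaining`), `total_excluded`, `remaining`.
#' @export
#' @examples
#' exclusion_ledger(203, c(T1_motion = 14, T1_extraction = 5, FOV = 5,
#'                         dMRI_registration = 3, fMRI_motion = 28,
#'                         fMRI_registration = 1, fMRI_residual = 17,
#'                         unpaired = 52))
exclusion_ledger <- function(initial, stages = NULL) {
  if (initial < 0) stop("`initial` must be non-negative", call. = FALSE)
  if (is.data.frame(stages)) {
    labels <- as.character(stages$label)
    counts <- as.numeric(stages$excluded)
  } else if (is.null(stages) || length(stages) == 0) {
    labels <- character(0)
    counts <- numeric(0)
  } else {
    labels <- names(stages) %||% paste0("stage", seq_along(stages))
    counts <- as.numeric(stages)
  }
  if (any(counts < 0)) stop("stage counts must be non-negative",
                            call. = FALSE)
  remaining <- initial - cumsum(counts)
  bad <- which(remaining < 0)
  if (length(bad) > 0) {
    stop(sprintf("stage '%s' excludes more scans than remain",
                 labels[bad[1]]), call. = FALSE)
  }
  structure(
    list(initial = initial,
         stages = data.frame(label = labels, excluded = counts,
                             remaining = remaining),
         total_excluded = sum(counts),
         remaining = initial - sum(counts)),
    class = "exclusion_ledger"
  )
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("<exclusion_ledger> initial scans: %d\n", x$initial))
  if (nrow(x$stages) > 0) {
    for (i in seq_len(nrow(x$stages))) {
      cat(sprintf("  - %-24s -%3d  -> %d\n", x$stages$label[i],
                  x$stages$excluded[i], x$stages$remaining[i]))
    }
  }
  cat(sprintf("  total excluded: %d; remaining: %d\n",
              x$total_excluded, x$remaining))
  invisible(x)
}

#' Variance explained by leading principal components of a panel
#'
#' Column-centers the scans x features panel and returns the fractions of
#' total variance carried by the leading principal components.
#'
#' @param panel Scans x features numeric matrix.
#' @param n_components Number of leading components (default 10); truncated
#'   with a warning if it exceeds the panel rank.
#' @return Numeric vector of non-increasing variance fractions summing to
#'   at most 1.
#' @export
panel_pca_variance <- function(panel, n_components = 10) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2) stop("PCA needs at least 2 scans", call. = FALSE)
  pc <- stats::prcomp(panel, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]
  frac <- ev / sum(ev)
  if (n_components > length(frac)) {
    warning(sprintf("panel rank %d < n_components %d: truncating",
                    length(frac), n_components), call. = FALSE)
    n_components <- length(frac)
  }
  frac[seq_len(n_components)]
}
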