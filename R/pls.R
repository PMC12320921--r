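# Mean-centered task PLS and behavioral PLS: SVD core and result object.

# Build the decomposed matrix R (p regions x k columns) for either mode.
# mean_centered: per-condition column means minus the unweighted grand mean
#   of condition means (k = number of conditions).
# behavioral: within-condition Pearson correlations of each behavior column
#   with each region column, stacked condition-major
#   (k = conditions x behaviors).
pls_cross_matrix <- function(panel, behaviors = NULL,
                             behavior_columns = NULL) {
  x <- panel$values
  blocks <- panel_blocks(panel)
  if (is.null(behaviors)) {
    m <- rbind(colMeans(x[blocks[[1]], , drop = FALSE]),
               colMeans(x[blocks[[2]], , drop = FALSE]))
    mc <- sweep(m, 2, colMeans(m))
    r <- t(mc)
    colnames(r) <- paste0("cond", names(blocks))
  } else {
    if (is.null(behavior_columns)) {
      stop("`behavior_columns` must name the behavior measures to use",
           call. = FALSE)
    }
    missing_cols <- setdiff(behavior_columns, names(behaviors))
    if (length(missing_cols) > 0) {
      stop(sprintf("behavior column(s) not found: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    rows <- list()
    for (ci in seq_along(blocks)) {
      xb <- x[blocks[[ci]], , drop = FALSE]
      for (bc in behavior_columns) {
        y <- behaviors[[bc]][blocks[[ci]]]
        if (anyNA(y)) {
          stop(sprintf("missing values in behavior '%s' (condition %s)",
                       bc, names(blocks)[ci]), call. = FALSE)
        }
        if (stats::sd(y) == 0) {
          stop(sprintf("zero-variance behavior '%s' in condition %s",
                       bc, names(blocks)[ci]), call. = FALSE)
        }
        cr <- suppressWarnings(as.numeric(stats::cor(y, xb)))
        if (anyNA(cr)) {
          warning("zero-variance region column(s): correlations set to 0",
                  call. = FALSE)
          cr[is.na(cr)] <- 0
        }
        rows[[sprintf("cond%s_%s", names(blocks)[ci], bc)]] <- cr
      }
    }
    r <- t(do.call(rbind, rows))
  }
  rownames(r) <- colnames(x)
  r
}

# SVD with the package's sign convention: the largest-magnitude element of
# each brain salience (U column) is positive, V flipped accordingly.
pls_svd <- function(r) {
  sv <- svd(r)
  u <- sv$u
  v <- sv$v
  for (l in seq_len(ncol(u))) {
    j <- which.max(abs(u[, l]))
    if (u[j, l] < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  rownames(u) <- rownames(r)
  rownames(v) <- colnames(r)
  list(u = u, v = v, d = sv$d)
}

new_pls_result <- function(mode, panel, behaviors, behavior_columns) {
  r <- pls_cross_matrix(panel, behaviors, behavior_columns)
  sv <- pls_svd(r)
  scores <- panel$values %*% sv$u
  colnames(scores) <- paste0("LV", seq_len(ncol(scores)))
  res <- structure(
    list(mode = mode, decomposed_matrix = r,
         U = sv$u, V = sv$v, s = sv$d,
         brain_scores = scores,
         perm_p = NULL, bsr = NULL,
         behavior_correlations = NULL,
         behavior_columns = behavior_columns),
    class = "pls_result"
  )
  if (mode == "behavioral") {
    res$behavior_correlations <-
      brain_behavior_correlations(res$brain_scores, panel, behaviors,
                                  behavior_columns)
  }
  res
}

# Per-condition correlations of per-LV brain scores with each behavior.
brain_behavior_correlations <- function(scores, panel, behaviors,
                                        behavior_columns) {
  blocks <- panel_blocks(panel)
  out <- list()
  for (ci in seq_along(blocks)) {
    rows <- blocks[[ci]]
    for (bc in behavior_columns) {
      cr <- as.numeric(stats::cor(behaviors[[bc]][rows],
                                  scores[rows, , drop = FALSE]))
      out[[sprintf("cond%s_%s", names(blocks)[ci], bc)]] <- cr
    }
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- colnames(scores)
  mat
}

#' Mean-centered task PLS
#'
#' Two-condition mean-centered task PLS: per-condition column means of the
#' panel are centered on the unweighted grand mean of the condition means,
#' and the transposed deviation matrix (regions x conditions) is decomposed
#' by SVD, X = U S V'.  U holds the brain saliences, V the condition
#' saliences, and the singular values the condition-related covariance.
#' Brain scores are the panel values projected onto U.
#'
#' @param panel A [build_cohort_panel()] result (paired, equal-n
#'   conditions).
#' @return A `pls_result` with `mode = "mean_centered"`.
#' @export
#' @examples
#' v <- rbind(matrix(1:6 / 10, 3, 2), matrix(0, 3, 2))
#' p <- build_cohort_panel(v, rep(c("a", "b", "c"), 2), rep(1:2, each = 3))
#' mean_centered_pls(p)$s
mean_centered_pls <- function(panel) {
  if (!inherits(panel, "cohort_panel")) {
    stop("`panel` must be a cohort_panel", call. = FALSE)
  }
  if (length(unique(panel$condition)) < 2) {
    stop("mean-centered PLS needs two conditions", call. = FALSE)
  }
  new_pls_result("mean_centered", panel, NULL, NULL)
}

#' Behavioral PLS
#'
#' Computes the within-condition Pearson correlation of each behavior
#' measure with each region column, stacks the condition-by-behavior
#' correlation rows, and decomposes the transpose by SVD.  Each latent
#' variable pairs a brain salience (U column) with behavior saliences (V)
#' and a singular value; per-condition correlations of the LV brain scores
#' with each behavior are attached for reporting.
#'
#' @param panel A [build_cohort_panel()] result.
#' @param behaviors A behavior table (data frame) aligned or alignable to
#'   the panel rows via `subject_id`/`timepoint` columns.
#' @param behavior_columns Character vector of behavior column names (e.g.
#'   `c("age", "sustained")`).
#' @return A `pls_result` with `mode = "behavioral"`.
#' @export
behavioral_pls <- function(panel, behaviors, behavior_columns) {
  if (!inherits(panel, "cohort_panel")) {
    stop("`panel` must be a cohort_panel", call. = FALSE)
  }
  if (all(c("subject_id", "timepoint") %in% names(behaviors))) {
    behaviors <- align_behavior(panel, behaviors)
  } else if (nrow(behaviors) != nrow(panel$values)) {
    stop("`behaviors` rows do not match the panel scans", call. = FALSE)
  }
  new_pls_result("behavioral", panel, behaviors, behavior_columns)
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %s PLS: %d regions x %d design columns\n",
              x$mode, nrow(x$U), nrow(x$V)))
  for (l in seq_along(x$s)) {
    pl <- if (is.null(x$perm_p)) "" else sprintf(", p = %.4g", x$perm_p[l])
    cat(sprintf("  LV%d: s = %.4f%s\n", l, x$s[l], pl))
  }
  invisible(x)
}
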