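# ConnectomeMatrix: one scan's square symmetric weighted network.

#' Construct a connectome matrix
#'
#' A `connectome_matrix` holds one scan's region-by-region weighted network:
#' a square symmetric numeric matrix with zero diagonal, ordered region
#' labels, a modality tag (`"SC"` for structural, `"FC"` for functional
#' connectivity), and scan identifiers.  SC weights (streamline proportions)
#' must be non-negative; FC weights (Fisher z correlations) may be negative.
#'
#' @param weights Square symmetric numeric matrix of edge weights.  The
#'   diagonal (self-connections) is forced to zero.
#' @param region_labels Character vector of region names, one per row.
#'   Defaults to existing rownames, or `"R1"..."RN"`.
#' @param modality `"SC"` or `"FC"`.
#' @param subject_id Scan's subject identifier.
#' @param timepoint Scan's timepoint, `1` or `2`.
#'
#' @return An object of class `connectome_matrix`: a list with elements
#'   `weights`, `region_labels`, `modality`, `subject_id`, `timepoint`.
#' @export
#' @examples
#' w <- matrix(c(0, .2, .2, 0), 2, 2)
#' connectome_matrix(w, c("A", "B"), "FC", subject_id = "s1", timepoint = 1)
connectome_matrix <- function(weights, region_labels = NULL,
                              modality = c("SC", "FC"),
                              subject_id = NA_character_, timepoint = 1L) {
  modality <- match.arg(modality)
  if (!is_square_matrix(weights)) {
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  }
  check_symmetric(weights)
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(weights) %||% paste0("R", seq_len(nrow(weights)))
  }
  if (length(region_labels) != nrow(weights)) {
    stop("`region_labels` length does not match matrix dimension",
         call. = FALSE)
  }
  if (anyDuplicated(region_labels)) {
    stop("region labels must be unique", call. = FALSE)
  }
  if (modality == "SC" && any(weights < 0)) {
    stop("SC matrices must have non-negative weights", call. = FALSE)
  }
  if (!timepoint %in% c(1L, 2L)) {
    stop("`timepoint` must be 1 or 2", call. = FALSE)
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(
    list(weights = weights, region_labels = as.character(region_labels),
         modality = modality, subject_id = subject_id,
         timepoint = as.integer(timepoint)),
    class = "connectome_matrix"
  )
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("<connectome_matrix> %s, %d regions, subject %s, timepoint %d\n",
              x$modality, length(x$region_labels),
              as.character(x$subject_id), x$timepoint))
  rng <- range(x$weights[upper.tri(x$weights)])
  cat(sprintf("  edge weights in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.matrix.connectome_matrix <- function(x, ...) x$weights

# Accept either a connectome_matrix or a bare symmetric matrix.
conn_weights <- function(m) {
  if (inherits(m, "connectome_matrix")) return(m$weights)
  if (!is_square_matrix(m)) {
    stop("expected a connectome_matrix or square numeric matrix",
         call. = FALSE)
  }
  m
}

conn_modality <- function(m, default = "SC") {
  if (inherits(m, "connectome_matrix")) m$modality else default
}

#' Fisher z-transform a correlation matrix into an FC connectome
#'
#' Applies `atanh` elementwise to the off-diagonal entries of a symmetric
#' correlation matrix, zeroing the diagonal, giving the Fisher z functional
#' connectivity weights used throughout the pipeline.
#'
#' @param r_matrix Square symmetric correlation matrix with off-diagonal
#'   entries strictly inside (-1, 1).
#' @param region_labels,subject_id,timepoint Passed to
#'   [connectome_matrix()].
#' @return A `connectome_matrix` with `modality = "FC"`.
#' @export
#' @examples
#' r <- matrix(c(1, .5, .5, 1), 2, 2)
#' fisher_z_transform(r)$weights  # off-diagonal atanh(0.5)
fisher_z_transform <- function(r_matrix, region_labels = NULL,
                               subject_id = NA_character_, timepoint = 1L) {
  if (!is_square_matrix(r_matrix)) {
    stop("`r_matrix` must be a square numeric matrix", call. = FALSE)
  }
  check_symmetric(r_matrix, what = "correlation")
  off <- r_matrix
  diag(off) <- 0
  bad <- which(abs(off) >= 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "off-diagonal correlation at (%d, %d) = %g is outside (-1, 1)",
      bad[1, 1], bad[1, 2], r_matrix[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  z <- atanh(off)
  diag(z) <- 0
  connectome_matrix(z, region_labels, "FC", subject_id, timepoint)
}

#' Normalize and symmetrize a streamline-count matrix into an SC connectome
#'
#' Converts raw streamline counts to streamline proportions: each row is
#' divided by its own row sum (the total number of streamlines sent from the
#' seed region), then the matrix is symmetrized by averaging the two
#' directions, and the diagonal is zeroed.  Rows with a zero sum (fully
#' disconnected seeds) are kept as all-zero rows and reported in a warning.
#'
#' @param counts Square non-negative streamline-count matrix.
#' @param region_labels,subject_id,timepoint Passed to
#'   [connectome_matrix()].
#' @return A `connectome_matrix` with `modality = "SC"`.
#' @export
normalize_and_symmetrize_sc <- function(counts, region_labels = NULL,
                                        subject_id = NA_character_,
                                        timepoint = 1L) {
  if (!is_square_matrix(counts)) {
    stop("`counts` must be a square numeric matrix", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("streamline counts must be non-negative", call. = FALSE)
  }
  diag(counts) <- 0
  rs <- rowSums(counts)
  if (all(rs == 0)) {
    stop("all rows have zero streamline counts", call. = FALSE)
  }
  zero_rows <- which(rs == 0)
  if (length(zero_rows) > 0) {
    warning(sprintf("%d seed row(s) with zero streamline sum kept as zeros: %s",
                    length(zero_rows),
                    paste(utils::head(zero_rows, 5), collapse = ", ")),
            call. = FALSE)
  }
  rs[rs == 0] <- 1  # leaves those rows all-zero
  w <- counts / rs
  w <- (w + t(w)) / 2
  diag(w) <- 0
  connectome_matrix(w, region_labels, "SC", subject_id, timepoint)
}

#' Drop excluded regions from a connectome matrix
#'
#' Removes the rows and columns of the named regions, preserving the order
#' of the remaining labels.  Used e.g. to go from a 200-region parcellation
#' to the analyzed 193-region matrices after field-of-view exclusions.
#'
#' @param m A `connectome_matrix`.
#' @param excluded Character vector of region names to drop (may be empty).
#' @return A `connectome_matrix` over the remaining regions.
#' @export
apply_region_exclusion <- function(m, excluded) {
  if (!inherits(m, "connectome_matrix")) {
    stop("`m` must be a connectome_matrix", call. = FALSE)
  }
  excluded <- as.character(excluded)
  unknown <- setdiff(excluded, m$region_labels)
  if (length(unknown) > 0) {
    stop(sprintf("unknown region name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- !(m$region_labels %in% excluded)
  connectome_matrix(m$weights[keep, keep, drop = FALSE],
                    m$region_labels[keep], m$modality,
                    m$subject_id, m$timepoint)
}

#' Consensus-threshold a panel of SC matrices
#'
#' An edge is "present" in a scan when its weight is strictly positive.
#' Edges present in fewer than `fraction` of the scans are set to zero in
#' every scan, suppressing probabilistic-tractography false positives.
#'
#' @param panel List of SC `connectome_matrix` objects with identical
#'   region labels.
#' @param fraction Minimum presence proportion in (0, 1] (default 0.75).
#' @return A list with elements `mask` (symmetric logical matrix of retained
#'   edges), `panel` (thresholded matrices), and `zeroed` (per-scan data
#'   frame with the count and proportion of previously present edges that
#'   were set to zero).
#' @export
consensus_threshold <- function(panel, fraction = 0.75) {
  if (length(panel) < 1) stop("empty panel", call. = FALSE)
  if (!(fraction > 0 && fraction <= 1)) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  ws <- lapply(panel, conn_weights)
  dims <- vapply(ws, nrow, 0L)
  if (length(unique(dims)) != 1) {
    stop("matrices in `panel` have mixed shapes", call. = FALSE)
  }
  labs <- lapply(panel, function(m) {
    if (inherits(m, "connectome_matrix")) m$region_labels else rownames(m)
  })
  labs <- labs[!vapply(labs, is.null, TRUE)]
  if (length(labs) > 1 &&
      !all(vapply(labs, identical, TRUE, labs[[1]]))) {
    stop("matrices in `panel` have mismatched region labels", call. = FALSE)
  }
  presence <- Reduce(`+`, lapply(ws, function(w) w > 0))
  mask <- presence >= fraction * length(ws)
  diag(mask) <- FALSE
  ut <- upper.tri(mask)
  n_off <- dims[1] * (dims[1] - 1) / 2  # undirected edge count
  zeroed <- data.frame(
    scan = seq_along(panel),
    n_zeroed = NA_integer_,
    prop_zeroed = NA_real_
  )
  out <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    w <- ws[[i]]
    was_present <- w > 0
    w[!mask] <- 0
    nz <- sum(was_present[ut] & !mask[ut])
    zeroed$n_zeroed[i] <- nz
    zeroed$prop_zeroed[i] <- nz / n_off
    if (inherits(panel[[i]], "connectome_matrix")) {
      mi <- panel[[i]]
      mi$weights <- w
      out[[i]] <- mi
    } else {
      out[[i]] <- w
    }
  }
  list(mask = mask, panel = out, zeroed = zeroed)
}
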