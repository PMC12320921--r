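# Signed weighted graph metrics: modularity, local clustering, degree.

# Signed modularity matrix with asymmetric treatment of negative weights.
# B = (W+ - g k+ k+'/v+)/v+  -  (W- - g k- k-'/v-)/(v+ + v-),
# so positive weights contribute at full strength while the negative-weight
# term is down-weighted by v-/(v+ + v-).  For all-non-negative input this is
# the standard Newman modularity matrix.
signed_modularity_matrix <- function(w, resolution = 1) {
  wp <- pmax(w, 0)
  wn <- -pmin(w, 0)
  vp <- sum(wp)
  vn <- sum(wn)
  if (vp == 0 && vn == 0) {
    stop("modularity undefined for an empty (all-zero) network",
         call. = FALSE)
  }
  b <- matrix(0, nrow(w), ncol(w))
  if (vp > 0) {
    kp <- rowSums(wp)
    b <- b + (wp - resolution * tcrossprod(kp) / vp) / vp
  }
  if (vn > 0) {
    kn <- rowSums(wn)
    b <- b - (wn - resolution * tcrossprod(kn) / vn) / (vp + vn)
  }
  (b + t(b)) / 2
}

# Modularity of a given partition under the asymmetric signed objective,
# computed directly from the weights (used both by the optimizer's scoring
# and exposed for forced-partition evaluation).
modularity_of_partition <- function(w, partition, resolution = 1) {
  b <- signed_modularity_matrix(w, resolution)
  same <- outer(partition, partition, `==`)
  sum(b[same])
}

# One Louvain run on a modularity matrix: greedy local moving plus
# aggregation, repeated until no community merge improves Q.
louvain_once <- function(b) {
  n0 <- nrow(b)
  membership <- seq_len(n0)
  repeat {
    n <- nrow(b)
    comm <- seq_len(n)
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        bi <- b[i, ]
        bi[i] <- 0
        gains <- rowsum(bi, comm, reorder = FALSE)[, 1]
        cl <- names(gains)
        cur <- as.character(comm[i])
        best <- which.max(gains)
        if (gains[best] > gains[cur] + 1e-12 && cl[best] != cur) {
          comm[i] <- as.integer(cl[best])
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!moved_any) break
    # relabel 1..K and aggregate
    comm <- match(comm, unique(comm))
    membership <- comm[membership]
    if (max(comm) == n) break
    b <- rowsum(t(rowsum(b, comm, reorder = TRUE)), comm, reorder = TRUE)
  }
  membership
}

#' Louvain modularity of a signed weighted network
#'
#' Optimizes the modularity statistic Q with asymmetric treatment of
#' negative weights: Q* = Q+ - v-/(v+ + v-) Q-, where Q+/Q- are Newman
#' modularities of the positive/negative sub-networks and v+/v- their total
#' weights, so positive weights dominate the objective.  For non-negative
#' (SC) input this reduces to standard weighted modularity.  The optimizer
#' is a Louvain-style greedy algorithm (random-order local moving with
#' aggregation); the best of `n_restarts` runs is returned and the result is
#' deterministic given `seed`.
#'
#' @param m A `connectome_matrix` or symmetric zero-diagonal matrix.
#' @param resolution Resolution parameter gamma (default 1).
#' @param n_restarts Number of random-order restarts (default 100).
#' @param seed Integer seed (required: Louvain is stochastic).
#' @return A `partitioned_modularity`: list with `Q`, `partition` (named
#'   integer vector of contiguous community ids starting at 1),
#'   `n_restarts_used`, `seed`.
#' @export
#' @examples
#' # two disconnected triangles: Q = 0.5
#' w <- matrix(0, 6, 6)
#' w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
#' modularity_signed(w, seed = 1)$Q
modularity_signed <- function(m, resolution = 1, n_restarts = 100, seed) {
  w <- conn_weights(m)
  check_symmetric(w)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_restarts < 1) stop("`n_restarts` must be >= 1", call. = FALSE)
  b <- signed_modularity_matrix(w, resolution)
  best_q <- -Inf
  best_part <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      part <- louvain_once(b)
      q <- sum(b[outer(part, part, `==`)])
      if (q > best_q + 1e-15) {
        best_q <- q
        best_part <- part
      }
    }
  })
  part <- match(best_part, unique(best_part))
  labels <- if (inherits(m, "connectome_matrix")) m$region_labels else
    rownames(w) %||% paste0("R", seq_len(nrow(w)))
  names(part) <- labels
  structure(
    list(Q = best_q, partition = part,
         n_restarts_used = as.integer(n_restarts), seed = as.integer(seed)),
    class = "partitioned_modularity"
  )
}

#' @export
print.partitioned_modularity <- function(x, ...) {
  cat(sprintf("<partitioned_modularity> Q = %.4f, %d communities (%d restarts)\n",
              x$Q, max(x$partition), x$n_restarts_used))
  invisible(x)
}

#' Weighted local clustering coefficient (non-negative networks)
#'
#' Per-region triangle intensity relative to the number of neighbor pairs:
#' C_i = sum_jh (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1)) with weights scaled
#' by the network maximum and k_i the binary degree; C_i = 0 for regions
#' with fewer than two neighbors.
#'
#' @param m An SC `connectome_matrix` or non-negative symmetric matrix.
#' @return Named numeric vector of per-region coefficients.
#' @export
local_clustering_positive <- function(m) {
  w <- conn_weights(m)
  check_symmetric(w)
  if (any(w < 0)) {
    stop("negative weights: use local_clustering_signed for FC matrices",
         call. = FALSE)
  }
  diag(w) <- 0
  mx <- max(w)
  labels <- if (inherits(m, "connectome_matrix")) m$region_labels else
    rownames(w)
  if (mx == 0) {
    return(stats::setNames(numeric(nrow(w)), labels))
  }
  wh <- (w / mx)^(1 / 3)
  cyc <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  stats::setNames(ci, labels)
}

#' Signed weighted local clustering coefficient
#'
#' Costantini-Perugini generalization for signed networks:
#' C_i = sum_{j != h} w_ij w_ih w_jh / sum_{j != h} |w_ij w_ih|,
#' the signed triangle products around region i normalized by the total
#' magnitude of its neighbor-pair weight products; C_i = 0 when the
#' denominator vanishes (isolated regions).
#'
#' @param m An FC `connectome_matrix` or symmetric signed matrix.
#' @return Named numeric vector of per-region coefficients.
#' @export
local_clustering_signed <- function(m) {
  w <- conn_weights(m)
  check_symmetric(w)
  diag(w) <- 0
  num <- diag(w %*% w %*% w)
  den <- rowSums(abs(w))^2 - rowSums(w^2)
  ci <- ifelse(den > 0, num / den, 0)
  labels <- if (inherits(m, "connectome_matrix")) m$region_labels else
    rownames(w)
  stats::setNames(ci, labels)
}

#' Weighted degree (average connection strength)
#'
#' Per-region mean edge weight over all other regions:
#' d_i = sum_{j != i} w_ij / (N - 1).
#'
#' @param m A `connectome_matrix` or symmetric zero-diagonal matrix.
#' @return Named numeric vector of per-region average strengths.
#' @export
weighted_degree <- function(m) {
  w <- conn_weights(m)
  check_symmetric(w)
  n <- nrow(w)
  if (n < 2) stop("weighted degree requires at least 2 regions",
                  call. = FALSE)
  diag(w) <- 0
  labels <- if (inherits(m, "connectome_matrix")) m$region_labels else
    rownames(w)
  stats::setNames(rowSums(w) / (n - 1), labels)
}
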