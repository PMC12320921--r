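# Independent oracles used across tests: brute-force implementations kept
# deliberately separate from the package's code paths.

# All set partitions of n elements (restricted-growth strings), as a list
# of integer membership vectors.  Feasible for n <= 8 (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_len(maxid + 1L)) {
      grow(c(prefix, k), max(maxid, k))
    }
  }
  grow(integer(0), 0L)
  out
}

# Direct evaluation of the asymmetric signed modularity of a partition from
# the weights: Q* = Q+ - v-/(v+ + v-) Q-, each Q from its definition.
oracle_modularity <- function(w, part, gamma = 1) {
  same <- outer(part, part, `==`)
  wp <- pmax(w, 0)
  wn <- -pmin(w, 0)
  vp <- sum(wp)
  vn <- sum(wn)
  qpos <- if (vp > 0) {
    k <- rowSums(wp)
    sum(wp[same] - gamma * tcrossprod(k)[same] / vp) / vp
  } else 0
  qneg <- if (vn > 0) {
    k <- rowSums(wn)
    sum(wn[same] - gamma * tcrossprod(k)[same] / vn) / (vp + vn)
  } else 0
  qpos - qneg
}

# Exhaustive-search optimum of the signed modularity over all partitions.
oracle_best_partition <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity(w, p, gamma), 0)
  list(Q = max(qs), partition = parts[[which.max(qs)]])
}

# Triple-loop triangle enumeration for the positive weighted clustering
# coefficient (normalized weights, binary degree denominator).
oracle_clustering_positive <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
        }
      }
    }
    k <- sum(w[i, ] > 0)
    out[i] <- if (k >= 2) acc / (k * (k - 1)) else 0
  }
  out
}

# Triple-loop enumeration for the signed clustering coefficient.
oracle_clustering_signed <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          num <- num + w[i, j] * w[i, h] * w[j, h]
          den <- den + abs(w[i, j] * w[i, h])
        }
      }
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# Random symmetric zero-diagonal matrix; signed or non-negative.
random_sym_graph <- function(n, density = 0.5, signed = FALSE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  ne <- sum(ut)
  vals <- stats::runif(ne) * (stats::runif(ne) < density)
  if (signed) vals <- vals * sign(stats::runif(ne) - 0.3)
  w[ut] <- vals
  w + t(w)
}

# Two-triangle fixture: two disconnected 3-cliques with unit weights.
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 0
  w
}

# Small paired cohort panel from raw values (subject-major within block).
tiny_panel <- function(values, n_sub = nrow(values) / 2) {
  build_cohort_panel(values,
                     rep(sprintf("s%02d", seq_len(n_sub)), 2),
                     rep(1:2, each = n_sub))
}
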