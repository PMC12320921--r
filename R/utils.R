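# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators stay pure functions of their arguments.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside the
# 32-bit signed-integer range.  Distinct (seed, labels) map to distinct
# streams with overwhelming probability.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 1103515245 + p * 12345 + 6789) %% 2147483647
  as.integer(h)
}

is_square_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

check_symmetric <- function(w, tol = 1e-12, what = "weights") {
  if (max(abs(w - t(w))) > tol) {
    stop(sprintf("%s matrix is not symmetric within %g", what, tol),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Cosine similarity of two vectors.
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

# Vectorize the strict upper triangle of a square matrix (column-major).
upper_tri_vec <- function(w) {
  w[upper.tri(w)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
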