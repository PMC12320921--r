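# Permutation, bootstrap, and reproducibility machinery for PLS results.

# Align a behavior table to a panel if it carries scan keys.
prep_behaviors <- function(panel, behaviors) {
  if (is.null(behaviors)) return(NULL)
  if (all(c("subject_id", "timepoint") %in% names(behaviors))) {
    behaviors <- align_behavior(panel, behaviors)
  } else if (nrow(behaviors) != nrow(panel$values)) {
    stop("`behaviors` rows do not match the panel scans", call. = FALSE)
  }
  behaviors
}

# Draw one permutation of the panel's value rows under a scheme:
#   unrestricted - shuffle all scan rows across the whole stack (breaks
#     condition assignment and X-Y correspondence, and also the panel's
#     within-subject pairing);
#   paired - respect the paired design: for a mean-centered analysis the two
#     rows of each subject are swapped with probability 1/2 (condition-label
#     permutation); for a behavioral analysis whole subject blocks are
#     permuted (timepoints held together), breaking only the X-Y link.
draw_permutation <- function(panel, scheme, behavioral) {
  n_rows <- nrow(panel$values)
  if (scheme == "unrestricted") {
    return(sample.int(n_rows))
  }
  n <- n_rows / 2L
  if (behavioral) {
    sigma <- sample.int(n)
    perm <- integer(n_rows)
    perm[seq_len(n)] <- sigma
    perm[n + seq_len(n)] <- n + sigma
    perm
  } else {
    swap <- stats::runif(n) < 0.5
    perm <- seq_len(n_rows)
    perm[seq_len(n)][swap] <- n + which(swap)
    perm[n + seq_len(n)][swap] <- which(swap)
    perm
  }
}

# Singular values of the permuted decomposition under the chosen scheme.
permuted_singular_values <- function(panel, behaviors, behavior_columns,
                                     n_perm, scheme = "unrestricted") {
  s_obs_len <- min(dim(pls_cross_matrix(panel, behaviors, behavior_columns)))
  out <- matrix(NA_real_, n_perm, s_obs_len)
  behavioral <- !is.null(behaviors)
  for (q in seq_len(n_perm)) {
    pp <- panel_permute_rows(panel,
                             draw_permutation(panel, scheme, behavioral))
    out[q, ] <- svd(pls_cross_matrix(pp, behaviors, behavior_columns),
                    nu = 0, nv = 0)$d
  }
  out
}

#' Permutation p-values for PLS latent variables
#'
#' Each permutation shuffles the scan rows of the panel across the whole
#' stack (resampling without replacement), recomputes the decomposition,
#' and records the per-LV singular values.  The p-value of LV l is the
#' proportion of permuted singular values greater than or equal to the
#' observed one.
#'
#' @param result A `pls_result`.
#' @param panel The panel the result was computed from.
#' @param behaviors Behavior table for behavioral mode (ignored for
#'   mean-centered).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param scheme `"unrestricted"` (default) shuffles all scan rows across
#'   the whole stack.  `"paired"` respects the paired two-timepoint design:
#'   within-subject condition swaps for mean-centered analyses, whole
#'   subject-block permutations (timepoints held together) for behavioral
#'   analyses.  The paired scheme has an exact null under subject
#'   exchangeability; the unrestricted scheme also breaks the within-
#'   subject dependence of the brain data, which can make it slightly
#'   anticonservative when scans of the same subject are correlated.
#' @return The `pls_result` with `perm_p` (per-LV p-values) and
#'   `perm_null` (n_perm x L matrix of permuted singular values) filled in.
#' @export
permutation_pvalues <- function(result, panel, behaviors = NULL,
                                n_perm = 1000, seed,
                                scheme = c("unrestricted", "paired")) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  scheme <- match.arg(scheme)
  behaviors <- if (result$mode == "behavioral") {
    prep_behaviors(panel, behaviors)
  } else {
    NULL
  }
  null_s <- with_seed(seed, {
    permuted_singular_values(panel, behaviors, result$behavior_columns,
                             n_perm, scheme)
  })
  result$perm_p <- vapply(seq_along(result$s), function(l) {
    mean(null_s[, l] >= result$s[l])
  }, 0)
  result$perm_null <- null_s
  result
}

# Orthogonal (procrustes) rotation aligning `u_new` onto `u_ref`.
procrustes_align <- function(u_new, u_ref) {
  sv <- svd(crossprod(u_new, u_ref))
  u_new %*% (sv$u %*% t(sv$v))
}

#' Bootstrap salience reliability (bootstrap ratios)
#'
#' Subjects are resampled with replacement with both timepoints held
#' together; for each resample the decomposition is recomputed and its
#' brain saliences are procrustes-rotated onto the original U to resolve
#' axis reflection/rotation.  The bootstrap ratio of region i on LV l is
#' BSR_il = U_il / SD_boot(U_il); |BSR| > 2 flags regions that reliably
#' carry the LV.  For behavioral mode, percentile intervals (2.5/97.5) of
#' the per-condition brain-score-behavior correlations are also returned.
#'
#' @param result A `pls_result`.
#' @param panel The panel the result was computed from.
#' @param behaviors Behavior table for behavioral mode.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @return The `pls_result` with `bsr` (regions x LV matrix, `NA` where the
#'   bootstrap SE is zero), `boot_sd`, and for behavioral mode
#'   `behavior_correlation_ci` (per condition-behavior row: lower/upper
#'   2.5/97.5 percentiles per LV).
#' @export
bootstrap_saliences <- function(result, panel, behaviors = NULL,
                                n_boot = 500, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  behaviors <- if (result$mode == "behavioral") {
    prep_behaviors(panel, behaviors)
  } else {
    NULL
  }
  n_sub <- panel_n_subjects(panel)
  p <- nrow(result$U)
  nl <- ncol(result$U)
  u_boot <- array(NA_real_, c(p, nl, n_boot))
  bc_boot <- if (result$mode == "behavioral") {
    array(NA_real_, c(nrow(result$behavior_correlations), nl, n_boot))
  } else {
    NULL
  }
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_sub, replace = TRUE)
      pb <- panel_subset_subjects(panel, idx)
      bb <- if (is.null(behaviors)) NULL else {
        behaviors[c(idx, n_sub + idx), , drop = FALSE]
      }
      r_b <- try(pls_cross_matrix(pb, bb, result$behavior_columns),
                 silent = TRUE)
      if (inherits(r_b, "try-error")) next  # degenerate resample
      sv <- pls_svd(r_b)
      u_rot <- procrustes_align(sv$u[, seq_len(nl), drop = FALSE], result$U)
      u_boot[, , b] <- u_rot
      if (!is.null(bc_boot)) {
        scores_b <- pb$values %*% u_rot
        bc_boot[, , b] <-
          brain_behavior_correlations(scores_b, pb, bb,
                                      result$behavior_columns)
      }
    }
  })
  sd_u <- apply(u_boot, c(1, 2), stats::sd, na.rm = TRUE)
  bsr <- result$U / sd_u
  if (any(sd_u == 0)) {
    warning(sprintf("bootstrap SE of 0 for %d salience element(s): BSR set to NA",
                    sum(sd_u == 0)), call. = FALSE)
    bsr[sd_u == 0] <- NA_real_
  }
  dimnames(bsr) <- list(rownames(result$U),
                        paste0("LV", seq_len(nl)))
  result$bsr <- bsr
  result$boot_sd <- sd_u
  if (!is.null(bc_boot)) {
    ci <- apply(bc_boot, c(1, 2), stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    dimnames(ci) <- list(c("lower", "upper"),
                         rownames(result$behavior_correlations),
                         paste0("LV", seq_len(nl)))
    result$behavior_correlation_ci <- ci
  }
  result
}

# Split subject indices into train/test halves; with an odd subject count
# the train half is the larger one (deterministic rule).
split_subjects <- function(n_sub) {
  n_train <- ceiling(n_sub / 2)
  train <- sample.int(n_sub, n_train)
  list(train = train, test = setdiff(seq_len(n_sub), train))
}

# z = mean/sd of per-split test singular values for one dataset.
test_train_z <- function(panel, behaviors, behavior_columns, n_splits) {
  n_sub <- panel_n_subjects(panel)
  nl <- min(dim(pls_cross_matrix(panel, behaviors, behavior_columns)))
  vals <- matrix(NA_real_, n_splits, nl)
  for (r in seq_len(n_splits)) {
    sp <- split_subjects(n_sub)
    ptr <- panel_subset_subjects(panel, sp$train)
    pte <- panel_subset_subjects(panel, sp$test)
    btr <- bte <- NULL
    if (!is.null(behaviors)) {
      btr <- behaviors[c(sp$train, n_sub + sp$train), , drop = FALSE]
      bte <- behaviors[c(sp$test, n_sub + sp$test), , drop = FALSE]
    }
    sv <- pls_svd(pls_cross_matrix(ptr, btr, behavior_columns))
    r_test <- pls_cross_matrix(pte, bte, behavior_columns)
    vals[r, ] <- diag(crossprod(sv$u, r_test %*% sv$v))[seq_len(nl)]
  }
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  list(z = mu / sdv, values = vals)
}

# z = mean/sd of per-split cross-half |cosine| similarities of brain
# saliences, LVs matched greedily by maximal |cosine|.
split_half_z <- function(panel, behaviors, behavior_columns, n_splits) {
  n_sub <- panel_n_subjects(panel)
  nl <- min(dim(pls_cross_matrix(panel, behaviors, behavior_columns)))
  vals <- matrix(NA_real_, n_splits, nl)
  for (r in seq_len(n_splits)) {
    sp <- split_subjects(n_sub)
    pa <- panel_subset_subjects(panel, sp$train)
    pb <- panel_subset_subjects(panel, sp$test)
    ba <- bb <- NULL
    if (!is.null(behaviors)) {
      ba <- behaviors[c(sp$train, n_sub + sp$train), , drop = FALSE]
      bb <- behaviors[c(sp$test, n_sub + sp$test), , drop = FALSE]
    }
    ua <- pls_svd(pls_cross_matrix(pa, ba, behavior_columns))$u
    ub <- pls_svd(pls_cross_matrix(pb, bb, behavior_columns))$u
    cosmat <- abs(crossprod(ua, ub))
    # greedy matching by maximal |cosine|
    for (k in seq_len(nl)) {
      best <- which(cosmat == max(cosmat), arr.ind = TRUE)[1, ]
      vals[r, best[1]] <- cosmat[best[1], best[2]]
      cosmat[best[1], ] <- -Inf
      cosmat[, best[2]] <- -Inf
    }
  }
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  list(z = mu / sdv, values = vals)
}

# Shared driver for the two reproducibility assessments.
reproducibility_assessment <- function(panel, behaviors, behavior_columns,
                                       n_splits, n_perm, seed, z_fun,
                                       assessment) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (panel_n_subjects(panel) < 4) {
    stop("reproducibility assessment needs at least 4 subjects",
         call. = FALSE)
  }
  behaviors <- prep_behaviors(panel, behaviors)
  n_rows <- nrow(panel$values)
  res <- with_seed(seed, {
    obs <- z_fun(panel, behaviors, behavior_columns, n_splits)
    z_null_q <- matrix(NA_real_, n_perm, length(obs$z))
    for (q in seq_len(n_perm)) {
      pp <- panel_permute_rows(panel, sample.int(n_rows))
      z_null_q[q, ] <- z_fun(pp, behaviors, behavior_columns, n_splits)$z
    }
    list(obs = obs, z_null_q = z_null_q)
  })
  z <- res$obs$z
  z_null <- colMeans(res$z_null_q)
  structure(
    list(assessment = assessment,
         z = z, z_null = z_null,
         reproducible = (z - z_null) > 2,
         values = res$obs$values,
         z_null_draws = res$z_null_q,
         n_splits = as.integer(n_splits), n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "reproducibility_report"
  )
}

#' Test-train reproducibility of PLS singular values
#'
#' Subjects are repeatedly split into halves (timepoints held together);
#' the train half's singular vectors are applied to the test half's
#' decomposed matrix, giving a distribution of "test" singular values per
#' LV whose mean/SD ratio is the reproducibility z-score.  The same
#' procedure on row-permuted data yields a null z (mean over permuted
#' datasets); an LV is flagged reproducible when z - z_null > 2.
#'
#' @param panel A cohort panel.
#' @param behaviors Behavior table for behavioral mode, `NULL` for
#'   mean-centered.
#' @param behavior_columns Behavior column names (behavioral mode only).
#' @param n_splits Number of split-half resamples (default 500).
#' @param n_perm Number of permuted null datasets, each assessed with the
#'   same number of splits (default 100).
#' @param seed Integer seed.
#' @return A `reproducibility_report` with per-LV `z`, `z_null`,
#'   `reproducible`.
#' @export
test_train_reproducibility <- function(panel, behaviors = NULL,
                                       behavior_columns = NULL,
                                       n_splits = 500, n_perm = 100, seed) {
  reproducibility_assessment(panel, behaviors, behavior_columns, n_splits,
                             n_perm, seed, test_train_z, "test_train")
}

#' Split-half reproducibility of PLS singular vectors
#'
#' Subjects are repeatedly split into halves (timepoints held together) and
#' each half decomposed independently; per LV the absolute cosine
#' similarity of the halves' brain saliences (after greedy matching of LVs
#' by maximal |cosine|) is recorded.  z = mean/SD of the similarity
#' distribution, compared against the null z from row-permuted data;
#' z - z_null > 2 flags a reproducible LV pattern.
#'
#' @inheritParams test_train_reproducibility
#' @return A `reproducibility_report` with per-LV `z`, `z_null`,
#'   `reproducible`.
#' @export
split_half_vector_reproducibility <- function(panel, behaviors = NULL,
                                              behavior_columns = NULL,
                                              n_splits = 500, n_perm = 100,
                                              seed) {
  reproducibility_assessment(panel, behaviors, behavior_columns, n_splits,
                             n_perm, seed, split_half_z, "split_half")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("<reproducibility_report> %s (%d splits, %d permutations)\n",
              x$assessment, x$n_splits, x$n_perm))
  for (l in seq_along(x$z)) {
    cat(sprintf("  LV%d: z = %.3f, z_null = %.3f -> %s\n", l, x$z[l],
                x$z_null[l],
                if (x$reproducible[l]) "reproducible" else "not reproducible"))
  }
  invisible(x)
}

#' Cosine specificity of a brain salience against another analysis
#'
#' Computes the cosine similarity between a reference brain salience and
#' the salience of a second analysis, and a permutation p-value: the scan
#' rows of the second analysis's panel are shuffled, its salience
#' recomputed, and the proportion of null |cosine| values at least as large
#' as the observed |cosine| reported.
#'
#' @param u_a Reference brain salience vector.
#' @param panel_b Panel of the second analysis.
#' @param behaviors_b,behavior_columns_b Behavior inputs of the second
#'   analysis (`NULL` for mean-centered).
#' @param lv Latent variable of the second analysis to compare (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `cosine` (signed observed value), `p`, and `null`
#'   (the |cosine| null distribution).
#' @export
salience_cosine_specificity <- function(u_a, panel_b, behaviors_b = NULL,
                                        behavior_columns_b = NULL, lv = 1,
                                        n_perm = 1000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (all(u_a == 0)) stop("`u_a` is a zero vector", call. = FALSE)
  behaviors_b <- prep_behaviors(panel_b, behaviors_b)
  u_b <- pls_svd(pls_cross_matrix(panel_b, behaviors_b,
                                  behavior_columns_b))$u[, lv]
  if (length(u_a) != length(u_b)) {
    stop("salience vectors have different lengths", call. = FALSE)
  }
  obs <- cosine_similarity(u_a, u_b)
  n_rows <- nrow(panel_b$values)
  null_cos <- with_seed(seed, {
    vapply(seq_len(n_perm), function(q) {
      pp <- panel_permute_rows(panel_b, sample.int(n_rows))
      up <- pls_svd(pls_cross_matrix(pp, behaviors_b,
                                     behavior_columns_b))$u[, lv]
      abs(cosine_similarity(u_a, up))
    }, 0)
  })
  list(cosine = obs, p = mean(null_cos >= abs(obs)), null = null_cos)
}
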