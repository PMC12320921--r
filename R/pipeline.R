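# Config-driven end-to-end runs: simulate -> metrics -> PLS -> QC.

#' Run the full analysis pipeline from a config
#'
#' Thin orchestration over the package's functions.  The config (a YAML
#' file or an equivalent named list) either requests a simulated cohort
#' (`simulate: true` with optional `cohort` parameter overrides) or names
#' input files (per-scan matrix files plus a behavior CSV).  Requested
#' stages run in order: regional metrics, modularity nulls, SC-FC
#' coupling, mean-centered and/or behavioral PLS with permutation and
#' bootstrap, and QC summaries.  All outputs are written as CSV/YAML under
#' `output_dir`, together with a run manifest recording the package
#' version, the config, and every seed, so identical config plus inputs
#' reproduce identical outputs.
#'
#' Config keys (defaults in parentheses): `simulate` (TRUE), `cohort`
#' (overrides for [cohort_spec()]), `metrics` (`"degree"`), `modality`
#' (`"FC"`), `pls_modes` (`c("mean_centered", "behavioral")`),
#' `behavior_columns` (`c("age", "sustained")`), `n_perm` (1000), `n_boot`
#' (500), `n_splits` (500), `n_perm_repro` (100), `run_reproducibility`
#' (FALSE), `n_nulls` (0: skip modularity nulls), `consensus_fraction`
#' (0.75), `seed` (1), `output_dir`.
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, a list with `manifest`, `results` (named list of in-
#'   memory results), and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(simulate = TRUE, cohort = list(), metrics = "degree",
         modality = "FC", pls_modes = c("mean_centered", "behavioral"),
         behavior_columns = c("age", "sustained"),
         n_perm = 1000, n_boot = 500, n_splits = 500, n_perm_repro = 100,
         run_reproducibility = FALSE, n_nulls = 0,
         consensus_fraction = 0.75, seed = 1, output_dir = tempfile("run")),
    config)
  if ("behavioral" %in% cfg$pls_modes && !cfg$simulate &&
      is.null(cfg$behavior_file)) {
    stop("behavioral PLS requested but no `behavior_file` given",
         call. = FALSE)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()

  if (isTRUE(cfg$simulate)) {
    spec <- do.call(cohort_spec, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$cohort))
    cohort <- generate_cohort(spec)
    scans <- if (cfg$modality == "FC") cohort$fc else cohort$sc
    behavior <- cohort$behavior
    results$spec <- spec
  } else {
    paths <- cfg$matrix_files
    scans <- lapply(seq_along(paths), function(i) {
      read_connectome_matrix(paths[[i]], modality = cfg$modality,
                             subject_id = cfg$subject_ids[[i]],
                             timepoint = cfg$timepoints[[i]])
    })
    behavior <- if (!is.null(cfg$behavior_file)) {
      read_behavior_table(cfg$behavior_file)
    } else {
      NULL
    }
  }

  metric_fun <- switch(cfg$metrics[1],
    degree = weighted_degree,
    clustering = if (cfg$modality == "FC") local_clustering_signed
                 else local_clustering_positive,
    stop(sprintf("unknown metric '%s'", cfg$metrics[1]), call. = FALSE))
  panel <- build_metric_panel(scans, metric_fun, cfg$metrics[1])
  f <- file.path(cfg$output_dir, "panel.csv")
  write_cohort_panel(panel, f)
  files <- c(files, f)
  results$panel <- panel

  if (cfg$n_nulls > 0) {
    obs <- modularity_signed(scans[[1]], n_restarts = 20,
                             seed = derive_seed(cfg$seed, 11))
    nulls <- generate_signed_null(scans[[1]], n_nulls = cfg$n_nulls,
                                  seed = derive_seed(cfg$seed, 12))
    null_q <- vapply(nulls$matrices, function(w) {
      modularity_signed(w, n_restarts = 5,
                        seed = derive_seed(cfg$seed, 13))$Q
    }, 0)
    results$modularity_null <- list(
      Q = obs$Q, null_Q = null_q,
      p = null_ensemble_pvalue(obs$Q, null_q, "greater"))
    f <- file.path(cfg$output_dir, "modularity_nulls.csv")
    utils::write.csv(data.frame(null_Q = null_q), f, row.names = FALSE)
    files <- c(files, f)
  }

  lv_rows <- list()
  for (mode in cfg$pls_modes) {
    res <- if (mode == "mean_centered") {
      mean_centered_pls(panel)
    } else {
      behavioral_pls(panel, behavior, cfg$behavior_columns)
    }
    res <- permutation_pvalues(res, panel,
                               behaviors = if (mode == "behavioral") behavior,
                               n_perm = cfg$n_perm,
                               seed = derive_seed(cfg$seed, 21, nchar(mode)))
    res <- bootstrap_saliences(res, panel,
                               behaviors = if (mode == "behavioral") behavior,
                               n_boot = cfg$n_boot,
                               seed = derive_seed(cfg$seed, 22, nchar(mode)))
    if (isTRUE(cfg$run_reproducibility)) {
      res$test_train <- test_train_reproducibility(
        panel, behaviors = if (mode == "behavioral") behavior,
        behavior_columns = if (mode == "behavioral") cfg$behavior_columns,
        n_splits = cfg$n_splits, n_perm = cfg$n_perm_repro,
        seed = derive_seed(cfg$seed, 23, nchar(mode)))
      res$split_half <- split_half_vector_reproducibility(
        panel, behaviors = if (mode == "behavioral") behavior,
        behavior_columns = if (mode == "behavioral") cfg$behavior_columns,
        n_splits = cfg$n_splits, n_perm = cfg$n_perm_repro,
        seed = derive_seed(cfg$seed, 24, nchar(mode)))
    }
    results[[mode]] <- res
    for (l in seq_along(res$s)) {
      lv_rows[[length(lv_rows) + 1L]] <- data.frame(
        mode = mode, lv = l, s = res$s[l], p = res$perm_p[l],
        z_test_train = res$test_train$z[l] %||% NA_real_,
        z_null_test_train = res$test_train$z_null[l] %||% NA_real_,
        z_split_half = res$split_half$z[l] %||% NA_real_,
        z_null_split_half = res$split_half$z_null[l] %||% NA_real_)
    }
    base <- file.path(cfg$output_dir, mode)
    utils::write.csv(data.frame(region = rownames(res$U), res$U),
                     paste0(base, "_saliences.csv"), row.names = FALSE)
    utils::write.csv(data.frame(region = rownames(res$bsr), res$bsr),
                     paste0(base, "_bsr.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject = panel$subject_ids,
                                condition = panel$condition,
                                res$brain_scores),
                     paste0(base, "_brain_scores.csv"), row.names = FALSE)
    files <- c(files, paste0(base, c("_saliences.csv", "_bsr.csv",
                                     "_brain_scores.csv")))
  }
  lv_summary <- do.call(rbind, lv_rows)
  f <- file.path(cfg$output_dir, "lv_summary.csv")
  utils::write.csv(lv_summary, f, row.names = FALSE)
  files <- c(files, f)
  results$lv_summary <- lv_summary

  if (cfg$modality == "FC" && length(scans) >= 2) {
    results$fingerprint <- fingerprint_match_rate(scans)
  }

  manifest <- list(
    package = "scfcpls",
    version = as.character(utils::packageVersion("scfcpls")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "cohort")],
    created = "run manifest"
  )
  f <- file.path(cfg$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, f)
  files <- c(files, f)

  invisible(list(manifest = manifest, results = results, files = files))
}

#' Render a human-readable run report
#'
#' Formats the per-LV table (singular values, permutation p, reproducibility
#' z-scores with the +-2 rule), the top bootstrap-ratio regions per LV at
#' the given threshold, and the QC summary.
#'
#' @param results The `results` element of a [run_pipeline()] return value
#'   (or a compatible list).
#' @param bsr_threshold |BSR| threshold for the region table (default 2).
#' @param file Optional path; when given the report is also written there.
#' @return The report as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
write_report <- function(results, bsr_threshold = 2, file = NULL) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(results$lv_summary) && nrow(results$lv_summary) > 0) {
    add("Latent variables")
    for (i in seq_len(nrow(results$lv_summary))) {
      r <- results$lv_summary[i, ]
      repro <- if (!is.na(r$z_test_train) && !is.na(r$z_null_test_train)) {
        if ((r$z_test_train - r$z_null_test_train) > 2) " [reproducible]"
        else " [not reproducible]"
      } else {
        ""
      }
      add("  %s LV%d: s = %.4f, p = %.4g%s", r$mode, r$lv, r$s, r$p, repro)
    }
  }
  for (mode in intersect(c("mean_centered", "behavioral"), names(results))) {
    res <- results[[mode]]
    if (is.null(res$bsr)) next
    top <- which(abs(res$bsr[, 1]) > bsr_threshold)
    top <- top[order(-abs(res$bsr[top, 1]))]
    add("Reliable regions (|BSR| > %.1f), %s LV1: %d", bsr_threshold,
        mode, length(top))
    for (j in utils::head(top, 10)) {
      add("  %s  BSR = %.2f", rownames(res$bsr)[j], res$bsr[j, 1])
    }
  }
  if (!is.null(results$modularity_null)) {
    add("Modularity vs null models: Q = %.4f, empirical p = %.4g",
        results$modularity_null$Q, results$modularity_null$p)
  }
  if (!is.null(results$fingerprint)) {
    add("Fingerprint match rate: %.2f%%", 100 * results$fingerprint)
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
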