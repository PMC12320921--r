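# Synthetic paired two-timepoint SC/FC cohorts with planted structure.

#' Specify a synthetic cohort
#'
#' Collects all parameters of the planted-structure generator emulating a
#' paired two-timepoint pediatric cohort: modular SC matrices (streamline
#' proportions), FC matrices coupled to SC with retained negative weights,
#' subject-specific fingerprint components, a planted longitudinal FC
#' change, and a planted brain-behavior salience linking FC weighted degree
#' to attention scores.
#'
#' Defaults mirror the study conditions the pipeline targets: 39 subjects,
#' 193 regions, two timepoints, baseline ages uniform on 4.14-6.88 years
#' with a one-year follow-up.
#'
#' @param n_subjects Number of paired subjects (default 39).
#' @param n_regions Number of regions (default 193).
#' @param n_modules Number of planted SC modules (default 4, contiguous
#'   blocks).
#' @param sc_within_mean,sc_between_mean Mean raw within-/between-module
#'   edge intensities before row normalization (defaults 1 and 0.25).
#' @param fc_coupling_strength Scale of the monotone SC-to-FC map
#'   (default 3).
#' @param fc_noise_sd SD of the stochastic FC component on the Fisher-z
#'   scale (default 0.15), split between the subject fingerprint and scan
#'   noise by `fingerprint_icc`.
#' @param fingerprint_icc Share of stochastic FC variance that is
#'   subject-specific and stable across timepoints, in \[0, 1)
#'   (default 0.6).
#' @param planted_salience List with `u` (unit-norm region vector, default
#'   +1/sqrt(40) on regions 1-20 and -1/sqrt(40) on regions 21-40) and
#'   `beta` (behavior-score SDs per SD of the latent brain score,
#'   default 3: a strong planted brain-behavior effect).
#' @param salience_edge_scale Edge-level scale of the planted salience
#'   component (default 0.2): scan latent g adds
#'   `g * scale * (u_i + u_j)` to edge (i, j).
#' @param longitudinal_delta Per-region additive FC change at timepoint 2
#'   applied as `(delta_i + delta_j) / 2` per edge (default +-0.05 on
#'   regions 41-80, zero elsewhere: a strong planted longitudinal effect
#'   on regions disjoint from the planted salience support).
#' @param modularity_age_slope Relative increase of the between-module SC
#'   intensity per year of age above the cohort mean (default 0.05): older
#'   children get relatively stronger between-module weights, hence lower
#'   modularity Q.
#' @param seed Integer master seed; every generated object is a pure
#'   function of (spec, subject, timepoint).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 39, n_regions = 193, n_modules = 4,
                        sc_within_mean = 1, sc_between_mean = 0.25,
                        fc_coupling_strength = 3, fc_noise_sd = 0.15,
                        fingerprint_icc = 0.6,
                        planted_salience = NULL,
                        salience_edge_scale = 0.2,
                        longitudinal_delta = NULL,
                        modularity_age_slope = 0.05,
                        seed = 1L) {
  if (n_modules > n_regions) {
    stop("`n_modules` cannot exceed `n_regions`", call. = FALSE)
  }
  if (sc_within_mean < 0 || sc_between_mean < 0) {
    stop("SC intensities must be non-negative", call. = FALSE)
  }
  if (fingerprint_icc < 0 || fingerprint_icc >= 1) {
    stop("`fingerprint_icc` must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(planted_salience)) {
    u <- numeric(n_regions)
    k <- min(40L, n_regions)
    u[seq_len(k)] <- rep(c(1, -1), each = ceiling(k / 2))[seq_len(k)]
    u <- u / sqrt(sum(u^2))
    planted_salience <- list(u = u, beta = 3)
  }
  if (abs(sqrt(sum(planted_salience$u^2)) - 1) > 1e-8) {
    stop("planted salience `u` must have unit norm", call. = FALSE)
  }
  if (length(planted_salience$u) != n_regions) {
    stop("planted salience `u` must have one entry per region",
         call. = FALSE)
  }
  if (is.null(longitudinal_delta)) {
    longitudinal_delta <- numeric(n_regions)
    if (n_regions >= 80) {
      longitudinal_delta[41:60] <- 0.05
      longitudinal_delta[61:80] <- -0.05
    }
  }
  if (length(longitudinal_delta) != n_regions) {
    stop("`longitudinal_delta` must have one entry per region",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_modules = as.integer(n_modules),
         sc_within_mean = sc_within_mean,
         sc_between_mean = sc_between_mean,
         fc_coupling_strength = fc_coupling_strength,
         fc_noise_sd = fc_noise_sd,
         fingerprint_icc = fingerprint_icc,
         planted_salience = planted_salience,
         salience_edge_scale = salience_edge_scale,
         longitudinal_delta = longitudinal_delta,
         modularity_age_slope = modularity_age_slope,
         age_range_t1 = c(4.14, 6.88),
         age_reference = 5.76,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Planted contiguous module assignment.
spec_modules <- function(spec) {
  rep(seq_len(spec$n_modules),
      each = ceiling(spec$n_regions / spec$n_modules))[seq_len(spec$n_regions)]
}

region_names <- function(spec) sprintf("R%03d", seq_len(spec$n_regions))

subject_names <- function(spec) sprintf("s%02d", seq_len(spec$n_subjects))

#' Ages of a synthetic subject
#'
#' Baseline age is uniform on the spec's baseline range; the follow-up age
#' adds one year plus a small jitter.  Pure function of (spec, subject).
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index.
#' @param timepoint 1 or 2.
#' @return Age in years.
#' @export
subject_age <- function(spec, subject, timepoint) {
  with_seed(derive_seed(spec$seed, 301, subject), {
    a1 <- stats::runif(1, spec$age_range_t1[1], spec$age_range_t1[2])
    jit <- stats::rnorm(1, 0, 0.1)
    if (timepoint == 1) a1 else a1 + 1 + jit
  })
}

# Scan-level latent brain score driving the planted salience and behavior.
scan_latent <- function(spec, subject, timepoint) {
  with_seed(derive_seed(spec$seed, 401, subject, timepoint),
            stats::rnorm(1))
}

# Symmetric zero-diagonal matrix with iid N(0, sd) upper-triangle entries.
sym_noise <- function(n, sd) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- stats::rnorm(sum(ut), 0, sd)
  m + t(m)
}

#' Generate one scan's modular SC matrix
#'
#' Block-structured non-negative symmetric streamline-proportion matrix:
#' within-module edge intensities are drawn around `sc_within_mean`
#' (presence probability 0.95), between-module around an age-adjusted
#' `sc_between_mean` (presence probability 0.6), then rows are scaled to
#' streamline proportions and symmetrized via
#' [normalize_and_symmetrize_sc()].  Older subjects get relatively stronger
#' between-module intensities (`modularity_age_slope`), lowering Q.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index.
#' @param timepoint 1 or 2.
#' @return An SC `connectome_matrix`.
#' @export
generate_modular_sc <- function(spec, subject, timepoint) {
  age <- subject_age(spec, subject, timepoint)
  mods <- spec_modules(spec)
  n <- spec$n_regions
  between_eff <- spec$sc_between_mean *
    max(0, 1 + spec$modularity_age_slope * (age - spec$age_reference))
  with_seed(derive_seed(spec$seed, 101, subject, timepoint), {
    same <- outer(mods, mods, `==`)
    ut <- upper.tri(same)
    n_edges <- sum(ut)
    is_within <- same[ut]
    mean_vec <- ifelse(is_within, spec$sc_within_mean, between_eff)
    sd_vec <- ifelse(is_within, 0.25 * spec$sc_within_mean,
                     0.4 * max(between_eff, 1e-12))
    present_p <- ifelse(is_within, 0.95, 0.6)
    present <- stats::runif(n_edges) < present_p
    raw <- pmax(stats::rnorm(n_edges, mean_vec, sd_vec), 0.01 * mean_vec)
    raw[!present | mean_vec == 0] <- 0
    counts <- matrix(0, n, n)
    counts[ut] <- raw
    counts <- counts + t(counts)
    suppressWarnings(
      normalize_and_symmetrize_sc(counts, region_names(spec),
                                  subject_id = subject_names(spec)[subject],
                                  timepoint = timepoint)
    )
  })
}

#' Generate one scan's FC matrix from its SC matrix
#'
#' FC on the Fisher-z scale: a monotone transform of SC
#' (`fc_coupling_strength * sqrt(SC)`), plus the scan latent's planted
#' salience component `g * salience_edge_scale * (u_i + u_j)`, plus the
#' longitudinal change `(delta_i + delta_j) / 2` at timepoint 2, plus a
#' subject-specific fingerprint component (variance share
#' `fingerprint_icc`, identical at both timepoints) and scan-specific
#' symmetric noise.  Negative weights occur; diagonal is zero.
#'
#' @param sc The scan's SC `connectome_matrix` (from
#'   [generate_modular_sc()]).
#' @param spec A [cohort_spec()].
#' @param subject Subject index.
#' @param timepoint 1 or 2.
#' @return An FC `connectome_matrix`.
#' @export
generate_fc_from_sc <- function(sc, spec, subject, timepoint) {
  w <- conn_weights(sc)
  n <- nrow(w)
  base <- spec$fc_coupling_strength * sqrt(w)
  g <- scan_latent(spec, subject, timepoint)
  u <- spec$planted_salience$u
  planted <- g * spec$salience_edge_scale * (outer(u, rep(1, n)) +
                                             outer(rep(1, n), u))
  drift <- if (timepoint == 2) {
    d <- spec$longitudinal_delta
    (outer(d, rep(1, n)) + outer(rep(1, n), d)) / 2
  } else {
    0
  }
  fingerprint <- with_seed(derive_seed(spec$seed, 202, subject), {
    sym_noise(n, spec$fc_noise_sd * sqrt(spec$fingerprint_icc))
  })
  noise <- with_seed(derive_seed(spec$seed, 203, subject, timepoint), {
    sym_noise(n, spec$fc_noise_sd * sqrt(1 - spec$fingerprint_icc))
  })
  z <- base + planted + drift + fingerprint + noise
  diag(z) <- 0
  connectome_matrix(z, region_names(spec), "FC",
                    subject_id = subject_names(spec)[subject],
                    timepoint = timepoint)
}

#' Generate a full paired synthetic cohort
#'
#' Generates every subject's SC and FC matrices at both timepoints (in the
#' canonical order: all timepoint-1 scans, then all timepoint-2 scans, same
#' subject order) and a behavior table in which each attention score is an
#' age trend plus `beta` times the scan's latent brain score (the same
#' latent that loads the planted salience onto the FC edges) plus noise.
#' The ground-truth record stores everything a test needs to assert
#' recovery.
#'
#' @param spec A [cohort_spec()].
#' @return List with `sc` and `fc` (lists of `connectome_matrix`, canonical
#'   scan order), `behavior` (a `behavior_table`), and `truth` (list with
#'   `u`, `beta`, `partition`, `longitudinal_delta`, `ages`, `latent`).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  order_df <- data.frame(
    subject = rep(seq_len(n), 2),
    timepoint = rep(1:2, each = n)
  )
  sc <- vector("list", nrow(order_df))
  fc <- vector("list", nrow(order_df))
  ages <- numeric(nrow(order_df))
  latent <- numeric(nrow(order_df))
  for (i in seq_len(nrow(order_df))) {
    s <- order_df$subject[i]
    t <- order_df$timepoint[i]
    sc[[i]] <- generate_modular_sc(spec, s, t)
    fc[[i]] <- generate_fc_from_sc(sc[[i]], spec, s, t)
    ages[i] <- subject_age(spec, s, t)
    latent[i] <- scan_latent(spec, s, t)
  }
  names(sc) <- names(fc) <- sprintf("%s_t%d",
                                    subject_names(spec)[order_df$subject],
                                    order_df$timepoint)
  beta <- spec$planted_salience$beta
  behavior <- with_seed(derive_seed(spec$seed, 501), {
    dage <- ages - spec$age_reference
    data.frame(
      subject_id = subject_names(spec)[order_df$subject],
      timepoint = order_df$timepoint,
      age = ages,
      sustained = 21 + 2.3 * dage + beta * latent +
        stats::rnorm(length(ages), 0, 1),
      selective = pmin(18, pmax(0, 9 + 1.78 * dage + 0.8 * beta * latent +
                                  stats::rnorm(length(ages), 0, 1))),
      executive = pmin(0, -15 + 4 * dage + 1.5 * beta * latent +
                         stats::rnorm(length(ages), 0, 2))
    )
  })
  list(sc = sc, fc = fc, behavior = as_behavior_table(behavior),
       truth = list(u = spec$planted_salience$u, beta = beta,
                    partition = spec_modules(spec),
                    longitudinal_delta = spec$longitudinal_delta,
                    ages = ages, latent = latent))
}

#' Stack a regional metric over a list of scans into a cohort panel
#'
#' Applies a per-scan metric to every `connectome_matrix` in `scans` and
#' stacks the results into the canonical paired panel.
#'
#' @param scans List of `connectome_matrix` objects (each carrying
#'   `subject_id` and `timepoint`).
#' @param metric_fun Function mapping a `connectome_matrix` to a numeric
#'   vector (e.g. [weighted_degree()]) or scalar.
#' @param metric_name Panel label.
#' @return A `cohort_panel`.
#' @export
build_metric_panel <- function(scans, metric_fun = weighted_degree,
                               metric_name = "degree") {
  first <- metric_fun(scans[[1]])
  vals <- t(vapply(scans, function(m) as.numeric(metric_fun(m)),
                   numeric(length(first))))
  colnames(vals) <- if (!is.null(names(first))) {
    names(first)
  } else if (length(first) == 1) {
    metric_name
  } else {
    paste0("R", seq_along(first))
  }
  build_cohort_panel(vals,
                     vapply(scans, function(m) as.character(m$subject_id), ""),
                     vapply(scans, function(m) m$timepoint, 0L),
                     metric_name)
}

#' Generate motion values and a motion-contaminated edge panel
#'
#' Draws a per-scan motion summary (mean framewise displacement) and an
#' unstructured scans x edges panel of Fisher-z-scale noise in which a
#' chosen fraction of edges receives additive motion-proportional
#' contamination.  The panel is deliberately independent across scans and
#' edges so that QC-FC calibration is exact under no contamination.
#'
#' @param spec A [cohort_spec()] (supplies scan count, noise scale, seed).
#' @param contaminated_edges Fraction of edges contaminated, in \[0, 1\]
#'   (default 0).
#' @param n_edges Number of edges in the panel (default 200).
#' @param contamination_strength Contamination amplitude in units of the
#'   edge noise SD per SD of motion (default 1).
#' @return List with `motion` (per-scan values), `panel` (scans x edges
#'   matrix), `contaminated` (edge indices).
#' @export
generate_motion_confound <- function(spec, contaminated_edges = 0,
                                     n_edges = 200,
                                     contamination_strength = 1) {
  if (contaminated_edges < 0 || contaminated_edges > 1) {
    stop("`contaminated_edges` must lie in [0, 1]", call. = FALSE)
  }
  n_scans <- 2L * spec$n_subjects
  with_seed(derive_seed(spec$seed, 601), {
    motion <- abs(stats::rnorm(n_scans, 0.15, 0.05))
    panel <- matrix(stats::rnorm(n_scans * n_edges, 0.3, spec$fc_noise_sd),
                    n_scans, n_edges)
    k <- round(contaminated_edges * n_edges)
    contaminated <- if (k > 0) sample.int(n_edges, k) else integer(0)
    if (k > 0) {
      zmot <- as.numeric(scale(motion))
      panel[, contaminated] <- panel[, contaminated] +
        contamination_strength * spec$fc_noise_sd * zmot
    }
    list(motion = motion, panel = panel, contaminated = contaminated)
  })
}
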