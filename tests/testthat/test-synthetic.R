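# Synthetic cohort generator: invariants, determinism, planted structure.

test_that("generated matrices satisfy connectome invariants", {
  sp <- cohort_spec(n_subjects = 3, n_regions = 50, seed = 5)
  for (s in 1:3) {
    for (t in 1:2) {
      sc <- generate_modular_sc(sp, s, t)
      fc <- generate_fc_from_sc(sc, sp, s, t)
      expect_equal(sc$weights, t(sc$weights))
      expect_equal(fc$weights, t(fc$weights))
      expect_equal(unname(diag(sc$weights)), rep(0, 50))
      expect_equal(unname(diag(fc$weights)), rep(0, 50))
      expect_true(all(sc$weights >= 0))
      expect_true(any(fc$weights < 0))  # FC retains negative weights
    }
  }
})

test_that("generators are pure functions of (spec, subject, timepoint)", {
  sp <- cohort_spec(n_subjects = 2, n_regions = 40, seed = 9)
  expect_identical(generate_modular_sc(sp, 1, 1),
                   generate_modular_sc(sp, 1, 1))
  sc <- generate_modular_sc(sp, 1, 2)
  expect_identical(generate_fc_from_sc(sc, sp, 1, 2),
                   generate_fc_from_sc(sc, sp, 1, 2))
  expect_identical(generate_motion_confound(sp, 0.2),
                   generate_motion_confound(sp, 0.2))
  # different scans differ
  expect_false(identical(generate_modular_sc(sp, 1, 1)$weights,
                         generate_modular_sc(sp, 2, 1)$weights))
  # calling a generator does not disturb the caller's RNG stream
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(generate_modular_sc(sp, 1, 1))
  expect_identical(rnorm(1), a)
})

test_that("zero between-module weight lets Louvain recover the planted partition", {
  sp <- cohort_spec(n_subjects = 2, n_regions = 48, n_modules = 4,
                    sc_between_mean = 0, seed = 3)
  m <- generate_modular_sc(sp, 1, 1)
  part <- modularity_signed(m, seed = 2, n_restarts = 10)$partition
  truthp <- scfcpls:::spec_modules(sp)
  # adjusted agreement 1: communities coincide exactly with planted modules
  tab <- table(part, truthp)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("a larger age slope strengthens the negative age-modularity trend", {
  cors <- vapply(c(0, 0.3), function(sl) {
    sp <- cohort_spec(n_subjects = 12, n_regions = 48,
                      modularity_age_slope = sl, seed = 7)
    qs <- vapply(1:12, function(s) {
      modularity_signed(generate_modular_sc(sp, s, 1), seed = 1,
                        n_restarts = 5)$Q
    }, 0)
    ages <- vapply(1:12, function(s) subject_age(sp, s, 1), 0)
    cor(ages, qs)
  }, 0)
  expect_lt(cors[2], -0.8)   # strong slope: strongly negative trend
  expect_lt(cors[2], cors[1])
})

test_that("noise-free fully-coupled FC has coupling 1 everywhere", {
  sp <- cohort_spec(n_subjects = 2, n_regions = 40, fc_noise_sd = 0,
                    fingerprint_icc = 0, salience_edge_scale = 0, seed = 5)
  sc <- generate_modular_sc(sp, 1, 1)
  fc <- generate_fc_from_sc(sc, sp, 1, 1)
  cp <- regional_scfc_coupling(sc, fc)
  expect_equal(unname(cp), rep(1, 40), tolerance = 1e-12)
})

test_that("cohorts have the canonical shape and a recoverable planted effect", {
  sp <- cohort_spec(seed = 2)
  co <- generate_cohort(sp)
  expect_length(co$fc, 78)
  panel <- build_metric_panel(co$fc, weighted_degree, "degree_fc")
  expect_identical(dim(panel$values), c(78L, 193L))
  expect_identical(panel$condition, rep(1:2, each = 39))
  # behavior table invariants hold
  expect_true(all(co$behavior$selective >= 0 & co$behavior$selective <= 18))
  expect_true(all(co$behavior$executive <= 0))
  # planted salience is recovered by behavioral PLS at the default SNR
  res <- behavioral_pls(panel, co$behavior, "sustained")
  expect_gte(abs(scfcpls:::cosine_similarity(res$U[, 1], co$truth$u)), 0.9)
  # planted longitudinal change is flagged with opposite BSR signs
  mres <- suppressWarnings(bootstrap_saliences(mean_centered_pls(panel),
                                               panel, n_boot = 100,
                                               seed = 11))
  up <- co$truth$longitudinal_delta > 0
  dn <- co$truth$longitudinal_delta < 0
  expect_gte(mean(abs(mres$bsr[up | dn, 1]) > 2), 0.8)
  expect_lt(median(mres$bsr[up, 1]) * median(mres$bsr[dn, 1]), 0)
})

test_that("motion confound contaminates the requested edge fraction", {
  sp <- cohort_spec(n_subjects = 30, seed = 4)
  mc <- generate_motion_confound(sp, contaminated_edges = 0.5, n_edges = 200,
                                 contamination_strength = 2)
  expect_length(mc$motion, 60)
  expect_identical(dim(mc$panel), c(60L, 200L))
  expect_length(mc$contaminated, 100)
  qc <- qcfc_summary(mc$panel, mc$motion)
  expect_gte(qc$fraction_significant, 0.4)
  # contaminated edges are the significant ones
  expect_gt(mean(qc$p_values[mc$contaminated] < 0.05), 0.9)
  expect_error(generate_motion_confound(sp, 1.5), "\\[0, 1\\]")
})
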