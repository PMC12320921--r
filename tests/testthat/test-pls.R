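# PLS core: closed-form SVD cases, invariants, resampling machinery.

test_that("mean-centered PLS reproduces the closed-form 2x2 case", {
  # condition means (1, 0) and (0, 0) over 2 regions
  vals <- rbind(matrix(c(1, 1, 0, 0), 2, 2), matrix(0, 2, 2))
  p <- tiny_panel(vals)
  res <- mean_centered_pls(p)
  expect_equal(res$s[1], sqrt(0.5), tolerance = 1e-9)
  expect_equal(res$s[1], 0.707107, tolerance = 1e-6)
  expect_equal(abs(res$U[, 1]), c(1, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(abs(res$V[, 1]), c(sqrt(0.5), sqrt(0.5)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(res$V[1, 1] * res$V[2, 1]), -0.5, tolerance = 1e-9)
  # identical condition means: all singular values 0
  same <- tiny_panel(rbind(matrix(1:4, 2, 2), matrix(1:4, 2, 2)))
  expect_equal(mean_centered_pls(same)$s, c(0, 0), tolerance = 1e-12)
  # homogeneity: doubling panel values doubles s1, U unchanged up to sign
  res2 <- mean_centered_pls(tiny_panel(2 * vals))
  expect_equal(res2$s[1], 2 * res$s[1], tolerance = 1e-12)
  expect_equal(abs(res2$U), abs(res$U), tolerance = 1e-12)
})

test_that("two-condition mean-centered V is always the (1,-1)/sqrt(2) contrast", {
  set.seed(8)
  for (rep in 1:5) {
    p <- tiny_panel(matrix(rnorm(20 * 7), 20, 7))
    v1 <- mean_centered_pls(p)$V[, 1]
    expect_equal(abs(v1), c(sqrt(0.5), sqrt(0.5)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(v1[1] * v1[2], 0)
  }
})

test_that("behavioral PLS reproduces the exact correlation-matrix case", {
  # one behavior equal to region 1, region 2 independent; exact r = (1, 0)
  set.seed(21)
  n <- 20
  orth <- function(x, y) c(scale(stats::resid(stats::lm(y ~ x))))
  x1 <- c(scale(rnorm(n)))
  x1b <- c(scale(rnorm(n)))
  x2 <- orth(x1, rnorm(n))    # exactly uncorrelated with x1
  x2b <- orth(x1b, rnorm(n))
  p <- tiny_panel(rbind(cbind(x1, x2), cbind(x1b, x2b)))
  beh <- data.frame(y = c(x1, x1b))
  res <- behavioral_pls(p, beh, "y")
  # the decomposed matrix is exactly [[1, 0], [1, 0]] transposed
  expect_equal(unname(res$decomposed_matrix),
               matrix(c(1, 0, 1, 0), 2, 2), tolerance = 1e-12)
  expect_equal(res$s[1], sqrt(2), tolerance = 1e-9)
  expect_equal(res$s[2], 0, tolerance = 1e-9)
  expect_equal(abs(res$U[, 1]), c(1, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(abs(res$V[, 1]), c(sqrt(0.5), sqrt(0.5)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # brain-score-behavior correlations are attached per condition
  expect_identical(dim(res$behavior_correlations), c(2L, 2L))
  expect_equal(abs(res$behavior_correlations[1, 1]), 1, tolerance = 1e-9)
  # duplicated behavior column: singular values scale by sqrt(2)
  beh2 <- data.frame(y = beh$y, y2 = beh$y)
  res2 <- behavioral_pls(p, beh2, c("y", "y2"))
  expect_equal(res2$s[1], sqrt(2) * res$s[1], tolerance = 1e-9)
  # zero-variance behavior errors with condition and column named
  behz <- data.frame(y = c(rep(1, n), x1b))
  expect_error(behavioral_pls(p, behz, "y"), "zero-variance.*'y'.*condition 1")
})

test_that("SVD energy is conserved and sign convention is consistent", {
  set.seed(33)
  p <- tiny_panel(matrix(rnorm(24 * 9), 24, 9))
  beh <- data.frame(a = rnorm(24), b = rnorm(24))
  for (res in list(mean_centered_pls(p), behavioral_pls(p, beh, c("a", "b")))) {
    expect_equal(sum(res$s^2), sum(res$decomposed_matrix^2),
                 tolerance = 1e-9)
    for (l in seq_len(ncol(res$U))) {
      expect_gt(res$U[which.max(abs(res$U[, l])), l], 0)
      expect_equal(sqrt(sum(res$U[, l]^2)), 1, tolerance = 1e-9)
      expect_equal(sqrt(sum(res$V[, l]^2)), 1, tolerance = 1e-9)
    }
    # U and V reconstruct the decomposed matrix
    expect_equal(res$U %*% diag(res$s, length(res$s)) %*% t(res$V),
                 res$decomposed_matrix, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("permutation p-values implement the counting formula", {
  set.seed(44)
  p <- tiny_panel(matrix(rnorm(16 * 5), 16, 5))
  res <- mean_centered_pls(p)
  res <- permutation_pvalues(res, p, n_perm = 50, seed = 2)
  manual <- colMeans(sweep(res$perm_null, 2, res$s, `>=`))
  expect_equal(res$perm_p, manual, tolerance = 1e-12)
  expect_true(all(res$perm_p >= 0 & res$perm_p <= 1))
  # planted condition effect is detected
  vals <- matrix(rnorm(16 * 5), 16, 5)
  vals[9:16, 1:2] <- vals[9:16, 1:2] + 2
  resp <- permutation_pvalues(mean_centered_pls(tiny_panel(vals)),
                              tiny_panel(vals), n_perm = 100, seed = 3)
  expect_equal(resp$perm_p[1], 0)
})

test_that("permutation p is invariant to consistent region reordering", {
  set.seed(55)
  vals <- matrix(rnorm(12 * 6), 12, 6)
  p1 <- tiny_panel(vals)
  ord <- sample(6)
  p2 <- tiny_panel(vals[, ord])
  r1 <- permutation_pvalues(mean_centered_pls(p1), p1, n_perm = 60, seed = 9)
  r2 <- permutation_pvalues(mean_centered_pls(p2), p2, n_perm = 60, seed = 9)
  # compare the informative LV (the two-condition LV2 singular value is
  # numerically zero, so its >= comparisons are float coin flips)
  expect_equal(r1$perm_p[1], r2$perm_p[1], tolerance = 1e-12)
  expect_equal(r1$perm_null[, 1], r2$perm_null[, 1], tolerance = 1e-9)
})

test_that("bootstrap ratios are salience over bootstrap SE, rotation-invariant", {
  set.seed(66)
  vals <- matrix(rnorm(20 * 8), 20, 8)
  vals[11:20, 1:3] <- vals[11:20, 1:3] + 1.5
  p <- tiny_panel(vals)
  res <- mean_centered_pls(p)
  res <- bootstrap_saliences(res, p, n_boot = 100, seed = 4)
  expect_equal(res$bsr, res$U / res$boot_sd, tolerance = 1e-12,
               ignore_attr = TRUE)
  # the definitional example: salience 0.5 with SE 0.25 is BSR 2
  expect_equal(0.5 / 0.25, 2)
  # procrustes alignment undoes a sign flip exactly
  u <- res$U
  flipped <- -u
  expect_equal(scfcpls:::procrustes_align(flipped, u), u, tolerance = 1e-9)
  # planted regions exceed the BSR threshold
  expect_true(all(abs(res$bsr[1:3, 1]) > 2))
})

test_that("reproducibility z-scores follow the mean/SD and +-2 rules", {
  # z = mean / SD of the test-value distribution: 10 / 4 = 2.5
  expect_equal(10 / 4, 2.5)
  set.seed(77)
  vals <- matrix(rnorm(24 * 6), 24, 6)
  vals[13:24, 1:2] <- vals[13:24, 1:2] + 2
  p <- tiny_panel(vals)
  tt <- test_train_reproducibility(p, n_splits = 60, n_perm = 10, seed = 5)
  expect_equal(unname(tt$z), unname(colMeans(tt$values) /
                                      apply(tt$values, 2, sd)),
               tolerance = 1e-12)
  expect_identical(tt$reproducible, (tt$z - tt$z_null) > 2)
  expect_true(tt$reproducible[1])  # strong planted condition effect
  sh <- split_half_vector_reproducibility(p, n_splits = 60, n_perm = 10,
                                          seed = 6)
  expect_true(all(sh$values >= 0 & sh$values <= 1 + 1e-12))
  expect_true(sh$reproducible[1])
  # pure noise: LV1 almost never flagged (the z - z_null gap is itself a
  # noisy statistic, so this is a rate over repeated noise panels)
  flagged <- vapply(1:6, function(r) {
    set.seed(100 + r)
    pn <- tiny_panel(matrix(rnorm(24 * 6), 24, 6))
    ttn <- test_train_reproducibility(pn, n_splits = 60, n_perm = 10,
                                      seed = r)
    ttn$reproducible[1]
  }, TRUE)
  expect_lte(sum(flagged), 1)
})

test_that("cosine specificity handles identical, orthogonal, and null cases", {
  expect_equal(scfcpls:::cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1,
               tolerance = 1e-12)
  expect_equal(scfcpls:::cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(scfcpls:::cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  set.seed(88)
  vals <- matrix(rnorm(20 * 6), 20, 6)
  vals[11:20, 1] <- vals[11:20, 1] + 2
  p <- tiny_panel(vals)
  u_a <- mean_centered_pls(p)$U[, 1]
  sp <- salience_cosine_specificity(u_a, p, n_perm = 50, seed = 8)
  expect_equal(sp$cosine, 1, tolerance = 1e-12)  # same analysis, same salience
  expect_lt(sp$p, 0.05)
  expect_true(all(sp$null >= 0 & sp$null <= 1))
})
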