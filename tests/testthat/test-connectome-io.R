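# Matrix ingestion, normalization, exclusion, consensus, panel assembly.

test_that("fisher z transform matches arctanh and preserves structure", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3, 3)
  m <- fisher_z_transform(r)
  expect_equal(m$weights[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(m$weights[1, 2], 0.549306, tolerance = 1e-6)
  expect_equal(m$weights[2, 3], atanh(-0.3), tolerance = 1e-12)
  expect_identical(diag(m$weights), c(R1 = 0, R2 = 0, R3 = 0))
  expect_equal(m$weights, t(m$weights))
  expect_identical(m$modality, "FC")
  # round trip: tanh of the z matrix recovers r off-diagonal
  back <- tanh(m$weights)
  diag(back) <- 1
  expect_equal(back, unname(r), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fisher z transform rejects out-of-range correlations", {
  r <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(fisher_z_transform(r), "outside")
})

test_that("SC normalization divides rows by their sums then symmetrizes", {
  counts <- matrix(c(0, 10, 10, 10, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  m <- normalize_and_symmetrize_sc(counts)
  expect_equal(unname(m$weights),
               matrix(c(0, 0.75, 0.75, 0.75, 0, 0, 0.75, 0, 0), 3, 3),
               tolerance = 1e-12)
  # all-equal off-diagonal counts -> all weights 1/(N-1)
  n <- 5
  eq <- matrix(7, n, n)
  diag(eq) <- 0
  meq <- normalize_and_symmetrize_sc(eq)
  expect_equal(unname(meq$weights[upper.tri(meq$weights)]),
               rep(1 / (n - 1), n * (n - 1) / 2), tolerance = 1e-12)
  # already-symmetric proportion matrix: symmetrization is idempotent
  again <- normalize_and_symmetrize_sc(meq$weights * 100)
  expect_equal(again$weights, meq$weights, tolerance = 1e-12)
})

test_that("SC normalization flags zero rows and rejects negatives", {
  counts <- matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_warning(m <- normalize_and_symmetrize_sc(counts), "zero streamline")
  expect_equal(unname(m$weights[3, ]), c(0, 0, 0))
  expect_error(normalize_and_symmetrize_sc(matrix(c(0, -1, -1, 0), 2, 2)),
               "non-negative")
})

test_that("row sums before symmetrization equal 1 for positive rows", {
  set.seed(11)
  counts <- matrix(rpois(100, 5), 10, 10)
  diag(counts) <- 0
  rs <- rowSums(counts)
  w <- counts / rs  # the normalization the package applies pre-symmetrization
  expect_equal(unname(rowSums(w)[rs > 0]), rep(1, sum(rs > 0)))
  # and the package output is the symmetrized version of exactly that
  m <- normalize_and_symmetrize_sc(counts)
  expect_equal(unname(m$weights), unname((w + t(w)) / 2) - diag(diag((w + t(w)) / 2)),
               tolerance = 1e-12)
})

test_that("region exclusion removes rows/columns and keeps order", {
  set.seed(2)
  labs <- sprintf("roi%03d", 1:200)
  w <- random_sym_graph(200, density = 0.2)
  m <- connectome_matrix(w, labs, "SC")
  excl <- labs[c(3, 50, 77, 120, 150, 180, 200)]
  m2 <- apply_region_exclusion(m, excl)
  expect_identical(dim(m2$weights), c(193L, 193L))
  expect_identical(m2$region_labels, setdiff(labs, excl))
  keep <- !(labs %in% excl)
  expect_equal(m2$weights, m$weights[keep, keep])
  # empty exclusion is the identity
  expect_equal(apply_region_exclusion(m, character(0))$weights, m$weights)
  # excluding all but 2 regions keeps the original edge weight
  m3 <- apply_region_exclusion(m, labs[-c(1, 2)])
  expect_equal(m3$weights[1, 2], m$weights[1, 2])
  expect_error(apply_region_exclusion(m, "nope"), "unknown region")
})

test_that("consensus thresholding retains edges present in enough scans", {
  base <- matrix(0, 4, 4)
  mk <- function(edges) {
    w <- base
    for (e in edges) w[e[1], e[2]] <- w[e[2], e[1]] <- 0.5
    connectome_matrix(w, paste0("R", 1:4), "SC")
  }
  # edge (1,2) present in 3 of 4 scans; edge (3,4) in 2 of 4
  panel <- list(mk(list(c(1, 2), c(3, 4))), mk(list(c(1, 2), c(3, 4))),
                mk(list(c(1, 2))), mk(list(c(2, 3))))
  ct <- consensus_threshold(panel, 0.75)
  expect_true(ct$mask[1, 2])
  expect_false(ct$mask[3, 4])
  expect_false(ct$mask[2, 3])
  expect_equal(ct$panel[[1]]$weights[3, 4], 0)
  expect_equal(ct$panel[[1]]$weights[1, 2], 0.5)
  expect_true(isSymmetric(ct$mask))
  # per-scan zeroed-edge counts support the cohort summary
  expect_equal(ct$zeroed$n_zeroed[1], 1)
})

test_that("consensus mask is monotone in the fraction and exact at limits", {
  set.seed(7)
  panel <- replicate(6, {
    w <- random_sym_graph(12, density = 0.4)
    connectome_matrix(w, paste0("R", 1:12), "SC")
  }, simplify = FALSE)
  fracs <- c(0.17, 0.5, 0.67, 0.83, 1)
  masks <- lapply(fracs, function(f) consensus_threshold(panel, f)$mask)
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # raising f never adds edges
  }
  # tiny fraction keeps every edge present in >= 1 scan
  union_support <- Reduce(`|`, lapply(panel, function(m) m$weights > 0))
  diag(union_support) <- FALSE
  expect_equal(consensus_threshold(panel, 1e-9)$mask, union_support)
  # identical panels: mask equals their binary support at any fraction
  same <- replicate(3, panel[[1]], simplify = FALSE)
  supp <- panel[[1]]$weights > 0
  diag(supp) <- FALSE
  expect_equal(consensus_threshold(same, 0.75)$mask, supp)
})

test_that("cohort panels stack condition blocks in canonical order", {
  set.seed(3)
  vals <- matrix(rnorm(6 * 4), 6, 4)
  subs <- c("b", "a", "c", "a", "c", "b")
  tps <- c(1, 1, 1, 2, 2, 2)
  p <- build_cohort_panel(vals, subs, tps, "degree")
  expect_identical(dim(p$values), c(6L, 4L))
  expect_identical(p$condition, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(p$subject_ids[1:3], p$subject_ids[4:6])
  # row content follows the subject/timepoint key
  expect_equal(p$values[1, ], vals[1, ])  # b, t1
  expect_equal(p$values[4 + which(p$subject_ids[4:6] == "a") - 1, ],
               vals[4, ])                 # a, t2
  # scalar metric gives an S x 1 panel
  q <- build_cohort_panel(rnorm(6), subs, tps, "Q")
  expect_identical(dim(q$values), c(6L, 1L))
  expect_error(build_cohort_panel(vals[-1, ], subs[-1], tps[-1]),
               "missing a timepoint")
})

test_that("matrix and panel round-trip through delimited text", {
  set.seed(5)
  m <- connectome_matrix(random_sym_graph(6), sprintf("area%d", 1:6), "FC",
                         subject_id = "s01", timepoint = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_connectome_matrix(m, f)
  m2 <- read_connectome_matrix(f, "FC", subject_id = "s01", timepoint = 2)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_identical(m2$region_labels, m$region_labels)
  # whitespace-delimited, no header, labels from file
  f2 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(m$weights, f2, row.names = FALSE, col.names = FALSE)
  lf <- withr::local_tempfile()
  writeLines(m$region_labels, lf)
  m3 <- read_connectome_matrix(f2, "FC", labels_file = lf)
  expect_equal(unname(m3$weights), unname(m$weights), tolerance = 1e-12)
  expect_identical(m3$region_labels, m$region_labels)
  # panel round trip
  p <- tiny_panel(matrix(rnorm(8), 4, 2))
  fp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_panel(p, fp)
  p2 <- read_cohort_panel(fp)
  expect_equal(p2$values, p$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(p2$condition, p$condition)
})
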