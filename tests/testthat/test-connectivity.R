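test_that("correlation_matrix matches the textbook formula with a zeroed diagonal", {
  set.seed(1)
  ts <- matrix(stats::rnorm(500), 100, 5)
  m <- correlation_matrix(ts)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) next
      xi <- ts[, i] - mean(ts[, i])
      xj <- ts[, j] - mean(ts[, j])
      oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  expect_equal(unclass(m), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(m), rep(0, 5), ignore_attr = TRUE)

  dup <- cbind(ts[, 1], ts[, 1], ts[, 2])
  expect_equal(correlation_matrix(dup)[1, 2], 1)
  neg <- cbind(ts[, 1], -ts[, 1])
  expect_equal(correlation_matrix(neg)[1, 2], -1)
})

test_that("degenerate time series are rejected with the region named", {
  ts <- matrix(stats::rnorm(60), 20, 3)
  colnames(ts) <- c("a", "b", "c")
  ts[, 2] <- 5
  expect_error(correlation_matrix(ts), "constant time series.*b")
  expect_error(correlation_matrix(ts[1:2, ]), "at least 3 time points")
})

test_that("rectification zeroes negatives and nothing else", {
  set.seed(2)
  m <- correlation_matrix(matrix(stats::rnorm(400), 50, 8))
  r <- rectify_negative(m)
  expect_true(all(unclass(r) >= 0))
  pos <- unclass(m) > 0
  expect_identical(unclass(r)[pos], unclass(m)[pos])
  expect_true(attr(r, "rectified"))
  allneg <- matrix(-0.5, 3, 3); diag(allneg) <- 0
  expect_equal(unclass(rectify_negative(allneg)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(rectify_negative(matrix(stats::runif(9), 3, 3)), "symmetric")
})

uniform_matrix <- function(n = 34, w = 0.5) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  rectify_negative(m)
}

test_that("correlation thresholding keeps strictly supra-threshold edges", {
  m <- uniform_matrix(6, 0.4)
  expect_equal(attr(threshold_correlation(m, 0), "density"), 1)
  expect_equal(attr(threshold_correlation(m, 0.4), "density"), 0)  # strict
  expect_equal(attr(threshold_correlation(m, 1), "density"), 0)
  expect_error(threshold_correlation(m, -0.1), "non-negative")
})

test_that("sparsity thresholding retains an exact edge count with lexicographic ties", {
  set.seed(3)
  cohort <- small_cohort(seed = 3, n_pat = 3, n_ctl = 3)
  m <- cohort_connectivity(cohort)[[1]]
  g <- threshold_sparsity(m, 0.34)
  expect_equal(sum(unclass(g)[upper.tri(g)]), 191)  # round(0.34 * 561)
  expect_equal(attr(threshold_sparsity(uniform_matrix(6, 0.2), 1),
                    "density"), 1)
  # tie at the cutoff: all weights equal, keep lexicographically first pairs
  tie <- uniform_matrix(4, 0.3)
  g2 <- threshold_sparsity(tie, round(2 / 6, 2))  # 2 edges of 6
  kept <- which(unclass(g2) == 1 & upper.tri(g2), arr.ind = TRUE)
  expect_equal(unname(kept[order(kept[, 1]), ]),
               matrix(c(1, 1, 2, 3), 2, 2))
  expect_error(threshold_sparsity(m, 0), "sparsity")
  zero <- uniform_matrix(5, 0)
  expect_error(threshold_sparsity(zero, 0.5), "positive weights")
})

test_that("sparsity edge sets are nested and cohort densities uniform", {
  cohort <- small_cohort(seed = 5, n_pat = 4, n_ctl = 4)
  mats <- cohort_connectivity(cohort)
  dens <- vapply(mats, function(m) {
    attr(threshold_sparsity(m, 0.3), "density")
  }, numeric(1))
  expect_equal(length(unique(round(dens, 10))), 1)
  dens_r <- vapply(mats, function(m) {
    attr(threshold_correlation(m, 0.2), "density")
  }, numeric(1))
  expect_gt(length(unique(dens_r)), 1)
  # nestedness under the deterministic tie rule
  m <- mats[[1]]
  for (pair in list(c(0.1, 0.2), c(0.2, 0.45), c(0.05, 0.4))) {
    g_small <- unclass(threshold_sparsity(m, pair[1]))
    g_big <- unclass(threshold_sparsity(m, pair[2]))
    expect_true(all(g_big[g_small == 1] == 1))
  }
})

test_that("threshold selection applies the 2 log N degree floor per subject", {
  # single complete uniform-weight subject: every correlation threshold below
  # the weight keeps the complete graph, so the max correlation threshold is
  # the last grid point below it; the minimal sparsity is the first grid
  # point whose edge count pushes mean degree above 2 ln 34 ~ 7.05
  m <- uniform_matrix(34, 0.5)
  sel <- select_thresholds(list(m))
  expect_equal(sel$max_correlation_threshold, 0.49)
  expect_equal(sel$min_sparsity_threshold, 0.22)
  expect_equal(sel$degree_floor, 2 * log(34))
  # closed form: round(s * 561) * 2 / 34 > 7.05 first holds at s = 0.22
  expect_false(round(0.21 * 561) * 2 / 34 > 2 * log(34))
  expect_true(round(0.22 * 561) * 2 / 34 > 2 * log(34))

  zero <- uniform_matrix(5, 0)
  expect_error(select_thresholds(list(zero)), "no threshold")
  expect_error(select_thresholds(list()), "empty cohort")
})

test_that("matrices serialize with a JSON sidecar", {
  m <- uniform_matrix(4, 0.3)
  path <- tempfile(fileext = ".tsv")
  write_matrix(threshold_sparsity(m, 0.5), path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$threshold_kind, "sparsity")
  expect_equal(meta$threshold_value, 0.5)
})
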