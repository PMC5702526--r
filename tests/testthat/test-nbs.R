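# build a toy cohort of connectivity matrices with full control over signs
toy_mats <- function(weights) {
  lapply(seq_len(nrow(weights)), function(s) {
    n <- (1 + sqrt(1 + 8 * ncol(weights))) / 2
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- weights[s, ]
    m <- m + t(m)
    rectify_negative(m)
  })
}

test_that("the prevalence mask pools both groups with a >= rule", {
  set.seed(1)
  w <- matrix(stats::runif(100 * 3, 0.1, 0.5), 100, 3)
  w[1:49, 2] <- 0    # positive in 51% of subjects
  w[1:51, 3] <- 0    # positive in 49%
  mask <- edge_inclusion_mask(toy_mats(w), prevalence = 0.5)
  expect_true(mask[1])
  expect_true(mask[2])
  expect_false(mask[3])
  expect_error(edge_inclusion_mask(list()), "empty cohort")
})

test_that("edge-wise t statistics match the textbook two-sample formula", {
  set.seed(2)
  w <- matrix(stats::rnorm(6 * 4), 6, 4)
  groups <- rep(c("control", "patient"), each = 3)
  out <- edgewise_tstats(w, groups)
  for (e in 1:4) {
    tt <- stats::t.test(w[1:3, e], w[4:6, e], var.equal = TRUE)
    expect_equal(out$t[e], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_equal(out$df, 4)
  same <- rbind(w[1:3, ], w[1:3, ])
  expect_equal(edgewise_tstats(same, groups)$t, rep(0, 4))
  const <- matrix(1, 6, 2)
  expect_warning(out0 <- edgewise_tstats(const, groups), "zero pooled")
  expect_equal(out0$t, c(0, 0))
  expect_error(edgewise_tstats(w[1:3, ], c("a", "a", "b")), "2 subjects")
})

test_that("covariate residualization absorbs confounds and flags collinearity", {
  set.seed(3)
  n <- 40
  groups <- rep(c("control", "patient"), each = n / 2)
  signal <- ifelse(groups == "control", 1, 0)
  w <- matrix(stats::rnorm(n * 5, sd = 0.3), n, 5) + signal
  # covariate identical to group labels absorbs the effect
  res <- residualize_edges(w, data.frame(grp = signal))
  expect_lt(max(abs(edgewise_tstats(res, groups)$t)), 1e-8)
  # orthogonal noise covariates barely change the statistics
  res2 <- residualize_edges(w, data.frame(x = stats::rnorm(n)))
  raw <- edgewise_tstats(scale(w, scale = FALSE), groups)$t
  expect_equal(edgewise_tstats(res2, groups)$t, raw, tolerance = 0.15)
  expect_error(residualize_edges(w, data.frame(a = 1:n, b = 2 * (1:n))),
               "collinear")
  expect_error(residualize_edges(w, data.frame(con = rep(1, n))),
               "collinear")
})

test_that("supra-threshold components reproduce the published component shape", {
  atlas <- fixture_atlas()
  comp <- fixture_component(atlas)
  pairs <- ctrlnet:::ut_pairs(34)
  t_stat <- rep(0, nrow(pairs))
  key <- paste(pairs[, 1], pairs[, 2])
  t_stat[key %in% paste(comp$i, comp$j)] <- 5
  comps <- supra_components(t_stat, df = 75, primary_p = 0.05,
                            pairs = pairs, n_nodes = 34)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 30)
  expect_equal(comps[[1]]$n_nodes, 26)
  expect_length(supra_components(rep(0, nrow(pairs)), 75, pairs = pairs,
                                 n_nodes = 34), 0)
})

test_that("component extraction agrees with an independent flood-fill oracle", {
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    pairs <- ctrlnet:::ut_pairs(n)
    t_stat <- stats::rnorm(nrow(pairs), sd = 2)
    comps <- supra_components(t_stat, df = 30, primary_p = 0.05,
                              tail = "two_sided", pairs = pairs, n_nodes = n)
    sel <- 2 * stats::pt(-abs(t_stat), 30) < 0.05
    oracle <- oracle_edge_components(pairs, sel)
    expect_equal(sort(unname(vapply(comps, `[[`, numeric(1), "n_edges"))),
                 sort(unname(lengths(oracle))))
  }
})

test_that("nbs_test is deterministic, direction-aware and conservative on ties", {
  cohort <- small_cohort(seed = 6, n_pat = 10, n_ctl = 10, n_vol = 80)
  mats <- cohort_connectivity(cohort)
  cov <- cohort_covariates(cohort)
  cfg <- nbs_config(n_perm = 200, seed = 4)
  r1 <- nbs_test(mats, cohort$group, cov, cfg)
  r2 <- nbs_test(mats, cohort$group, cov, cfg)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_identical(glance(r1), glance(r2))
  # corrected p uses strictly-larger counting
  if (length(r1$components) > 0) {
    m <- r1$components[[1]]$n_edges
    expect_equal(r1$components[[1]]$corrected_p,
                 mean(r1$null_max_sizes > m))
    # add-one insertion of the observed value stays a valid p
    p_ins <- (sum(r1$null_max_sizes > m) + 1) / (length(r1$null_max_sizes) + 1)
    expect_gt(p_ins, 0)
    expect_lte(p_ins, 1)
  }
  # two-sided corrected p invariant to which group is called positive
  cfg2 <- nbs_config(n_perm = 150, tail = "two_sided", seed = 9)
  ra <- nbs_test(mats, cohort$group, cov, cfg2)
  flipped <- ifelse(cohort$group == "patient", "control", "patient")
  rb <- nbs_test(mats, flipped, cov, cfg2)
  expect_equal(vapply(ra$components, `[[`, numeric(1), "corrected_p"),
               vapply(rb$components, `[[`, numeric(1), "corrected_p"))
})

test_that("exhaustive enumeration kicks in for tiny cohorts", {
  cohort <- small_cohort(seed = 7, n_pat = 3, n_ctl = 3, n_vol = 80)
  mats <- cohort_connectivity(cohort)
  expect_warning(
    res <- nbs_test(mats, cohort$group, NULL, nbs_config(n_perm = 100,
                                                         seed = 1)),
    "exhaustively")
  expect_equal(res$n_exhaustive, choose(6, 3))
  expect_length(res$null_max_sizes, choose(6, 3))
})

test_that("lowering the primary threshold shrinks the supra-threshold edge set", {
  cohort <- small_cohort(seed = 8, n_pat = 8, n_ctl = 8, n_vol = 80)
  mats <- cohort_connectivity(cohort)
  t_obs <- edgewise_tstats(
    residualize_edges(ctrlnet:::edge_weight_table(mats)$weights, NULL),
    cohort$group)
  pairs <- ctrlnet:::ut_pairs(34)
  edges_at <- function(p) {
    comps <- supra_components(t_obs$t, t_obs$df, p, pairs = pairs,
                              n_nodes = 34)
    do.call(rbind, lapply(comps, function(x) cbind(x$edges$i, x$edges$j)))
  }
  loose <- edges_at(0.10)
  strict <- edges_at(0.01)
  if (!is.null(strict)) {
    expect_true(all(paste(strict[, 1], strict[, 2]) %in%
                      paste(loose[, 1], loose[, 2])))
  }
  expect_gte(NROW(loose), NROW(strict))
})

test_that("component mean strength averages the right entries", {
  m <- matrix(0.2, 5, 5)
  diag(m) <- 0
  comp <- tibble::tibble(i = c(1, 2, 3), j = c(2, 3, 4))
  expect_equal(component_mean_strength(m, comp), 0.2)
  m[1, 2] <- m[2, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.1
  expect_equal(component_mean_strength(m, comp), mean(c(0.4, 0.1, 0.2)))
  expect_error(component_mean_strength(m, comp[0, ]), "empty")
  expect_error(component_mean_strength(m, tibble::tibble(i = 1, j = 9)),
               "outside")
})
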