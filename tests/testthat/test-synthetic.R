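test_that("group covariance targets follow the block-and-planting design", {
  atlas <- fixture_atlas()
  cfg <- cohort_config()
  ctl <- build_group_covariance(atlas, cfg, "control")
  pat <- build_group_covariance(atlas, cfg, "patient")
  expect_true(isSymmetric(ctl))
  expect_equal(diag(ctl), rep(1, 34), ignore_attr = TRUE)
  expect_gt(min(eigen(ctl, symmetric = TRUE)$values), 0)
  expect_gt(min(eigen(pat, symmetric = TRUE)$values), 0)

  same <- outer(atlas$network, atlas$network, "==")
  pe <- ctrlnet:::resolve_planted(atlas, cfg)
  planted <- matrix(FALSE, 34, 34)
  planted[pe] <- TRUE
  planted <- planted | t(planted)
  ut <- upper.tri(ctl)
  expect_equal(unique(ctl[ut & same]), 0.45)
  expect_equal(unique(ctl[ut & !same]), 0.15)
  # hypoconnectivity planting: reduced by effect_delta, floored at zero
  # (the default planted set is entirely inter-network, so 0.15 - 0.25 -> 0)
  expect_gt(sum(ut & planted), 0)
  expect_equal(pat[ut & planted], rep(0, sum(ut & planted)))
  expect_equal(pat[ut & !planted], ctl[ut & !planted])
  # a within-network planted edge is reduced by the full delta
  cfg_w <- cohort_config(planted_edges = cbind(1, 2))
  pat_w <- build_group_covariance(atlas, cfg_w, "patient")
  expect_equal(pat_w[1, 2], 0.45 - 0.25)

  # no effect, no difference
  cfg0 <- cohort_config(effect_delta = 0)
  expect_equal(build_group_covariance(atlas, cfg0, "patient"),
               build_group_covariance(atlas, cfg0, "control"))
})

test_that("a single network with zero between-network target is compound symmetric", {
  flat <- as_atlas(data.frame(name = letters[1:4], abbreviation = letters[1:4],
                              x = 1:4, y = 0, z = 0, network = "FPN"))
  cfg <- cohort_config(base_within_network_r = 0.3,
                       base_between_network_r = 0, effect_delta = 0)
  m <- build_group_covariance(flat, cfg, "control")
  expect_equal(unname(m), 0.3 + 0.7 * diag(4))
})

test_that("the default planted component is 30 long-range inter-network edges on 26 nodes", {
  atlas <- fixture_atlas()
  pe <- planted_long_range_component(atlas)
  expect_equal(nrow(pe), 30)
  expect_equal(length(unique(as.vector(pe))), 26)
  d <- ctrlnet:::dist_lookup(pairwise_distances(atlas))
  expect_true(all(d[pe] > 75))
  expect_true(all(atlas$network[pe[, 1]] != atlas$network[pe[, 2]]))
  gi <- igraph::graph_from_edgelist(
    matrix(match(pe, unique(as.vector(pe))), ncol = 2), directed = FALSE)
  expect_equal(igraph::count_components(gi), 1)
  # deterministic
  expect_identical(pe, planted_long_range_component(atlas))
})

test_that("cohort generation is deterministic and structurally sound", {
  cohort <- small_cohort(seed = 7)
  again <- small_cohort(seed = 7)
  expect_identical(cohort$timeseries, again$timeseries)
  expect_identical(cohort$age, again$age)
  expect_false(identical(cohort$timeseries, small_cohort(seed = 8)$timeseries))

  expect_equal(nrow(cohort), 16)
  expect_equal(sum(cohort$group == "patient"), 8)
  expect_true(all(vapply(cohort$timeseries, function(ts) {
    all(dim(ts) == c(80, 34)) && !anyNA(ts)
  }, logical(1))))
  expect_true(all(cohort$hyperactivity_index >= 0 &
                    cohort$hyperactivity_index <= 3))
})

test_that("long series reproduce the target correlation matrix", {
  atlas <- fixture_atlas()
  cfg <- cohort_config(n_patients = 2, n_controls = 2, n_volumes = 20000,
                       subject_sd = 0, temporal_ar = 0, seed = 42)
  cohort <- generate_cohort(atlas, cfg)
  target <- build_group_covariance(atlas, cfg, "patient")
  emp <- stats::cor(cohort$timeseries[[1]])
  expect_lt(max(abs(emp - target)), 0.02)
})

test_that("temporal autocorrelation matches the AR(1) setting", {
  atlas <- fixture_atlas()
  cfg <- cohort_config(n_patients = 2, n_controls = 2, n_volumes = 8000,
                       subject_sd = 0, temporal_ar = 0.3, seed = 3)
  ts <- generate_cohort(atlas, cfg)$timeseries[[1]]
  lag1 <- mean(vapply(seq_len(34), function(j) {
    stats::cor(ts[-1, j], ts[-nrow(ts), j])
  }, numeric(1)))
  expect_equal(lag1, 0.3, tolerance = 0.03)
})

test_that("covariates have no built-in group difference but clinical scores do", {
  cohort <- generate_cohort(fixture_atlas(),
                            cohort_config(n_patients = 150, n_controls = 150,
                                          n_volumes = 70, seed = 9))
  pat <- cohort$group == "patient"
  for (v in c("age", "iq", "gender", "motion_meanFD")) {
    expect_gt(stats::t.test(cohort[[v]][pat], cohort[[v]][!pat])$p.value,
              0.001)
  }
  expect_gt(mean(cohort$hyperactivity_index[pat]),
            mean(cohort$hyperactivity_index[!pat]) + 0.5)
  expect_gt(mean(cohort$impulsive_score[pat]),
            mean(cohort$impulsive_score[!pat]) + 0.5)
})

test_that("patient clinical scores track realized planted connectivity", {
  atlas <- fixture_atlas()
  cohort <- generate_cohort(atlas, cohort_config(n_patients = 120,
                                                 n_controls = 10,
                                                 n_volumes = 80, seed = 5))
  pe <- attr(cohort, "planted_edges")
  pat <- which(cohort$group == "patient")
  strength <- vapply(cohort$timeseries[pat], function(ts) {
    mean(stats::cor(ts)[pe])
  }, numeric(1))
  r <- stats::cor(strength, cohort$hyperactivity_index[pat])
  expect_gt(r, 0.15)
})

test_that("vine partial-correlation transform round-trips and stays PD", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    r <- stats::cor(matrix(stats::rnorm(n * 50), 50, n))
    p <- ctrlnet:::partial_from_corr(r)
    expect_equal(ctrlnet:::corr_from_partial(p), r, tolerance = 1e-10)
  }
  # jittered targets remain valid correlation matrices
  atlas <- fixture_atlas()
  cohort <- small_cohort(seed = 2, n_pat = 3, n_ctl = 3)
  for (ts in cohort$timeseries) expect_false(anyNA(ts))
})

test_that("cohorts round-trip through disk", {
  cohort <- small_cohort(seed = 4, n_pat = 3, n_ctl = 3)
  dir <- tempfile("cohort_")
  write_cohort(cohort, dir)
  back <- read_cohort(dir, fixture_atlas())
  expect_equal(back$subject_id, cohort$subject_id)
  expect_equal(back$group, cohort$group)
  expect_equal(back$timeseries[[1]], unname(cohort$timeseries[[1]]),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(read_cohort(tempfile(), fixture_atlas()), "phenotype")
})

test_that("configuration validation rejects invalid settings", {
  expect_error(cohort_config(base_within_network_r = 1.2), "correlation")
  expect_error(cohort_config(temporal_ar = 1), "temporal_ar")
  expect_error(cohort_config(subject_sd = -0.1), "subject_sd")
  expect_error(cohort_config(covariates = list(nope = 1)), "unknown covariate")
  expect_error(cohort_config(covariates = list(age_sd = -1)), "non-negative")
  expect_error(generate_cohort(fixture_atlas(),
                               cohort_config(n_volumes = 40)),
               "at least 2 \\* N")
})
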