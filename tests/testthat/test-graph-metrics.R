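path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  binary_graph(a)
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L
  binary_graph(a)
}

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  binary_graph(a)
}

test_that("shortest paths and geodesic counts match hand cases", {
  k4 <- shortest_paths_data(complete_graph(4))
  expect_equal(k4$d, 1 - diag(4), ignore_attr = TRUE)
  p3 <- shortest_paths_data(path_graph(3))
  expect_equal(p3$d[1, 3], 2)
  expect_equal(p3$sigma[1, 3], 1)
  # 4-cycle: two geodesics across the diagonal
  c4 <- matrix(0L, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1L
  c4 <- binary_graph(c4 + t(c4))
  expect_equal(shortest_paths_data(c4)$sigma[1, 3], 2)
  # disconnected pair
  two <- binary_graph(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  sp <- shortest_paths_data(two)
  expect_equal(sp$d[1, 3], Inf)
  expect_equal(sp$sigma[1, 3], 0)
})

test_that("efficiencies reproduce hand-enumerated values", {
  expect_equal(global_efficiency(complete_graph(5)), 1)
  empty <- binary_graph(matrix(0L, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  # star with 4 leaves: 8 ordered pairs at d=1, 12 at d=2
  expect_equal(global_efficiency(star_graph(4)), (8 + 12 * 0.5) / 20)
  expect_equal(local_efficiency(complete_graph(4)), 1)
  expect_equal(local_efficiency(star_graph(4)), 0)
})

test_that("modularity formula matches hand calculation and igraph", {
  # two triangles joined by a bridge, natural split
  a <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  }
  g <- binary_graph(a)
  p <- c(1, 1, 1, 2, 2, 2)
  expect_equal(modularity_of_partition(g, p), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)
  expect_equal(modularity_of_partition(g, rep(1, 6)), 0)
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    rg <- random_graph(n, 0.5)
    if (sum(rg) == 0) next
    part <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_of_partition(rg, part),
                 oracle_modularity(unclass(rg), part), tolerance = 1e-12)
  }
  expect_error(modularity_of_partition(g, c(1, 1, 1)), "length")
  expect_error(modularity_of_partition(binary_graph(matrix(0L, 3, 3)),
                                       c(1, 2, 3)), "edgeless")
})

test_that("spectral module detection separates planted structure deterministically", {
  # two disjoint cliques
  a <- matrix(0L, 8, 8)
  a[1:4, 1:4] <- 1L
  a[5:8, 5:8] <- 1L
  diag(a) <- 0L
  g <- binary_graph(a)
  part <- detect_modules(g)
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$membership[1:4])), 1)
  expect_equal(length(unique(part$membership[5:8])), 1)
  expect_identical(detect_modules(g)$membership, part$membership)
  expect_error(detect_modules(binary_graph(matrix(0L, 4, 4))), "edgeless")
  # q_max is the modularity of the returned partition
  set.seed(5)
  rg <- random_graph(10, 0.3)
  pp <- detect_modules(rg)
  expect_equal(pp$q_max, modularity_of_partition(rg, pp$membership))
  expect_equal(sum(pp$l_s), sum(vapply(unique(pp$membership), function(m) {
    idx <- pp$membership == m
    sum(unclass(rg)[idx, idx]) / 2
  }, numeric(1))))
  expect_equal(sum(pp$d_s), 2 * pp$L)
})

test_that("nodal metrics match their definitions on canonical graphs", {
  nm <- nodal_metrics(star_graph(4))
  expect_equal(nm$degree, c(4, 1, 1, 1, 1))
  expect_equal(nm$betweenness[1], choose(4, 2))
  expect_equal(nm$betweenness[-1], rep(0, 4))
  nm2 <- nodal_metrics(complete_graph(5))
  expect_equal(nm2$betweenness, rep(0, 5))
  expect_equal(nm2$efficiency, rep(1, 5))
  set.seed(6)
  for (rep in 1:30) {
    rg <- random_graph(sample(4:12, 1), stats::runif(1, 0.2, 0.7))
    nm3 <- nodal_metrics(rg)
    gi <- igraph::graph_from_adjacency_matrix(unclass(rg), "undirected")
    expect_equal(nm3$betweenness, igraph::betweenness(gi), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(nm3$degree, rowSums(unclass(rg)), ignore_attr = TRUE)
  }
})

test_that("rewired nulls preserve the degree sequence exactly", {
  set.seed(7)
  g <- random_graph(15, 0.3)
  nulls <- rewire_null(g, n_nulls = 15, seed = 3)
  expect_length(nulls, 15)
  for (null in nulls) {
    expect_equal(sort(rowSums(unclass(null))), sort(rowSums(unclass(g))))
  }
  expect_true(any(vapply(nulls, function(x) !identical(unclass(x),
                                                       unclass(g)),
                         logical(1))))
  # cycle stays 2-regular
  c6 <- matrix(0L, 6, 6)
  c6[cbind(1:6, c(2:6, 1))] <- 1L
  c6 <- binary_graph(c6 + t(c6))
  expect_equal(unique(rowSums(unclass(rewire_null(c6, 3, seed = 1)[[1]]))), 2)
  # same seed, same nulls
  expect_identical(lapply(rewire_null(g, 4, seed = 9), unclass),
                   lapply(rewire_null(g, 4, seed = 9), unclass))
  tiny <- binary_graph(rbind(c(0, 1), c(1, 0)))
  expect_warning(rewire_null(tiny, 2, seed = 1), "constrained")
})

test_that("null normalization is a plain ratio with guards", {
  g <- random_graph(12, 0.4)
  real <- global_metrics(g)
  expect_equal(
    as.numeric(normalize_globals(real, list(real, real))[
      , c("normalized_e_glob", "normalized_e_loc", "normalized_q")]),
    c(1, 1, 1))
  expect_error(normalize_globals(real, list()), "at least one null")
  fake <- real
  fake$e_loc <- 0
  expect_error(normalize_globals(real, list(fake)), "e_loc is zero")
})

test_that("adding an edge never decreases global efficiency or degree", {
  set.seed(8)
  for (rep in 1:20) {
    g <- random_graph(10, 0.3)
    a <- unclass(g)
    open <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(open) == 0) next
    pick <- open[sample(nrow(open), 1), ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(binary_graph(a2)), global_efficiency(g))
    expect_true(all(rowSums(a2) >= rowSums(a)))
  }
})
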