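# Independent brute-force oracles used to validate the graph machinery.

fixture_atlas <- function() load_atlas(ctrlnet_file("control_atlas.tsv"))

fixture_component <- function(atlas = fixture_atlas()) {
  load_component_edges(ctrlnet_file("nbs_component_edges.csv"), atlas)
}

random_graph <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  binary_graph(a)
}

# Floyd-Warshall shortest path lengths, written independently of the BFS
# implementation under test.
fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

efficiency_from_distances <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(d) * (nrow(d) - 1))
}

# local efficiency oracle: neighbourhood subgraphs + Floyd-Warshall
oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_from_distances(fw_distances(a[nb, nb, drop = FALSE]))
  }, numeric(1)))
}

oracle_modularity <- function(a, membership) {
  gi <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::modularity(gi, membership)
}

# enumerate all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxval + 1)) recurse(c(prefix, v), max(maxval, v))
  }
  recurse(1L, 1L)
  out
}

# exhaustive best modularity over every partition (tiny graphs only)
oracle_best_modularity <- function(a) {
  n <- nrow(a)
  big_l <- sum(a) / 2
  k <- rowSums(a)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- 0
    for (mod in unique(p)) {
      idx <- p == mod
      q <- q + sum(a[idx, idx]) / 2 / big_l - (sum(k[idx]) / (2 * big_l))^2
    }
    if (q > best) best <- q
  }
  best
}

# components of an edge subset by repeated flood fill (independent of the
# igraph-based implementation)
oracle_edge_components <- function(pairs, sel) {
  sub <- pairs[sel, , drop = FALSE]
  if (nrow(sub) == 0) return(list())
  nodes <- sort(unique(as.vector(sub)))
  comp_id <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    key <- as.character(start)
    if (!is.na(comp_id[key])) next
    cur <- cur + 1L
    frontier <- start
    comp_id[key] <- cur
    while (length(frontier) > 0) {
      nxt <- unique(c(sub[sub[, 1] %in% frontier, 2],
                      sub[sub[, 2] %in% frontier, 1]))
      nxt <- nxt[is.na(comp_id[as.character(nxt)])]
      comp_id[as.character(nxt)] <- cur
      frontier <- nxt
    }
  }
  split(seq_len(nrow(sub)), comp_id[as.character(sub[, 1])])
}

default_covariate_names <- c("age", "gender", "iq", "motion_max",
                             "motion_rms", "motion_meanFD")

cohort_covariates <- function(cohort) {
  as.data.frame(cohort)[, default_covariate_names, drop = FALSE]
}

# tiny cohort for fast end-to-end tests
small_cohort <- function(seed = 1, n_pat = 8, n_ctl = 8, n_vol = 80, ...) {
  generate_cohort(fixture_atlas(),
                  cohort_config(n_patients = n_pat, n_controls = n_ctl,
                                n_volumes = n_vol, seed = seed, ...))
}
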