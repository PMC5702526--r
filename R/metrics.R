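as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(unclass(g) > 0, mode = "undirected",
                                      diag = FALSE)
}

check_binary <- function(g) {
  a <- unclass(g)
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  if (!isSymmetric(a)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  invisible(a)
}

#' Binary graph from an adjacency matrix
#'
#' @param a Symmetric 0/1 matrix with zero diagonal.
#' @return A `binary_graph`.
#' @export
binary_graph <- function(a) {
  a <- check_binary(a)
  storage.mode(a) <- "integer"
  new_binary_graph(a, "manual", NA_real_)
}

#' Hop distances and geodesic counts
#'
#' Breadth-first-search shortest path lengths between all node pairs, together
#' with the number of distinct shortest paths per pair. Disconnected pairs
#' have infinite distance and zero geodesic count.
#'
#' @param g A `binary_graph`.
#' @return A list of class `shortest_path_data` with `d` (N x N hop counts)
#'   and `sigma` (N x N geodesic counts).
#' @export
shortest_paths_data <- function(g) {
  a <- check_binary(g)
  n <- nrow(a)
  d <- igraph::distances(as_igraph(g))
  dimnames(d) <- dimnames(a)
  # geodesic counts by dynamic programming over BFS levels:
  # sigma[s, v] = sum of sigma[s, u] over neighbours u one hop closer to s
  sigma <- matrix(0, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ds <- d[s, ]
    finite_levels <- sort(unique(ds[is.finite(ds) & ds > 0]))
    for (lev in finite_levels) {
      for (v in which(ds == lev)) {
        prev <- which(a[, v] > 0 & ds == lev - 1)
        sigma[s, v] <- sum(sigma[s, prev])
      }
    }
  }
  structure(list(d = d, sigma = sigma), class = "shortest_path_data")
}

#' Global efficiency
#'
#' Mean of `1 / d_ij` over all ordered pairs of distinct nodes, with
#' disconnected pairs contributing zero.
#'
#' @param g A `binary_graph`.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  a <- check_binary(g)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- igraph::distances(as_igraph(g))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph (the subgraph induced by its direct neighbours). Nodes with fewer
#' than two neighbours contribute zero.
#'
#' @param g A `binary_graph`.
#' @return Efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  a <- check_binary(g)
  n <- nrow(a)
  per_node <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(binary_graph(a[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(per_node)
}

#' Modularity of a given partition
#'
#' `Q(p) = sum_s [ l_s / L - (d_s / 2L)^2 ]` where `L` is the total edge
#' count, `l_s` the number of edges inside module `s` and `d_s` the summed
#' degree of module `s`.
#'
#' @param g A `binary_graph`.
#' @param p Integer/character module assignment, one entry per node; no empty
#'   modules (every level must be used).
#' @return Modularity value.
#' @export
modularity_of_partition <- function(g, p) {
  a <- check_binary(g)
  n <- nrow(a)
  if (length(p) != n) stop("partition length must equal node count",
                           call. = FALSE)
  if (anyNA(p)) stop("partition contains empty (NA) assignments",
                     call. = FALSE)
  big_l <- sum(a) / 2
  if (big_l == 0) stop("edgeless graph: modularity undefined", call. = FALSE)
  k <- rowSums(a)
  q <- 0
  for (mod in unique(p)) {
    idx <- which(p == mod)
    l_s <- sum(a[idx, idx, drop = FALSE]) / 2
    d_s <- sum(k[idx])
    q <- q + l_s / big_l - (d_s / (2 * big_l))^2
  }
  q
}

# One Kernighan-Lin pass: greedily flip each node once, keep the best state.
kl_refine <- function(b, s) {
  repeat {
    best_s <- s
    best_val <- as.numeric(t(s) %*% b %*% s)
    start_val <- best_val
    moved <- rep(FALSE, length(s))
    cur <- s
    cur_val <- best_val
    for (step in seq_along(s)) {
      bs <- as.numeric(b %*% cur)
      gains <- -4 * cur * bs + 4 * diag(b)
      gains[moved] <- -Inf
      pick <- which.max(gains)
      cur[pick] <- -cur[pick]
      moved[pick] <- TRUE
      cur_val <- cur_val + gains[pick]
      if (cur_val > best_val + 1e-12) {
        best_val <- cur_val
        best_s <- cur
      }
    }
    if (best_val <= start_val + 1e-12) return(s)
    s <- best_s
  }
}

#' Detect modules by spectral modularity optimization
#'
#' Newman's leading-eigenvector method: recursively bisect node groups along
#' the sign of the leading eigenvector of the (generalized) modularity
#' matrix, refine each candidate bisection with Kernighan-Lin node moves, and
#' stop splitting a group when no bisection increases modularity. Eigenvector
#' sign ties (zero loadings) are assigned to the first module. The algorithm
#' is deterministic; `seed` is accepted for interface uniformity across the
#' package's stochastic operations.
#'
#' @param g A `binary_graph` with at least one edge.
#' @param seed Unused by the deterministic algorithm; kept for API symmetry.
#' @return A list of class `modularity_partition`: `membership` (integer
#'   module per node), `n_modules`, `q_max`, and per-module `l_s`, `d_s`.
#' @export
detect_modules <- function(g, seed = 1L) {
  a <- check_binary(g)
  n <- nrow(a)
  big_l <- sum(a) / 2
  if (big_l == 0) {
    stop("edgeless graph: every node is its own module and Q is undefined",
         call. = FALSE)
  }
  k <- rowSums(a)
  b <- a - outer(k, k) / (2 * big_l)

  membership <- rep(1L, n)
  next_id <- 2L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    idx <- queue[[1]]
    queue <- queue[-1]
    if (length(idx) < 2) next
    bg <- b[idx, idx, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)  # generalized modularity matrix
    ev <- eigen((bg + t(bg)) / 2, symmetric = TRUE)
    s <- ifelse(ev$vectors[, 1] >= 0, 1, -1)
    s <- kl_refine(bg, s)
    dq <- as.numeric(t(s) %*% bg %*% s) / (4 * big_l)
    if (dq <= 1e-10 || all(s == 1) || all(s == -1)) next
    half2 <- idx[s < 0]
    membership[half2] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(idx[s > 0]), list(half2))
  }
  membership <- as.integer(factor(membership, levels = unique(membership)))
  mods <- sort(unique(membership))
  l_s <- vapply(mods, function(mod) {
    idx <- membership == mod
    sum(a[idx, idx, drop = FALSE]) / 2
  }, numeric(1))
  d_s <- vapply(mods, function(mod) sum(k[membership == mod]), numeric(1))
  structure(list(
    membership = membership,
    n_modules = length(mods),
    q_max = modularity_of_partition(g, membership),
    l_s = l_s, d_s = d_s, L = big_l
  ), class = "modularity_partition")
}

#' Nodal degree, efficiency and betweenness
#'
#' Degree `k_i` is the number of incident edges; nodal efficiency `e_i` is
#' the mean inverse hop distance from node `i` to every other node
#' (disconnected pairs contribute zero); betweenness `b_i` is the summed
#' fraction of geodesics between unordered pairs of other nodes that pass
#' through `i`.
#'
#' @param g A `binary_graph` with `N >= 3`.
#' @return A tibble with columns `node`, `label` (when the adjacency has
#'   dimnames), `degree`, `efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(g) {
  a <- check_binary(g)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes for betweenness", call. = FALSE)
  sp <- shortest_paths_data(g)
  inv <- 1 / sp$d
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  btw <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    tot <- 0
    for (m in others) {
      for (v in others) {
        if (v <= m) next
        if (!is.finite(sp$d[m, v]) || sp$sigma[m, v] == 0) next
        on_path <- is.finite(sp$d[m, i]) && is.finite(sp$d[i, v]) &&
          sp$d[m, i] + sp$d[i, v] == sp$d[m, v]
        if (on_path) {
          tot <- tot + sp$sigma[m, i] * sp$sigma[i, v] / sp$sigma[m, v]
        }
      }
    }
    tot
  }, numeric(1))
  out <- tibble::tibble(node = seq_len(n), degree = rowSums(a),
                        efficiency = eff, betweenness = btw)
  if (!is.null(rownames(a))) {
    out <- tibble::add_column(out, label = rownames(a), .after = "node")
  }
  out
}

#' Degree-preserving rewired null graphs
#'
#' Generates random graphs with exactly the input's degree sequence by
#' double-edge swaps (`10 * edge count` attempted swaps per null).
#'
#' @param g A `binary_graph` with at least 2 edges.
#' @param n_nulls Number of null graphs (default 100).
#' @param seed Integer seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return List of `binary_graph` objects.
#' @export
rewire_null <- function(g, n_nulls = 100, seed = 1L, swaps_per_edge = 10) {
  a <- check_binary(g)
  gi <- as_igraph(g)
  n_edges <- igraph::ecount(gi)
  if (n_edges < 2) {
    warning("graph too constrained to rewire; returning copies")
    return(replicate(n_nulls, binary_graph(a), simplify = FALSE))
  }
  set.seed(seed)
  lapply(seq_len(n_nulls), function(dummy) {
    ri <- igraph::rewire(gi, igraph::keeping_degseq(
      niter = swaps_per_edge * n_edges))
    null_a <- as.matrix(igraph::as_adjacency_matrix(ri, sparse = FALSE))
    dimnames(null_a) <- dimnames(a)
    binary_graph(null_a)
  })
}

#' Global topological measures of one graph
#'
#' @param g A `binary_graph`.
#' @return One-row tibble: `density`, `e_glob`, `e_loc`, `q_max`, `n_modules`.
#' @export
global_metrics <- function(g) {
  a <- check_binary(g)
  n <- nrow(a)
  part <- detect_modules(g)
  tibble::tibble(
    density = sum(a) / (n * (n - 1)),
    e_glob = global_efficiency(g),
    e_loc = local_efficiency(g),
    q_max = part$q_max,
    n_modules = part$n_modules
  )
}

#' Normalize observed global measures against null graphs
#'
#' Divides each observed measure by the mean of the same measure over the
#' null ensemble. A small-world graph shows `normalized_e_loc > 1` with
#' `normalized_e_glob` near 1; a modular one shows `normalized_q > 1`.
#'
#' @param real One-row tibble from [global_metrics()] (or any list with
#'   `e_glob`, `e_loc`, `q_max`).
#' @param nulls List of one-row tibbles from [global_metrics()] on null
#'   graphs.
#' @return The `real` row with `normalized_e_glob`, `normalized_e_loc`,
#'   `normalized_q` appended.
#' @export
normalize_globals <- function(real, nulls) {
  if (length(nulls) < 1) stop("need at least one null", call. = FALSE)
  null_mean <- function(field) {
    mean(vapply(nulls, function(x) as.numeric(x[[field]]), numeric(1)))
  }
  out <- tibble::as_tibble(real[c("density", "e_glob", "e_loc", "q_max",
                                  "n_modules")])
  for (field in c("e_glob", "e_loc", "q_max")) {
    mu <- null_mean(field)
    if (mu == 0) stop("null mean of ", field, " is zero", call. = FALSE)
    out[[paste0("normalized_", sub("q_max", "q", field))]] <-
      as.numeric(real[[field]]) / mu
  }
  out
}

#' Observed and null-normalized global measures in one call
#'
#' @param g A `binary_graph`.
#' @param n_nulls Number of degree-preserving rewired nulls (default 100).
#' @param seed Integer seed for the rewiring.
#' @return One-row tibble from [normalize_globals()].
#' @export
normalized_global_metrics <- function(g, n_nulls = 100, seed = 1L) {
  real <- global_metrics(g)
  nulls <- lapply(rewire_null(g, n_nulls = n_nulls, seed = seed),
                  global_metrics)
  normalize_globals(real, nulls)
}
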