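dist_lookup <- function(dist_tab) {
  n <- max(dist_tab$i, dist_tab$j)
  d <- matrix(NA_real_, n, n)
  d[cbind(dist_tab$i, dist_tab$j)] <- dist_tab$distance
  d[cbind(dist_tab$j, dist_tab$i)] <- dist_tab$distance
  d
}

component_edge_matrix <- function(component) {
  if (is.list(component) && !is.data.frame(component) &&
      !is.null(component[["edges"]])) {
    component <- component$edges
  }
  comp <- as.data.frame(component)
  if (nrow(comp) == 0) stop("empty component", call. = FALSE)
  comp
}

#' Anatomical-distance profile of a component
#'
#' Per-edge distances plus the counts and proportions of long-range
#' (> 75 mm) and inter-network connections in a component. When the
#' component table carries its own `distance` / `inter_network` columns
#' (e.g. a published edge list with printed values) those are used;
#' otherwise both are looked up from an [pairwise_distances()] table.
#'
#' @param component Component (from [nbs_test()]) or tibble of edges with
#'   columns `i`, `j` and optionally `distance`, `inter_network`.
#' @param dist A [pairwise_distances()] table; required for any quantity not
#'   carried by the component itself.
#' @param cutoff Long-range cutoff in millimetres (default 75).
#' @return A list of class `component_distance_summary` with `edges` (per
#'   edge: `i`, `j`, `distance`, `long_range`, `inter_network`) and `summary`
#'   (one-row tibble: `n_edges`, `n_nodes`, `mean_distance`, `n_long_range`,
#'   `prop_long_range`, `n_inter_network`, `prop_inter_network`).
#' @export
component_distance_summary <- function(component, dist = NULL, cutoff = 75) {
  comp <- component_edge_matrix(component)
  need_lookup <- !("distance" %in% names(comp)) ||
    !("inter_network" %in% names(comp))
  d <- NULL
  if (need_lookup) {
    if (is.null(dist)) {
      stop("component lacks distance/inter_network columns and no distance ",
           "table was supplied", call. = FALSE)
    }
    d <- dist_lookup(dist)
    if (any(comp$i < 1 | comp$j < 1 | comp$i > nrow(d) | comp$j > nrow(d))) {
      stop("component edge outside the atlas", call. = FALSE)
    }
  }
  edge_dist <- if ("distance" %in% names(comp)) comp$distance else
    d[cbind(comp$i, comp$j)]
  inter <- if ("inter_network" %in% names(comp)) comp$inter_network else {
    inter_mat <- matrix(NA, nrow(d), nrow(d))
    inter_mat[cbind(dist$i, dist$j)] <- dist$inter_network
    inter_mat[cbind(dist$j, dist$i)] <- dist$inter_network
    inter_mat[cbind(comp$i, comp$j)]
  }
  lr <- is_long_range(edge_dist, cutoff = cutoff)
  edges <- tibble::tibble(i = comp$i, j = comp$j, distance = edge_dist,
                          long_range = lr, inter_network = inter)
  summary <- tibble::tibble(
    n_edges = nrow(edges),
    n_nodes = length(unique(c(comp$i, comp$j))),
    mean_distance = mean(edge_dist),
    n_long_range = sum(lr),
    prop_long_range = mean(lr),
    n_inter_network = sum(inter),
    prop_inter_network = mean(inter)
  )
  structure(list(edges = edges, summary = summary),
            class = "component_distance_summary")
}

#' @export
print.component_distance_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Component of %d edges / %d nodes: mean distance %.1f mm, %d/%d (%.1f%%) long-range, %d/%d (%.0f%%) inter-network\n",
    s$n_edges, s$n_nodes, s$mean_distance,
    s$n_long_range, s$n_edges, 100 * s$prop_long_range,
    s$n_inter_network, s$n_edges, 100 * s$prop_inter_network))
  invisible(x)
}

#' Two-sample t-test of component vs remaining edge distances
#'
#' Compares the anatomical distances of a component's edges against the
#' distances of every other region pair in the network (pooled-variance
#' two-sample t-test, two-tailed).
#'
#' @param component Component or edge tibble with `i`, `j`.
#' @param dist A [pairwise_distances()] table defining the full edge
#'   universe.
#' @return One-row tibble: `t`, `df`, `p`, `mean_component`, `mean_rest`,
#'   `n_component`, `n_rest`.
#' @export
distance_ttest <- function(component, dist) {
  comp <- component_edge_matrix(component)
  key <- paste(pmin(comp$i, comp$j), pmax(comp$i, comp$j))
  all_key <- paste(dist$i, dist$j)
  if (!all(key %in% all_key)) {
    stop("component edge outside the distance table", call. = FALSE)
  }
  in_comp <- all_key %in% key
  x <- dist$distance[in_comp]
  y <- dist$distance[!in_comp]
  if (length(x) < 2 || length(y) < 2) {
    stop("component and complement must each contain at least 2 edges",
         call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate distance variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_component = mean(x),
                 mean_rest = mean(y), n_component = length(x),
                 n_rest = length(y))
}

#' Sample a connected edge set with fixed edge and node counts
#'
#' Draws a random connected set of `m_edges` edges spanning exactly
#' `n_nodes` nodes from the complete graph on `n_universe` nodes. A
#' uniformly chosen starting edge is grown by repeatedly adding a uniformly
#' random unused edge incident to the current node set; the draw is accepted
#' only if the final node count equals `n_nodes`, otherwise it is rejected
#' and restarted. An exhaustive mode enumerates all qualifying edge sets and
#' samples one uniformly (tiny universes only) to audit the growth sampler's
#' bias.
#'
#' @param n_universe Number of nodes in the complete universe graph.
#' @param m_edges Number of edges to draw.
#' @param n_nodes Number of nodes the edge set must span.
#' @param seed Optional integer seed.
#' @param max_reject Rejection budget before giving up (default 1e6).
#' @param method `"growth"` (default) or `"exhaustive"`.
#' @return Two-column matrix of node pairs (`i < j`) with attribute
#'   `n_rejected`.
#' @export
sample_connected_edge_set <- function(n_universe, m_edges, n_nodes,
                                      seed = NULL, max_reject = 1e6,
                                      method = c("growth", "exhaustive")) {
  method <- match.arg(method)
  if (n_nodes < 2 || n_nodes > n_universe ||
      m_edges < n_nodes - 1 || m_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible (m_edges, n_nodes) for a connected subgraph of a ",
         n_universe, "-node universe", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pairs <- ut_pairs(n_universe)
  n_pairs <- nrow(pairs)

  if (method == "exhaustive") {
    if (choose(n_pairs, m_edges) > 2e6) {
      stop("exhaustive mode infeasible for this universe size", call. = FALSE)
    }
    sets <- utils::combn(n_pairs, m_edges, simplify = FALSE)
    ok <- vapply(sets, function(eidx) {
      sub <- pairs[eidx, , drop = FALSE]
      nodes <- unique(as.vector(sub))
      if (length(nodes) != n_nodes) return(FALSE)
      gi <- igraph::graph_from_edgelist(
        matrix(match(sub, nodes), ncol = 2), directed = FALSE)
      igraph::count_components(gi) == 1
    }, logical(1))
    sets <- sets[ok]
    if (length(sets) == 0) stop("no qualifying edge set exists",
                                call. = FALSE)
    out <- pairs[sets[[sample.int(length(sets), 1)]], , drop = FALSE]
    attr(out, "n_rejected") <- 0L
    return(out)
  }

  pi_ <- pairs[, 1]
  pj <- pairs[, 2]
  rejected <- 0L
  repeat {
    chosen <- logical(n_pairs)
    in_set <- logical(n_universe)
    first <- sample.int(n_pairs, 1)
    chosen[first] <- TRUE
    in_set[pairs[first, ]] <- TRUE
    for (step in seq_len(m_edges - 1)) {
      cand <- which(!chosen & (in_set[pi_] | in_set[pj]))
      pick <- cand[sample.int(length(cand), 1)]
      chosen[pick] <- TRUE
      in_set[pairs[pick, ]] <- TRUE
    }
    if (sum(in_set) == n_nodes) {
      out <- pairs[chosen, , drop = FALSE]
      attr(out, "n_rejected") <- rejected
      return(out)
    }
    rejected <- rejected + 1L
    if (rejected > max_reject) {
      stop("rejection limit exceeded while sampling a connected edge set",
           call. = FALSE)
    }
  }
}

#' Resampling null for a component's mean anatomical distance
#'
#' Tests whether a component's mean inter-regional distance is unusually
#' large given its topology: `n_iter` random connected edge sets with the
#' same edge and node counts are drawn from the full region-pair universe
#' and the empirical p value is the proportion of null sets whose mean
#' distance is strictly larger than the observed mean.
#'
#' @param component Component or edge tibble (`i`, `j`, optional printed
#'   `distance` used for the observed mean).
#' @param dist A [pairwise_distances()] table (defines the universe and the
#'   null sets' distances).
#' @param n_iter Number of null draws (default 10,000).
#' @param seed Integer seed.
#' @return A list of class `distance_null_result`: `observed_mean`,
#'   `null_means`, `empirical_p`, `n_rejected`, `m_edges`, `n_nodes`.
#' @export
distance_resampling_test <- function(component, dist, n_iter = 10000,
                                     seed = 1L) {
  if (n_iter < 1) stop("n_iter must be positive", call. = FALSE)
  comp <- component_edge_matrix(component)
  obs <- component_distance_summary(component, dist)$summary
  d <- dist_lookup(dist)
  n_universe <- nrow(d)
  set.seed(seed)
  rejected <- 0L
  null_means <- vapply(seq_len(n_iter), function(it) {
    es <- sample_connected_edge_set(n_universe, obs$n_edges, obs$n_nodes)
    rejected <<- rejected + attr(es, "n_rejected")
    mean(d[es])
  }, numeric(1))
  structure(list(
    observed_mean = obs$mean_distance,
    null_means = null_means,
    empirical_p = mean(null_means > obs$mean_distance),
    n_rejected = rejected,
    m_edges = obs$n_edges, n_nodes = obs$n_nodes
  ), class = "distance_null_result")
}

#' @export
print.distance_null_result <- function(x, ...) {
  cat(sprintf(
    "Distance resampling null (%d edges / %d nodes, %d draws): observed mean %.1f mm, empirical p = %.4g\n",
    x$m_edges, x$n_nodes, length(x$null_means), x$observed_mean,
    x$empirical_p))
  invisible(x)
}
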