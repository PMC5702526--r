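ut_pairs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# subjects x edges weight table from a list of connectivity matrices
edge_weight_table <- function(mats) {
  if (length(mats) < 1) stop("empty cohort", call. = FALSE)
  n <- nrow(mats[[1]])
  pairs <- ut_pairs(n)
  w <- t(vapply(mats, function(m) unclass(m)[pairs], numeric(nrow(pairs))))
  list(weights = w, pairs = pairs, n_nodes = n)
}

#' NBS configuration
#'
#' @param primary_p Edge-level primary threshold on the t-test p-value
#'   (default 0.05).
#' @param n_perm Number of group-label permutations (default 10,000).
#' @param prevalence Minimum fraction of subjects (both groups pooled) in
#'   which an edge must be positive to enter the analysis (default 0.5).
#' @param tail Direction of the component search: `"controls_greater"`
#'   (default; hypoconnectivity in patients), `"patients_greater"`, or
#'   `"two_sided"` (both directions pooled into one supra-threshold graph).
#' @param edge_p For directional tails, how the edge-level primary threshold
#'   is interpreted: `"two_sided"` (default) declares an edge
#'   supra-threshold when its two-tailed two-sample p value is below
#'   `primary_p` *and* its sign matches the tested direction — the
#'   one-contrast-at-a-time convention of component-based inference;
#'   `"one_sided"` uses the one-tailed p value directly. Ignored when
#'   `tail = "two_sided"`.
#' @param seed Integer seed for the permutations.
#' @return A list of class `nbs_config`.
#' @export
nbs_config <- function(primary_p = 0.05, n_perm = 10000, prevalence = 0.5,
                       tail = c("controls_greater", "patients_greater",
                                "two_sided"),
                       edge_p = c("two_sided", "one_sided"),
                       seed = 1L) {
  if (primary_p <= 0 || primary_p >= 1) {
    stop("primary_p must be in (0, 1)", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  structure(list(primary_p = primary_p, n_perm = as.integer(n_perm),
                 prevalence = prevalence, tail = match.arg(tail),
                 edge_p = match.arg(edge_p), seed = as.integer(seed)),
            class = "nbs_config")
}

#' Prevalence-based edge inclusion mask
#'
#' An edge enters the NBS analysis only if its (rectified) weight is strictly
#' positive in at least `prevalence` of all subjects, both groups pooled.
#'
#' @param mats List of rectified `connectivity_matrix` objects.
#' @param prevalence Required fraction (default 0.5).
#' @return Logical vector over the `N(N-1)/2` unordered node pairs (row-major
#'   upper triangle, `i < j`), with the pair index matrix as attribute
#'   `pairs`.
#' @export
edge_inclusion_mask <- function(mats, prevalence = 0.5) {
  et <- edge_weight_table(mats)
  frac_pos <- colMeans(et$weights > 0)
  structure(frac_pos >= prevalence, pairs = et$pairs)
}

#' Residualize edge weights on nuisance covariates
#'
#' Ordinary least-squares residuals of every edge's weight across subjects
#' after regressing out the covariates (plus intercept), pooled over both
#' groups. Used to control age, gender, IQ and head motion before
#' permutation inference.
#'
#' @param weights Subjects x edges numeric matrix.
#' @param covariates Data frame of numeric covariates (one row per subject),
#'   or `NULL` for intercept-only (centering).
#' @return Residual matrix of the same shape.
#' @export
residualize_edges <- function(weights, covariates = NULL) {
  weights <- as.matrix(weights)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(scale(weights, center = TRUE, scale = FALSE))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(weights)) {
    stop("covariates and weights disagree on subject count", call. = FALSE)
  }
  x <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr.resid(qx, weights)
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance two-sample t per edge, signed as
#' `mean(positive group) - mean(other group)` (default positive group:
#' controls, so positive t means hypoconnectivity in patients). Edges with
#' zero pooled variance get t = 0 with a warning.
#'
#' @param weights Subjects x edges matrix (typically residualized).
#' @param groups Character vector of group labels per subject.
#' @param positive Label of the group whose mean enters with positive sign
#'   (default `"control"`).
#' @return A list with `t` (per-edge statistic) and `df`.
#' @export
edgewise_tstats <- function(weights, groups, positive = "control") {
  weights <- as.matrix(weights)
  g1 <- groups == positive
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group",
                             call. = FALSE)
  m1 <- colMeans(weights[g1, , drop = FALSE])
  m2 <- colMeans(weights[!g1, , drop = FALSE])
  ss1 <- colSums(weights[g1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(weights[!g1, , drop = FALSE]^2) - n2 * m2^2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  if (any(se == 0)) {
    warning("zero pooled variance for ", sum(se == 0),
            " edge(s); t set to 0")
    t_stat[se == 0] <- 0
  }
  list(t = t_stat, df = df)
}

# p value an edge is screened on: for directional tails with two-sided edge
# p, a wrong-sign edge can never be supra-threshold (p = 1)
edge_pvals <- function(t_stat, df, tail, edge_p = "two_sided") {
  switch(tail,
         controls_greater = {
           p1 <- stats::pt(t_stat, df, lower.tail = FALSE)
           if (edge_p == "two_sided") ifelse(t_stat > 0, 2 * p1, 1) else p1
         },
         patients_greater = {
           p1 <- stats::pt(t_stat, df, lower.tail = TRUE)
           if (edge_p == "two_sided") ifelse(t_stat < 0, 2 * p1, 1) else p1
         },
         two_sided = 2 * stats::pt(-abs(t_stat), df))
}

# max component size in edges via union-find; used in the permutation loop
# where only the maximum matters
max_component_edges <- function(ei, ej, n_nodes) {
  parent <- seq_len(n_nodes)
  ecount <- integer(n_nodes)
  best <- 0L
  for (k in seq_along(ei)) {
    x <- ei[k]
    while (parent[x] != x) {
      parent[x] <- parent[parent[x]]
      x <- parent[x]
    }
    y <- ej[k]
    while (parent[y] != y) {
      parent[y] <- parent[parent[y]]
      y <- parent[y]
    }
    if (x == y) {
      ecount[x] <- ecount[x] + 1L
    } else {
      parent[y] <- x
      ecount[x] <- ecount[x] + ecount[y] + 1L
    }
    if (ecount[x] > best) best <- ecount[x]
  }
  best
}

# connected components of an edge subset; returns list of edge-index vectors
edge_components <- function(pairs, sel, n_nodes) {
  if (!any(sel)) return(list())
  sub <- pairs[sel, , drop = FALSE]
  gi <- igraph::graph_from_edgelist(sub, directed = FALSE)
  gi <- igraph::add_vertices(gi, max(0, n_nodes - igraph::vcount(gi)))
  memb <- igraph::components(gi)$membership
  comp_of_edge <- memb[sub[, 1]]
  sel_idx <- which(sel)
  split(sel_idx, comp_of_edge)
}

#' Connected components of supra-threshold edges
#'
#' Applies the primary threshold to an edge-wise t matrix and identifies the
#' connected components formed by the surviving edges. Components are sorted
#' by edge count, largest first (ties: smallest participating node index
#' first).
#'
#' @param t_stat Per-edge t statistics (vector over unordered pairs) or an
#'   N x N symmetric t matrix.
#' @param df Degrees of freedom of the edge tests.
#' @param primary_p Edge-level p threshold.
#' @param tail,edge_p See [nbs_config()].
#' @param pairs Pair index matrix (required when `t_stat` is a vector);
#'   ignored for matrix input.
#' @param n_nodes Number of nodes (inferred from matrix input).
#' @return List of components, each a list with `edges` (tibble `i`, `j`,
#'   `t`), `n_edges`, `n_nodes`, `nodes`.
#' @export
supra_components <- function(t_stat, df, primary_p = 0.05,
                             tail = "controls_greater",
                             edge_p = "two_sided", pairs = NULL,
                             n_nodes = NULL) {
  if (is.matrix(t_stat)) {
    n_nodes <- nrow(t_stat)
    pairs <- ut_pairs(n_nodes)
    t_stat <- t_stat[pairs]
  }
  if (is.null(pairs) || is.null(n_nodes)) {
    stop("pairs and n_nodes are required for vector input", call. = FALSE)
  }
  p <- edge_pvals(t_stat, df, tail, edge_p)
  sel <- !is.na(p) & p < primary_p
  comps <- edge_components(pairs, sel, n_nodes)
  comps <- lapply(comps, function(eidx) {
    nodes <- sort(unique(as.vector(pairs[eidx, , drop = FALSE])))
    list(edges = tibble::tibble(i = pairs[eidx, 1], j = pairs[eidx, 2],
                                t = t_stat[eidx]),
         n_edges = length(eidx), n_nodes = length(nodes), nodes = nodes)
  })
  ord <- order(-vapply(comps, `[[`, numeric(1), "n_edges"),
               vapply(comps, function(x) min(x$nodes), numeric(1)))
  comps[ord]
}

#' Network-based statistic (NBS) group comparison
#'
#' Edge-wise covariate-controlled two-sample comparison with family-wise
#' error control at the level of connected components. Edge weights are
#' residualized on the covariates (pooled across groups), an edge-wise t
#' matrix is computed over the prevalence-masked edges, supra-threshold
#' components are extracted, and each observed component of size `M` edges is
#' assigned a corrected p value: the fraction of group-label permutations
#' whose maximal supra-threshold component is larger than `M`.
#'
#' @param mats List of rectified `connectivity_matrix` objects, one per
#'   subject.
#' @param groups Character vector (`"patient"` / `"control"`) per subject.
#' @param covariates Data frame of nuisance covariates per subject, or
#'   `NULL`.
#' @param config An [nbs_config()].
#' @param atlas Optional `ctrlnet_atlas` used to label edges in tidied
#'   output.
#' @return A list of class `nbs_result`: `t_matrix` (N x N, `NA` off-mask),
#'   `mask`, `pairs`, `components` (each with `corrected_p` attached),
#'   `null_max_sizes`, `df`, `config`, `n_exhaustive` (if label permutations
#'   were enumerated exhaustively).
#' @export
nbs_test <- function(mats, groups, covariates = NULL, config = nbs_config(),
                     atlas = NULL) {
  stopifnot(inherits(config, "nbs_config"))
  et <- edge_weight_table(mats)
  if (length(groups) != nrow(et$weights)) {
    stop("groups length must match subject count", call. = FALSE)
  }
  labs <- unique(groups)
  if (length(labs) != 2) stop("need exactly two groups", call. = FALSE)
  positive <- if ("control" %in% labs) "control" else labs[1]
  n_sub <- length(groups)
  n1 <- sum(groups == positive)
  if (n1 < 2 || n_sub - n1 < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }

  mask <- edge_inclusion_mask(mats, config$prevalence)
  if (!any(mask)) stop("prevalence mask excludes every edge", call. = FALSE)
  w <- et$weights[, mask, drop = FALSE]
  pairs <- et$pairs[mask, , drop = FALSE]
  res <- residualize_edges(w, covariates)

  obs <- edgewise_tstats(res, groups, positive = positive)
  comps <- supra_components(obs$t, obs$df, config$primary_p, config$tail,
                            config$edge_p, pairs = pairs,
                            n_nodes = et$n_nodes)

  # permutation null of the maximal component size (in edges)
  set.seed(config$seed)
  n_perm <- config$n_perm
  n_exhaustive <- NULL
  total_arrangements <- choose(n_sub, n1)
  if (total_arrangements <= n_perm) {
    warning("n_perm (", n_perm, ") exceeds the ", total_arrangements,
            " distinct label arrangements; enumerating exhaustively")
    idx_sets <- utils::combn(n_sub, n1, simplify = FALSE)
    n_exhaustive <- length(idx_sets)
  } else {
    idx_sets <- replicate(n_perm, sample.int(n_sub, n1), simplify = FALSE)
  }

  alpha_side <- if (config$tail == "two_sided" ||
                    config$edge_p == "two_sided") {
    config$primary_p / 2
  } else {
    config$primary_p
  }
  t_crit <- stats::qt(1 - alpha_side, obs$df)
  res_sq <- res^2
  tot_sum <- colSums(res)
  tot_sq <- colSums(res_sq)
  n2 <- n_sub - n1
  n_sets <- length(idx_sets)
  null_max <- integer(n_sets)
  # block the permutations: group sums for a whole block come from one
  # indicator-matrix product, leaving only thresholding + component search
  # per permutation
  block_size <- 500L
  for (start in seq(1L, n_sets, by = block_size)) {
    idx_block <- idx_sets[start:min(start + block_size - 1L, n_sets)]
    ind <- matrix(0, length(idx_block), n_sub)
    for (b in seq_along(idx_block)) ind[b, idx_block[[b]]] <- 1
    s1 <- ind %*% res
    q1 <- ind %*% res_sq
    m1 <- s1 / n1
    m2 <- sweep(-s1, 2, tot_sum, "+") / n2
    ss1 <- s1^2 / n1
    ss2 <- sweep(-q1, 2, tot_sq, "+") - m2^2 * n2
    se <- sqrt((q1 - ss1 + ss2) / obs$df * (1 / n1 + 1 / n2))
    t_perm <- (m1 - m2) / se
    t_perm[!is.finite(t_perm)] <- 0
    sel_block <- switch(config$tail,
                        controls_greater = t_perm > t_crit,
                        patients_greater = -t_perm > t_crit,
                        two_sided = abs(t_perm) > t_crit)
    for (b in seq_along(idx_block)) {
      sel <- sel_block[b, ]
      null_max[start + b - 1L] <- if (!any(sel)) 0L else {
        max_component_edges(pairs[sel, 1], pairs[sel, 2], et$n_nodes)
      }
    }
  }

  for (k in seq_along(comps)) {
    comps[[k]]$corrected_p <- mean(null_max > comps[[k]]$n_edges)
  }

  t_matrix <- matrix(NA_real_, et$n_nodes, et$n_nodes)
  t_matrix[pairs] <- obs$t
  t_matrix[pairs[, c(2, 1), drop = FALSE]] <- obs$t
  if (!is.null(atlas)) dimnames(t_matrix) <- list(atlas$label, atlas$label)

  structure(list(
    t_matrix = t_matrix, mask = mask, pairs = pairs, components = comps,
    null_max_sizes = null_max, df = obs$df, config = config,
    atlas = atlas, positive_group = positive, n_exhaustive = n_exhaustive
  ), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS result (", x$config$tail, ", primary p < ", x$config$primary_p,
      ", ", length(x$null_max_sizes), " permutations)\n", sep = "")
  if (length(x$components) == 0) {
    cat("  no supra-threshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      comp <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, %d nodes, corrected p = %.4g\n",
                  k, comp$n_edges, comp$n_nodes, comp$corrected_p))
    }
  }
  invisible(x)
}

#' Mean connectivity strength over a component's edges
#'
#' The subject-level feature used for brain-clinical correlation and ROC
#' classification: the arithmetic mean of a subject's connectivity weights
#' over the edges of an NBS component.
#'
#' @param m A `connectivity_matrix`.
#' @param component A component from an `nbs_result`, or any tibble/matrix
#'   with node-pair columns `i`, `j`.
#' @return Scalar mean weight.
#' @export
component_mean_strength <- function(m, component) {
  if (is.list(component) && !is.data.frame(component) &&
      !is.null(component[["edges"]])) {
    component <- component[["edges"]]
  }
  comp <- as.data.frame(component)
  if (nrow(comp) == 0) stop("empty component", call. = FALSE)
  idx <- if (all(c("i", "j") %in% names(comp))) {
    cbind(comp$i, comp$j)
  } else {
    as.matrix(comp[, 1:2])
  }
  if (any(idx < 1 | idx > nrow(m))) {
    stop("component edge outside the atlas", call. = FALSE)
  }
  mean(unclass(m)[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
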