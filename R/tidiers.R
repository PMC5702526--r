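#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NBS result into one row per supra-threshold edge
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return Tibble with `component`, `i`, `j`, (`node_i`, `node_j` when an
#'   atlas was attached), `t`, `p_edge`, `corrected_p`.
#' @export
tidy.nbs_result <- function(x, ...) {
  if (length(x$components) == 0) {
    return(tibble::tibble(component = integer(), i = integer(),
                          j = integer(), t = numeric(),
                          p_edge = numeric(), corrected_p = numeric()))
  }
  rows <- purrr::imap(x$components, function(comp, k) {
    out <- comp$edges
    out$component <- k
    out$p_edge <- edge_pvals(out$t, x$df, x$config$tail, x$config$edge_p)
    out$corrected_p <- comp$corrected_p
    out
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(x$atlas)) {
    out$node_i <- x$atlas$label[out$i]
    out$node_j <- x$atlas$label[out$j]
  }
  dplyr::relocate(out, "component")
}

#' One-row summary of an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return One-row tibble: component count, size and corrected p of the
#'   largest component, permutation count, masked edge count.
#' @export
glance.nbs_result <- function(x, ...) {
  lead <- if (length(x$components) > 0) x$components[[1]] else NULL
  tibble::tibble(
    n_components = length(x$components),
    n_edges = if (is.null(lead)) 0L else lead$n_edges,
    n_nodes = if (is.null(lead)) 0L else lead$n_nodes,
    corrected_p = if (is.null(lead)) NA_real_ else lead$corrected_p,
    n_perm = length(x$null_max_sizes),
    n_masked_edges = sum(x$mask)
  )
}

#' @export
tidy.modularity_partition <- function(x, ...) {
  tibble::tibble(node = seq_along(x$membership), module = x$membership)
}

#' @export
glance.modularity_partition <- function(x, ...) {
  tibble::tibble(q_max = x$q_max, n_modules = x$n_modules, n_edges = x$L)
}

#' @export
glance.perm_test_result <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff, p = x$p,
                 critical_value = x$critical_value, tail = x$tail,
                 exhaustive = x$exhaustive)
}

#' @export
tidy.perm_test_result <- function(x, ...) {
  tibble::tibble(null_diff = x$null_diffs)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_auc = x$p_auc, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_correct_patients = x$n_correct_patients,
                 n_correct_controls = x$n_correct_controls)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.distance_null_result <- function(x, ...) {
  tibble::tibble(observed_mean = x$observed_mean,
                 empirical_p = x$empirical_p,
                 n_iter = length(x$null_means),
                 n_rejected = x$n_rejected)
}

#' @export
tidy.distance_null_result <- function(x, ...) {
  tibble::tibble(null_mean = x$null_means)
}

#' @export
glance.threshold_selection <- function(x, ...) {
  tibble::tibble(max_correlation_threshold = x$max_correlation_threshold,
                 min_sparsity_threshold = x$min_sparsity_threshold,
                 degree_floor = x$degree_floor)
}

#' @export
tidy.threshold_selection <- function(x, ...) x$diagnostics
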