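#' Pearson correlation connectivity matrix
#'
#' Computes the N x N matrix of pairwise Pearson correlations between the
#' columns of a regional time-series matrix and zeroes the diagonal (a
#' region's self-correlation carries no connectivity information).
#'
#' @param ts T x N numeric matrix, one column per region; `T >= 3` and no
#'   constant columns.
#' @param subject_id Optional label stored with the matrix.
#' @return An N x N symmetric matrix of class `connectivity_matrix` with zero
#'   diagonal and attribute `rectified = FALSE`.
#' @export
correlation_matrix <- function(ts, subject_id = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series for region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(ts)
  diag(m) <- 0
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = subject_id, rectified = FALSE)
}

#' Zero out negative correlations
#'
#' Negative resting-state correlations are excluded from all analyses (set to
#' zero); positive entries are untouched.
#'
#' @param m A symmetric `connectivity_matrix` (or plain matrix).
#' @return The matrix with all entries non-negative and `rectified = TRUE`.
#' @export
rectify_negative <- function(m) {
  if (!isSymmetric(unclass(m), tol = 1e-8)) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  out <- pmax(unclass(m), 0)
  structure(out, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = attr(m, "subject_id"), rectified = TRUE)
}

#' Correlation matrices for a whole cohort
#'
#' Convenience wrapper: computes the rectified correlation matrix of every
#' subject's time series.
#'
#' @param cohort A `ctrlnet_cohort` tibble (see [generate_cohort()]).
#' @param rectify Zero out negative correlations (default `TRUE`).
#' @return Named list of `connectivity_matrix` objects, one per subject.
#' @export
cohort_connectivity <- function(cohort, rectify = TRUE) {
  stopifnot(inherits(cohort, "ctrlnet_cohort"))
  mats <- purrr::map2(cohort$timeseries, cohort$subject_id,
                      function(ts, id) correlation_matrix(ts, id))
  if (rectify) mats <- purrr::map(mats, rectify_negative)
  stats::setNames(mats, cohort$subject_id)
}

new_binary_graph <- function(a, threshold_kind, threshold_value) {
  n <- nrow(a)
  structure(a, class = c("binary_graph", "matrix", "array"),
            threshold_kind = threshold_kind,
            threshold_value = threshold_value,
            density = sum(a[upper.tri(a)]) / (n * (n - 1) / 2))
}

#' Threshold a connectivity matrix at a fixed correlation value
#'
#' Keeps an edge wherever the (rectified) weight is strictly greater than
#' `r0`. Different subjects generally end up with different numbers of edges,
#' so this probes the absolute network organization.
#'
#' @param m A rectified `connectivity_matrix`.
#' @param r0 Correlation threshold, `r0 >= 0`.
#' @return A `binary_graph`: 0/1 adjacency matrix with attributes
#'   `threshold_kind`, `threshold_value`, `density`.
#' @export
threshold_correlation <- function(m, r0) {
  if (r0 < 0) stop("correlation threshold must be non-negative", call. = FALSE)
  check_rectified(m)
  a <- (unclass(m) > r0) * 1L
  diag(a) <- 0L
  new_binary_graph(a, "correlation", r0)
}

check_rectified <- function(m) {
  if (any(unclass(m) < 0)) {
    stop("matrix has negative entries; apply rectify_negative() first",
         call. = FALSE)
  }
  invisible(m)
}

#' Threshold a connectivity matrix to a fixed sparsity
#'
#' Retains exactly `round(s * N(N-1)/2)` strongest edges, so every subject's
#' graph has the same density (wiring cost), probing the relative network
#' organization. Ties at the cutoff weight are broken deterministically in
#' favour of the lexicographically smaller node pair.
#'
#' @param m A rectified `connectivity_matrix`.
#' @param s Sparsity (density) in (0, 1].
#' @return A `binary_graph`.
#' @export
threshold_sparsity <- function(m, s) {
  if (s <= 0 || s > 1) stop("sparsity must be in (0, 1]", call. = FALSE)
  check_rectified(m)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- unclass(m)[ut]
  k <- round(s * n * (n - 1) / 2)
  if (k > sum(w > 0)) {
    stop("requested ", k, " edges but only ", sum(w > 0),
         " positive weights available",
         if (!is.null(attr(m, "subject_id")))
           paste0(" (subject ", attr(m, "subject_id"), ")"),
         call. = FALSE)
  }
  # order by weight desc, then lexicographic (i, j) for reproducible ties
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  a <- matrix(0L, n, n, dimnames = dimnames(m))
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  new_binary_graph(a, "sparsity", s)
}

mean_degree <- function(a) mean(rowSums(a))
has_isolated <- function(a) any(rowSums(a) == 0)

#' Automatic threshold selection for a cohort
#'
#' Searches a 0.01 grid for (a) the largest fixed correlation threshold and
#' (b) the smallest sparsity such that, for every subject, the thresholded
#' graph has mean degree larger than `2 * log(N)` (natural log) and no
#' isolated nodes.
#'
#' @param cohort_mats List of rectified `connectivity_matrix` objects.
#' @param grid_step Grid resolution (default 0.01).
#' @return A list of class `threshold_selection` with elements
#'   `max_correlation_threshold`, `min_sparsity_threshold`, `degree_floor`
#'   (the `2 log N` bound) and `diagnostics`, a tibble of per-subject mean
#'   degree and isolated-node count at each candidate value.
#' @export
select_thresholds <- function(cohort_mats, grid_step = 0.01) {
  if (length(cohort_mats) < 1) stop("empty cohort", call. = FALSE)
  purrr::walk(cohort_mats, check_rectified)
  n <- nrow(cohort_mats[[1]])
  floor_deg <- 2 * log(n)

  ok_all <- function(graphs) {
    all(vapply(graphs, function(a) {
      mean_degree(a) > floor_deg && !has_isolated(a)
    }, logical(1)))
  }

  diag_rows <- list()
  record <- function(kind, value, graphs) {
    diag_rows[[length(diag_rows) + 1]] <<- tibble::tibble(
      threshold_kind = kind, threshold_value = value,
      subject = seq_along(graphs),
      mean_degree = vapply(graphs, mean_degree, numeric(1)),
      n_isolated = vapply(graphs, function(a) sum(rowSums(a) == 0),
                          numeric(1))
    )
  }

  r_grid <- seq(0, 1 - grid_step, by = grid_step)
  best_r <- NA_real_
  for (r0 in r_grid) {
    graphs <- lapply(cohort_mats, function(m) unclass(threshold_correlation(m, r0)))
    record("correlation", r0, graphs)
    if (ok_all(graphs)) best_r <- r0 else break
  }

  s_grid <- seq(grid_step, 1, by = grid_step)
  max_edges <- min(vapply(cohort_mats,
                          function(m) sum(m[upper.tri(m)] > 0), numeric(1)))
  best_s <- NA_real_
  for (s in s_grid) {
    if (round(s * n * (n - 1) / 2) > max_edges) break
    graphs <- lapply(cohort_mats, function(m) unclass(threshold_sparsity(m, s)))
    record("sparsity", s, graphs)
    if (ok_all(graphs)) {
      best_s <- s
      break
    }
  }

  if (is.na(best_r) && is.na(best_s)) {
    stop("no threshold on the grid satisfies the mean-degree and ",
         "no-isolated-node criteria for every subject", call. = FALSE)
  }
  structure(list(
    max_correlation_threshold = best_r,
    min_sparsity_threshold = best_s,
    degree_floor = floor_deg,
    diagnostics = dplyr::bind_rows(diag_rows)
  ), class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat("Threshold selection (mean degree > ",
      format(x$degree_floor, digits = 4), ", no isolated nodes)\n", sep = "")
  cat("  max correlation threshold:", x$max_correlation_threshold, "\n")
  cat("  min sparsity threshold:   ", x$min_sparsity_threshold, "\n")
  invisible(x)
}

#' Write a connectivity matrix with a JSON metadata sidecar
#'
#' @param m A `connectivity_matrix` or `binary_graph`.
#' @param path Output path for the tab-separated N x N matrix; metadata
#'   (subject, rectification, threshold settings) goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(m)))
  meta <- list(subject_id = attr(m, "subject_id"),
               rectified = attr(m, "rectified"),
               threshold_kind = attr(m, "threshold_kind"),
               threshold_value = attr(m, "threshold_value"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
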