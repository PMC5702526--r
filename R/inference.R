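residualize_vector <- function(x, covariates) {
  res <- residualize_edges(matrix(x, ncol = 1), covariates)
  as.numeric(res)
}

#' Covariate-controlled permutation test of a group mean difference
#'
#' Residualizes a per-subject metric on nuisance covariates (pooled OLS with
#' intercept), then permutes group labels to build the null distribution of
#' the mean difference. The p value uses the add-one convention
#' `(b + 1) / (n_perm + 1)`; the 95th percentile of the null is reported as
#' the one-tailed critical value. When the number of distinct label
#' arrangements does not exceed `n_perm`, the null is enumerated exhaustively
#' and the p value is exact.
#'
#' @param values Numeric metric, one per subject.
#' @param groups Character group labels (two groups).
#' @param covariates Data frame of nuisance covariates, or `NULL`.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param tail `"greater"` tests positive-group mean > other; `"less"` the
#'   reverse.
#' @param positive Label whose mean enters with positive sign (default
#'   `"control"` when present, else the first label).
#' @return A list of class `perm_test_result`: `observed_diff`, `null_diffs`,
#'   `p`, `critical_value`, `exhaustive`.
#' @export
permutation_metric_test <- function(values, groups, covariates = NULL,
                                    n_perm = 10000, seed = 1L,
                                    tail = c("greater", "less"),
                                    positive = NULL) {
  tail <- match.arg(tail)
  if (!all(is.finite(values))) stop("metric values must be finite",
                                    call. = FALSE)
  labs <- unique(groups)
  if (length(labs) != 2) stop("need exactly two groups", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("control" %in% labs) "control" else labs[1]
  }
  g1 <- groups == positive
  n1 <- sum(g1)
  n <- length(values)
  if (n1 < 2 || n - n1 < 2) stop("need at least 2 subjects per group",
                                 call. = FALSE)
  res <- residualize_vector(values, covariates)
  diff_for <- function(idx1) {
    mean(res[idx1]) - mean(res[-idx1])
  }
  observed <- diff_for(which(g1))

  set.seed(seed)
  exhaustive <- choose(n, n1) <= n_perm
  idx_mat <- if (exhaustive) {
    utils::combn(n, n1)
  } else {
    replicate(n_perm, sample.int(n, n1))
  }
  # one indicator-matrix product gives every permutation's group-1 sum
  ind <- matrix(0, ncol(idx_mat), n)
  ind[cbind(rep(seq_len(ncol(idx_mat)), each = n1), as.vector(idx_mat))] <- 1
  s1 <- as.numeric(ind %*% res)
  null_diffs <- s1 / n1 - (sum(res) - s1) / (n - n1)
  signed_null <- if (tail == "greater") null_diffs else -null_diffs
  signed_obs <- if (tail == "greater") observed else -observed
  p <- if (exhaustive) {
    mean(signed_null >= signed_obs - 1e-12)
  } else {
    (sum(signed_null >= signed_obs - 1e-12) + 1) / (length(null_diffs) + 1)
  }
  structure(list(
    observed_diff = observed, null_diffs = null_diffs, p = p,
    critical_value = stats::quantile(signed_null, 0.95, names = FALSE),
    tail = tail, positive = positive, exhaustive = exhaustive
  ), class = "perm_test_result")
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals Vector of p values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Tibble with `p`, `p_adjusted` (BH step-up) and `significant`
#'   (`p_adjusted <= q`).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value list", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, p_adjusted = adj, significant = adj <= q)
}

#' Rank partial correlation
#'
#' Spearman-type association controlling for covariates: the two variables
#' and every numeric covariate are rank-transformed (average ranks on ties),
#' each variable is residualized on the ranked covariates (plus intercept),
#' and the Pearson correlation of the residuals is reported with a
#' t-approximation p value on `n - k - 2` degrees of freedom (`k` = number
#' of covariate design columns beyond the intercept). With no covariates
#' this equals the Spearman correlation. If the covariates absorb all of a
#' variable's rank variance, the partial correlation is reported as 0.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame of covariates, or `NULL`.
#' @return One-row tibble: `r`, `df`, `p`, `n`.
#' @export
rank_partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant x or y", call. = FALSE)
  }
  k <- 0
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    num <- vapply(covariates, is.numeric, logical(1))
    covariates[num] <- lapply(covariates[num], rank)
    k <- ncol(stats::model.matrix(~ ., data = covariates)) - 1
  }
  if (n <= k + 2) stop("need n > number of covariates + 2", call. = FALSE)
  rx <- residualize_vector(rank(x), covariates)
  ry <- residualize_vector(rank(y), covariates)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    return(tibble::tibble(r = 0, df = n - k - 2, p = 1, n = n))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(r = r, df = df, p = p, n = n)
}

#' ROC analysis of a subject-level network feature
#'
#' Evaluates how well a feature (e.g. mean connectivity strength within an
#' NBS component) separates patients from controls. Patients are classified
#' positive when the feature falls *below* the cutoff — the hypoconnectivity
#' direction — so AUC > 0.5 means patients score lower. AUC is the
#' tie-corrected Mann-Whitney estimate; the operating cutoff maximizes
#' Youden's J (sensitivity + specificity - 1), taking the smallest cutoff on
#' ties; its significance is assessed by label permutation with the add-one
#' convention.
#'
#' @param scores Numeric feature per subject.
#' @param labels Character labels; `positive` marks the patient class.
#' @param n_perm Number of label permutations for `p_auc` (default 10,000).
#' @param seed Integer seed.
#' @param positive Label of the patient class (default `"patient"`).
#' @param direction `"low"` (default): patients expected below the cutoff;
#'   `"high"`: above.
#' @return A list of class `roc_result`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `p_auc`, `n_correct_patients`, `n_correct_controls`,
#'   `curve` (tibble of cutoff/sensitivity/specificity), `direction`.
#' @export
roc_analysis <- function(scores, labels, n_perm = 10000, seed = 1L,
                         positive = "patient",
                         direction = c("low", "high")) {
  direction <- match.arg(direction)
  is_pos <- labels == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  oriented <- if (direction == "low") -scores else scores

  auc_of <- function(pos_mask) {
    rk <- rank(oriented)  # midranks handle ties
    (sum(rk[pos_mask]) - sum(pos_mask) * (sum(pos_mask) + 1) / 2) /
      (sum(pos_mask) * sum(!pos_mask))
  }
  auc <- auc_of(is_pos)

  cuts <- c(-Inf, sort(unique(scores)), Inf)
  classify_pos <- function(cut) {
    if (direction == "low") scores < cut else scores > cut
  }
  sens <- vapply(cuts, function(cut) mean(classify_pos(cut)[is_pos]),
                 numeric(1))
  spec <- vapply(cuts, function(cut) mean(!classify_pos(cut)[!is_pos]),
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # cuts ascending: first max = smallest cutoff
  curve <- tibble::tibble(cutoff = cuts, sensitivity = sens,
                          specificity = spec)

  set.seed(seed)
  null_auc <- vapply(seq_len(n_perm), function(it) {
    auc_of(sample(is_pos))
  }, numeric(1))
  p_auc <- (sum(null_auc >= auc - 1e-12) + 1) / (n_perm + 1)

  structure(list(
    auc = auc, cutoff = cuts[best], sensitivity = sens[best],
    specificity = spec[best], p_auc = p_auc,
    n_correct_patients = round(sens[best] * n1),
    n_correct_controls = round(spec[best] * n0),
    n_patients = n1, n_controls = n0,
    curve = curve, direction = direction
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (permutation p = %.4g), cutoff = %.3f, sensitivity = %.1f%%, specificity = %.1f%%\n",
    x$auc, x$p_auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  %d/%d patients and %d/%d controls classified correctly\n",
              x$n_correct_patients, x$n_patients,
              x$n_correct_controls, x$n_controls))
  invisible(x)
}
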