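#' Configuration for a synthetic two-group cohort
#'
#' Describes the statistical structure of a simulated resting-state cohort:
#' two groups of subjects, each with a T x N matrix of regional BOLD-like time
#' series whose cross-sectional correlation follows a network-block pattern
#' (higher within a functional network than between networks), plus a planted
#' hypoconnectivity component — a connected set of edges whose correlation is
#' reduced in the patient group only. Covariates (age, gender, IQ, head-motion
#' summaries) are drawn from common distributions for both groups so that any
#' downstream group difference in them is null by construction; the clinical
#' scores carry a planted group difference and, within patients, a positive
#' correlation with realized planted-edge connectivity.
#'
#' @param n_patients,n_controls Group sizes (defaults 46 and 31).
#' @param n_volumes Time points per subject (default 230, i.e. an 8-minute
#'   acquisition at TR = 2 s minus 10 equilibration volumes).
#' @param base_within_network_r Target correlation between regions of the same
#'   network (default 0.45).
#' @param base_between_network_r Target correlation between regions of
#'   different networks (default 0.15).
#' @param planted_edges Two-column matrix or data frame of node index pairs on
#'   which the patient group's correlation is reduced. `NULL` (default)
#'   selects a deterministic connected set of 30 long-range (> 75 mm)
#'   inter-network pairs spanning 26 nodes, preferring the longest distances
#'   (see [planted_long_range_component()]). The packaged published component
#'   edge list can be supplied instead via [load_component_edges()].
#' @param effect_delta Correlation reduction applied to planted edges in the
#'   patient group (default 0.25). Planted correlations are floored at zero:
#'   hypoconnectivity is modelled as loss of positive coupling, never as
#'   induced anticorrelation, matching the rectified-positive analysis regime.
#' @param temporal_ar Lag-1 autocorrelation of each regional series (default
#'   0.3), emulating the smoothness left by band-pass filtering.
#' @param subject_sd Between-subject standard deviation of the true edge
#'   connectivity (default 0.10): each subject's target correlation matrix
#'   is obtained by adding independent Gaussian noise of this sd to the
#'   group target's canonical partial-correlation (vine) parametrization and
#'   mapping back, which keeps the matrix positive definite by construction
#'   and makes the induced edge-level deviations approximately independent
#'   across edges — the structure expected of nuisance-regressed
#'   connectivity, where shared global fluctuations have already been
#'   removed. The default keeps planted edge-level group effects in the
#'   t = 3-5 range typical of published component edge lists; set to 0 for
#'   identical true connectivity across subjects.
#' @param clinical_rho Within-patient correlation between clinical scores and
#'   realized mean planted-edge connectivity (default 0.4).
#' @param covariates Named list overriding any of the covariate/clinical
#'   distribution parameters; see the `cov` defaults in the function body
#'   (means/SDs for age, IQ, motion summaries, male proportion, and per-group
#'   clinical score means/SDs on the 0-3 questionnaire scale).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 46, n_controls = 31, n_volumes = 230,
                          base_within_network_r = 0.45,
                          base_between_network_r = 0.15,
                          planted_edges = NULL, effect_delta = 0.25,
                          temporal_ar = 0.3, subject_sd = 0.10,
                          clinical_rho = 0.4,
                          covariates = list(), seed = 1L) {
  stopifnot(n_patients >= 2, n_controls >= 2, n_volumes >= 2)
  for (r in c(base_within_network_r, base_between_network_r)) {
    if (r < 0 || r >= 1) stop("correlation targets must be in [0, 1)",
                              call. = FALSE)
  }
  if (abs(temporal_ar) >= 1) stop("temporal_ar must be in (-1, 1)",
                                  call. = FALSE)
  if (subject_sd < 0 || subject_sd >= 1) {
    stop("subject_sd must be in [0, 1)", call. = FALSE)
  }
  cov <- list(
    age_mean = 8.6, age_sd = 1.8,
    iq_mean = 119, iq_sd = 12,
    male_prop = 0.78,
    motion_max_mean = 1.0, motion_max_sd = 0.4,
    motion_rms_mean = 0.30, motion_rms_sd = 0.10,
    motion_fd_mean = 0.15, motion_fd_sd = 0.05,
    hyper_patient_mean = 1.45, hyper_patient_sd = 0.55,
    hyper_control_mean = 0.40, hyper_control_sd = 0.35,
    impulsive_patient_mean = 1.54, impulsive_patient_sd = 0.63,
    impulsive_control_mean = 0.50, impulsive_control_sd = 0.48
  )
  unknown <- setdiff(names(covariates), names(cov))
  if (length(unknown) > 0) {
    stop("unknown covariate parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cov[names(covariates)] <- covariates
  bad <- names(cov)[vapply(cov, function(v) !is.finite(v), logical(1))]
  if (length(bad) > 0) {
    stop("non-finite covariate parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(cov[grepl("_sd$", names(cov))]) < 0)) {
    stop("covariate SDs must be non-negative", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, n_controls = n_controls, n_volumes = n_volumes,
    base_within_network_r = base_within_network_r,
    base_between_network_r = base_between_network_r,
    planted_edges = planted_edges, effect_delta = effect_delta,
    temporal_ar = temporal_ar, subject_sd = subject_sd,
    clinical_rho = clinical_rho,
    covariates = cov, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Deterministic long-range inter-network component for planting
#'
#' Builds the generator's default hypoconnectivity substrate: a connected set
#' of `m_edges` edges spanning exactly `n_nodes` nodes, drawn greedily from
#' the long-range (> 75 mm) inter-network region pairs in order of
#' decreasing distance. Growth alternates between node-adding and
#' set-internal edges as needed to land exactly on the requested node count,
#' so the result is connected by construction and reproducible for a given
#' atlas.
#'
#' @param atlas A `ctrlnet_atlas`.
#' @param m_edges Edge count (default 30).
#' @param n_nodes Node count the set must span (default 26).
#' @return Two-column matrix of node index pairs (`i < j`).
#' @export
planted_long_range_component <- function(atlas, m_edges = 30, n_nodes = 26) {
  dist_tab <- pairwise_distances(atlas)
  cand <- dist_tab[dist_tab$long_range & dist_tab$inter_network, ]
  cand <- cand[order(-cand$distance), ]
  if (nrow(cand) < m_edges) {
    stop("atlas has only ", nrow(cand), " long-range inter-network pairs",
         call. = FALSE)
  }
  in_set <- logical(nrow(atlas))
  chosen <- matrix(NA_integer_, m_edges, 2)
  in_set[c(cand$i[1], cand$j[1])] <- TRUE
  chosen[1, ] <- c(cand$i[1], cand$j[1])
  taken <- rep(FALSE, nrow(cand))
  taken[1] <- TRUE
  for (k in 2:m_edges) {
    nodes_now <- sum(in_set)
    edges_left <- m_edges - k + 1
    nodes_needed <- n_nodes - nodes_now
    touches <- in_set[cand$i] + in_set[cand$j]
    admissible <- !taken & touches >= 1 &
      (touches == 2 | nodes_needed > 0) &      # may not overshoot node count
      (touches == 1 | edges_left > nodes_needed) # must still reach node count
    pick <- which(admissible)[1]
    if (is.na(pick)) {
      stop("could not grow a ", m_edges, "-edge / ", n_nodes,
           "-node long-range inter-network component on this atlas",
           call. = FALSE)
    }
    chosen[k, ] <- c(cand$i[pick], cand$j[pick])
    in_set[chosen[k, ]] <- TRUE
    taken[pick] <- TRUE
  }
  if (sum(in_set) != n_nodes) {
    stop("planted component construction failed to reach ", n_nodes,
         " nodes", call. = FALSE)
  }
  cbind(pmin(chosen[, 1], chosen[, 2]), pmax(chosen[, 1], chosen[, 2]))
}

default_planted_edges <- function(atlas) {
  planted_long_range_component(atlas)
}

resolve_planted <- function(atlas, config) {
  pe <- config$planted_edges
  if (is.null(pe)) pe <- default_planted_edges(atlas)
  pe <- as.matrix(as.data.frame(pe))[, 1:2, drop = FALSE]
  storage.mode(pe) <- "integer"
  n <- nrow(atlas)
  if (any(pe < 1 | pe > n) || any(pe[, 1] == pe[, 2])) {
    stop("planted edges must be pairs of distinct node indices in 1..", n,
         call. = FALSE)
  }
  cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
}

# Canonical (C-vine) partial correlations of a correlation matrix: entry
# [k, j] (k < j) is the correlation of variables k and j given 1..k-1.
# Any such set with entries in (-1, 1) maps back to a positive-definite
# correlation matrix, which is what makes it a safe space to jitter in.
partial_from_corr <- function(r) {
  n <- nrow(r)
  p <- matrix(0, n, n)
  prt <- r
  for (k in seq_len(n - 1)) {
    p[k, (k + 1):n] <- prt[k, (k + 1):n]
    if (k < n - 1) {
      idx <- (k + 1):n
      rk <- prt[k, idx]
      denom <- sqrt(1 - rk^2)
      prt[idx, idx] <- (prt[idx, idx] - outer(rk, rk)) / outer(denom, denom)
    }
  }
  p
}

# Inverse map: correlation matrix from canonical partial correlations.
corr_from_partial <- function(p) {
  n <- nrow(p)
  r <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rho <- p[i, j]
      if (i > 1) {
        for (k in (i - 1):1) {
          rho <- rho * sqrt((1 - p[k, i]^2) * (1 - p[k, j]^2)) +
            p[k, i] * p[k, j]
        }
      }
      r[i, j] <- r[j, i] <- rho
    }
  }
  dimnames(r) <- dimnames(p)
  r
}

# Clip eigenvalues at `floor`, re-symmetrize, restore unit diagonal.
nearest_pd <- function(m, floor = 1e-6) {
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(eig$values) >= floor) return((m + t(m)) / 2)
  vals <- pmax(eig$values, floor)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  out <- (out + t(out)) / 2
  if (any(!is.finite(out)) || any(diag(out) <= 0)) {
    stop("covariance repair failed; minimum eigenvalue ",
         format(min(eig$values)), call. = FALSE)
  }
  stats::cov2cor(out)
}

#' Target cross-sectional correlation matrix for one group
#'
#' Builds the N x N block-structured target: unit diagonal,
#' `base_within_network_r` for same-network pairs, `base_between_network_r`
#' for cross-network pairs; for the patient group, planted edges are reduced
#' by `effect_delta` (floored at zero). The result is projected to the nearest
#' positive-definite correlation matrix (eigenvalue clipping at 1e-6) if the
#' raw target is not already positive definite.
#'
#' @param atlas A `ctrlnet_atlas`.
#' @param config A `cohort_config`.
#' @param group `"patient"` or `"control"`.
#' @return A symmetric positive-definite N x N matrix with unit diagonal.
#' @export
build_group_covariance <- function(atlas, config, group = c("control",
                                                            "patient")) {
  stopifnot(inherits(atlas, "ctrlnet_atlas"), inherits(config, "cohort_config"))
  group <- match.arg(group)
  n <- nrow(atlas)
  same <- outer(atlas$network, atlas$network, "==")
  m <- ifelse(same, config$base_within_network_r,
              config$base_between_network_r)
  diag(m) <- 1
  if (group == "patient" && config$effect_delta != 0) {
    pe <- resolve_planted(atlas, config)
    for (k in seq_len(nrow(pe))) {
      v <- max(m[pe[k, 1], pe[k, 2]] - config$effect_delta, 0)
      m[pe[k, 1], pe[k, 2]] <- v
      m[pe[k, 2], pe[k, 1]] <- v
    }
  }
  dimnames(m) <- list(atlas$label, atlas$label)
  nearest_pd(m)
}

#' Generate a synthetic two-group cohort
#'
#' Draws each subject's T x N time-series matrix from a zero-mean Gaussian
#' process whose cross-sectional correlation is the group target from
#' [build_group_covariance()] and whose temporal structure is AR(1) with
#' coefficient `temporal_ar` (applied per latent series before spatial
#' mixing, so the marginal variance and the cross-sectional correlation are
#' unaffected). Covariates are drawn from common distributions for both
#' groups; clinical scores are higher in patients and, within patients,
#' positively correlated (rho = `clinical_rho`) with the subject's realized
#' mean correlation over the planted edges.
#'
#' @param atlas A `ctrlnet_atlas`.
#' @param config A `cohort_config`.
#' @return A tibble of class `ctrlnet_cohort`, one row per subject, with
#'   columns `subject_id`, `group`, `age`, `gender` (0/1, 1 = male), `iq`,
#'   `motion_max`, `motion_rms`, `motion_meanFD`, `hyperactivity_index`,
#'   `impulsive_score`, and a list-column `timeseries` of T x N matrices
#'   (columns named by atlas labels). The atlas and config are attached as
#'   attributes `atlas` and `config`.
#' @examples
#' atlas <- load_atlas(ctrlnet_file("control_atlas.tsv"))
#' cfg <- cohort_config(n_patients = 4, n_controls = 4, n_volumes = 80)
#' cohort <- generate_cohort(atlas, cfg)
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(atlas, config) {
  stopifnot(inherits(atlas, "ctrlnet_atlas"), inherits(config, "cohort_config"))
  n <- nrow(atlas)
  if (config$n_volumes < 2 * n) {
    stop("n_volumes must be at least 2 * N = ", 2 * n, call. = FALSE)
  }
  set.seed(config$seed)
  sigma <- list(
    patient = build_group_covariance(atlas, config, "patient"),
    control = build_group_covariance(atlas, config, "control")
  )
  pe <- resolve_planted(atlas, config)
  phi <- config$temporal_ar
  tt <- config$n_volumes

  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  n_sub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n_sub))

  partials <- lapply(sigma, partial_from_corr)
  subject_target <- function(group) {
    if (config$subject_sd == 0) return(sigma[[group]])
    p <- partials[[group]]
    noise <- matrix(stats::rnorm(n * n, sd = config$subject_sd), n, n)
    p[upper.tri(p)] <- pmin(pmax(p[upper.tri(p)] + noise[upper.tri(noise)],
                                 -0.98), 0.98)
    corr_from_partial(p)
  }
  sim_one <- function(group) {
    u <- chol(subject_target(group))
    z <- matrix(stats::rnorm(tt * n), tt, n)
    if (phi != 0) {
      scale <- sqrt(1 - phi^2)
      for (t in 2:tt) z[t, ] <- phi * z[t - 1, ] + scale * z[t, ]
    }
    ts <- z %*% u
    colnames(ts) <- atlas$label
    ts
  }
  timeseries <- lapply(groups, sim_one)

  # realized planted-edge connectivity, the substrate of the clinical scores
  planted_mean <- vapply(timeseries, function(ts) {
    r <- stats::cor(ts)
    mean(r[pe])
  }, numeric(1))

  cv <- config$covariates
  rtrunc <- function(n, mean, sd, lower = 0) pmax(stats::rnorm(n, mean, sd),
                                                  lower)
  pheno <- tibble::tibble(
    subject_id = ids,
    group = groups,
    age = round(stats::rnorm(n_sub, cv$age_mean, cv$age_sd), 1),
    gender = stats::rbinom(n_sub, 1, cv$male_prop),
    iq = round(stats::rnorm(n_sub, cv$iq_mean, cv$iq_sd)),
    motion_max = rtrunc(n_sub, cv$motion_max_mean, cv$motion_max_sd, 0.05),
    motion_rms = rtrunc(n_sub, cv$motion_rms_mean, cv$motion_rms_sd, 0.01),
    motion_meanFD = rtrunc(n_sub, cv$motion_fd_mean, cv$motion_fd_sd, 0.01)
  )

  clin_score <- function(is_patient, mean_pat, sd_pat, mean_ctl, sd_ctl) {
    out <- numeric(n_sub)
    eps <- stats::rnorm(n_sub)
    pat <- which(is_patient)
    z <- as.numeric(scale(planted_mean[pat]))
    rho <- config$clinical_rho
    out[pat] <- mean_pat + sd_pat * (rho * z + sqrt(1 - rho^2) * eps[pat])
    ctl <- which(!is_patient)
    out[ctl] <- mean_ctl + sd_ctl * eps[ctl]
    pmin(pmax(out, 0), 3)
  }
  is_pat <- groups == "patient"
  pheno$hyperactivity_index <- clin_score(is_pat, cv$hyper_patient_mean,
                                          cv$hyper_patient_sd,
                                          cv$hyper_control_mean,
                                          cv$hyper_control_sd)
  pheno$impulsive_score <- clin_score(is_pat, cv$impulsive_patient_mean,
                                      cv$impulsive_patient_sd,
                                      cv$impulsive_control_mean,
                                      cv$impulsive_control_sd)
  pheno$timeseries <- timeseries
  attr(pheno, "atlas") <- atlas
  attr(pheno, "config") <- config
  attr(pheno, "planted_edges") <- pe
  class(pheno) <- c("ctrlnet_cohort", class(pheno))
  pheno
}

#' Write a cohort to disk as plain text
#'
#' Writes one tab-separated T x N time-series file per subject (header row of
#' atlas labels) and a `phenotype.csv` table.
#'
#' @param cohort A `ctrlnet_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctrlnet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map2_chr(cohort$subject_id, cohort$timeseries, function(id, ts) {
    path <- file.path(dir, paste0(id, "_timeseries.tsv"))
    utils::write.table(format(ts, digits = 8, trim = TRUE), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    path
  })
  pheno <- dplyr::select(tibble::as_tibble(cohort), -"timeseries")
  pheno_path <- file.path(dir, "phenotype.csv")
  utils::write.csv(pheno, pheno_path, row.names = FALSE)
  invisible(c(paths, pheno_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `phenotype.csv` and per-subject
#'   `*_timeseries.tsv` files.
#' @param atlas The atlas the time series were generated against.
#' @return A `ctrlnet_cohort` tibble (without generator attributes other than
#'   the atlas).
#' @export
read_cohort <- function(dir, atlas) {
  pheno_path <- file.path(dir, "phenotype.csv")
  if (!file.exists(pheno_path)) {
    stop("no phenotype.csv under ", dir, call. = FALSE)
  }
  pheno <- tibble::as_tibble(utils::read.csv(pheno_path,
                                             stringsAsFactors = FALSE))
  pheno$timeseries <- lapply(pheno$subject_id, function(id) {
    path <- file.path(dir, paste0(id, "_timeseries.tsv"))
    if (!file.exists(path)) stop("missing time-series file for ", id,
                                 call. = FALSE)
    m <- as.matrix(utils::read.delim(path, check.names = FALSE))
    if (ncol(m) != nrow(atlas)) {
      stop("time series for ", id, " has ", ncol(m), " columns; atlas has ",
           nrow(atlas), call. = FALSE)
    }
    m
  })
  attr(pheno, "atlas") <- atlas
  class(pheno) <- c("ctrlnet_cohort", class(pheno))
  pheno
}
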