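stage_seed <- function(seed, k) {
  # single global seed fans out to per-stage seeds via a fixed counter scheme
  as.integer((as.numeric(seed) * 101 + k) %% (.Machine$integer.max - 1))
}

#' Study pipeline configuration
#'
#' Collects every tunable of the end-to-end study replica. Any element can be
#' overridden; defaults reproduce the analysis design at publication-scale
#' permutation counts (reduce `nbs_n_perm`, `distance_n_iter`,
#' `inference_n_perm` and `n_nulls` for quick runs).
#'
#' @param output_dir Where result files are written.
#' @param atlas_path Atlas file; `NULL` uses the packaged 34-region atlas.
#' @param cohort_dir Directory of an existing cohort ([write_cohort()]
#'   layout); `NULL` simulates one with `cohort`.
#' @param cohort A [cohort_config()] for simulation.
#' @param threshold_mode `"auto"` (select on the cohort), or `"fixed"` using
#'   `correlation_threshold` / `sparsity_threshold`.
#' @param correlation_threshold,sparsity_threshold Fixed threshold values
#'   (used when `threshold_mode = "fixed"`).
#' @param n_nulls Rewired nulls per subject graph for metric normalization.
#' @param nbs_primary_p,nbs_n_perm,nbs_prevalence,nbs_tail NBS settings; see
#'   [nbs_config()].
#' @param distance_n_iter Draws for the distance resampling null.
#' @param inference_n_perm Permutations for metric group tests and ROC.
#' @param covariate_names Phenotype columns regressed out everywhere.
#' @param fdr_q FDR level for nodal tests.
#' @param seed Global seed; per-stage seeds derive from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(output_dir = tempfile("ctrlnet_study_"),
                         atlas_path = NULL, cohort_dir = NULL,
                         cohort = cohort_config(),
                         threshold_mode = c("auto", "fixed"),
                         correlation_threshold = NULL,
                         sparsity_threshold = NULL,
                         n_nulls = 100,
                         nbs_primary_p = 0.05, nbs_n_perm = 10000,
                         nbs_prevalence = 0.5,
                         nbs_tail = "controls_greater",
                         distance_n_iter = 10000,
                         inference_n_perm = 10000,
                         covariate_names = c("age", "gender", "iq",
                                             "motion_max", "motion_rms",
                                             "motion_meanFD"),
                         fdr_q = 0.05, seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" &&
      is.null(correlation_threshold) && is.null(sparsity_threshold)) {
    stop("fixed threshold mode needs correlation_threshold and/or ",
         "sparsity_threshold", call. = FALSE)
  }
  structure(as.list(environment()), class = "study_config")
}

metric_tail <- function(metric) {
  # patients are expected to have fewer modules' complement: controls lower
  if (metric == "n_modules") "less" else "greater"
}

#' Run the full study replica
#'
#' Sequences the whole analysis: cohort (simulated or loaded), rectified
#' correlation matrices, threshold selection, per-subject global/nodal
#' metrics with null normalization under both thresholding strategies,
#' covariate-controlled NBS, anatomical-distance analysis of the largest
#' significant component (long-range/inter-network profile, complement
#' t-test, matched resampling null), covariate-controlled permutation tests
#' of every global metric with FDR-corrected nodal tests, rank partial
#' correlations of component strength with clinical scores (patients and
#' controls separately), and ROC classification on component strength.
#' All quantitative outputs are written as CSV/JSON under
#' `config$output_dir` together with a manifest of seeds and timings.
#'
#' @param config A [study_config()].
#' @return A list of class `ctrlnet_study` with elements `atlas`, `cohort`,
#'   `thresholds`, `global_metrics`, `nodal_metrics`, `global_tests`,
#'   `nodal_tests`, `nbs`, `distance`, `clinical`, `roc`, `manifest`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  fail <- function(stage, e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # -- atlas ---------------------------------------------------------------
  atlas <- tryCatch({
    path <- config$atlas_path
    if (is.null(path)) path <- ctrlnet_file("control_atlas.tsv")
    load_atlas(path)
  }, error = function(e) fail("atlas", e))
  dist_tab <- pairwise_distances(atlas)
  log_stage("atlas", nrow(atlas), " regions")

  # -- cohort --------------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$cohort_dir)) {
      read_cohort(config$cohort_dir, atlas)
    } else {
      cfg <- config$cohort
      cfg$seed <- stage_seed(config$seed, 1)
      generate_cohort(atlas, cfg)
    }
  }, error = function(e) fail("cohort", e))
  groups <- cohort$group
  covariates <- as.data.frame(cohort)[, config$covariate_names, drop = FALSE]
  log_stage("cohort", sum(groups == "patient"), " patients / ",
            sum(groups == "control"), " controls")

  # -- connectivity & thresholds ------------------------------------------
  mats <- tryCatch(cohort_connectivity(cohort),
                   error = function(e) fail("connectivity", e))
  thresholds <- tryCatch({
    if (config$threshold_mode == "auto") {
      sel <- select_thresholds(mats)
      list(correlation = sel$max_correlation_threshold,
           sparsity = sel$min_sparsity_threshold, selection = sel)
    } else {
      list(correlation = config$correlation_threshold,
           sparsity = config$sparsity_threshold, selection = NULL)
    }
  }, error = function(e) fail("thresholds", e))
  log_stage("thresholds", "correlation = ", thresholds$correlation,
            ", sparsity = ", thresholds$sparsity)

  modes <- list()
  if (!is.null(thresholds$correlation) && !is.na(thresholds$correlation)) {
    modes$correlation <- lapply(mats, threshold_correlation,
                                r0 = thresholds$correlation)
  }
  if (!is.null(thresholds$sparsity) && !is.na(thresholds$sparsity)) {
    modes$sparsity <- lapply(mats, threshold_sparsity,
                             s = thresholds$sparsity)
  }

  # -- topological metrics -------------------------------------------------
  metrics_global <- tryCatch({
    rows <- list()
    for (mode in names(modes)) {
      graphs <- modes[[mode]]
      for (s in seq_along(graphs)) {
        row <- normalized_global_metrics(
          graphs[[s]], n_nulls = config$n_nulls,
          seed = stage_seed(config$seed, 2 + s))
        row <- tibble::add_column(row, subject_id = cohort$subject_id[s],
                                  group = groups[s], threshold_kind = mode,
                                  .before = 1)
        rows[[length(rows) + 1]] <- row
      }
    }
    dplyr::bind_rows(rows)
  }, error = function(e) fail("global-metrics", e))

  metrics_nodal <- tryCatch({
    rows <- list()
    for (mode in names(modes)) {
      graphs <- modes[[mode]]
      for (s in seq_along(graphs)) {
        nm <- nodal_metrics(graphs[[s]])
        nm <- tibble::add_column(nm, subject_id = cohort$subject_id[s],
                                 group = groups[s], threshold_kind = mode,
                                 .before = 1)
        rows[[length(rows) + 1]] <- nm
      }
    }
    dplyr::bind_rows(rows)
  }, error = function(e) fail("nodal-metrics", e))
  log_stage("metrics", "computed for ", length(modes), " thresholding modes")

  # -- group tests on metrics ---------------------------------------------
  global_fields <- c("density", "e_glob", "e_loc", "q_max", "n_modules",
                     "normalized_e_glob", "normalized_e_loc", "normalized_q")
  global_tests <- tryCatch({
    rows <- list()
    for (mode in names(modes)) {
      sub <- metrics_global[metrics_global$threshold_kind == mode, ]
      for (field in global_fields) {
        if (mode == "sparsity" && field == "density") next
        pt <- permutation_metric_test(
          sub[[field]], sub$group, covariates,
          n_perm = config$inference_n_perm,
          seed = stage_seed(config$seed, 90), tail = metric_tail(field))
        rows[[length(rows) + 1]] <- tibble::tibble(
          threshold_kind = mode, metric = field,
          observed_diff = pt$observed_diff, p = pt$p,
          critical_value = pt$critical_value, tail = pt$tail)
      }
    }
    dplyr::bind_rows(rows)
  }, error = function(e) fail("global-tests", e))

  nodal_tests <- tryCatch({
    rows <- list()
    for (mode in names(modes)) {
      sub <- metrics_nodal[metrics_nodal$threshold_kind == mode, ]
      for (field in c("degree", "efficiency", "betweenness")) {
        per_node <- lapply(seq_len(nrow(atlas)), function(v) {
          vv <- sub[sub$node == v, ]
          pt <- permutation_metric_test(
            vv[[field]], vv$group, covariates,
            n_perm = max(200, config$inference_n_perm %/% 10),
            seed = stage_seed(config$seed, 91), tail = "greater")
          tibble::tibble(threshold_kind = mode, metric = field, node = v,
                         label = atlas$label[v],
                         observed_diff = pt$observed_diff, p = pt$p)
        })
        block <- dplyr::bind_rows(per_node)
        block <- dplyr::bind_cols(
          block, fdr_correct(block$p, config$fdr_q)[, c("p_adjusted",
                                                        "significant")])
        rows[[length(rows) + 1]] <- block
      }
    }
    dplyr::bind_rows(rows)
  }, error = function(e) fail("nodal-tests", e))
  log_stage("inference", "metric permutation tests done")

  # -- NBS -----------------------------------------------------------------
  nbs <- tryCatch({
    cfg <- nbs_config(primary_p = config$nbs_primary_p,
                      n_perm = config$nbs_n_perm,
                      prevalence = config$nbs_prevalence,
                      tail = config$nbs_tail,
                      seed = stage_seed(config$seed, 4))
    nbs_test(mats, groups, covariates, cfg, atlas = atlas)
  }, error = function(e) fail("nbs", e))
  significant <- purrr::keep(nbs$components,
                             function(x) x$corrected_p < 0.05)
  log_stage("nbs", length(nbs$components), " component(s), ",
            length(significant), " significant")

  # -- distance analysis of the leading significant component -------------
  distance <- NULL
  clinical <- NULL
  roc <- NULL
  if (length(significant) > 0) {
    comp <- significant[[1]]
    distance <- tryCatch(list(
      summary = component_distance_summary(comp, dist_tab),
      ttest = distance_ttest(comp, dist_tab),
      resampling = distance_resampling_test(
        comp, dist_tab, n_iter = config$distance_n_iter,
        seed = stage_seed(config$seed, 5))
    ), error = function(e) fail("distance", e))
    log_stage("distance", "resampling p = ",
              distance$resampling$empirical_p)

    strength <- vapply(mats, component_mean_strength, numeric(1),
                       component = comp)
    clinical <- tryCatch({
      rows <- list()
      for (grp in c("patient", "control")) {
        in_grp <- groups == grp
        for (score in c("hyperactivity_index", "impulsive_score")) {
          rr <- rank_partial_correlation(strength[in_grp],
                                         cohort[[score]][in_grp],
                                         covariates[in_grp, , drop = FALSE])
          rows[[length(rows) + 1]] <- tibble::add_column(
            rr, group = grp, score = score, .before = 1)
        }
      }
      dplyr::bind_rows(rows)
    }, error = function(e) fail("clinical", e))

    roc <- tryCatch(
      roc_analysis(strength, groups, n_perm = config$inference_n_perm,
                   seed = stage_seed(config$seed, 6)),
      error = function(e) fail("roc", e))
    log_stage("roc", "AUC = ", round(roc$auc, 3))
  } else {
    log_stage("nbs", "no significant component; distance/clinical/ROC ",
              "stages skipped")
  }

  # -- outputs -------------------------------------------------------------
  out <- config$output_dir
  readr::write_csv(metrics_global, file.path(out, "global_metrics.csv"))
  readr::write_csv(metrics_nodal, file.path(out, "nodal_metrics.csv"))
  readr::write_csv(global_tests, file.path(out, "global_tests.csv"))
  readr::write_csv(nodal_tests, file.path(out, "nodal_tests.csv"))
  write_nbs_outputs(nbs, dist_tab, atlas, out)
  if (!is.null(distance)) {
    readr::write_csv(tibble::tibble(null_mean = distance$resampling$null_means),
                     file.path(out, "distance_null_means.csv"))
    jsonlite::write_json(list(
      observed_mean = distance$resampling$observed_mean,
      empirical_p = distance$resampling$empirical_p,
      ttest = as.list(distance$ttest),
      summary = as.list(distance$summary$summary)),
      file.path(out, "distance_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(clinical)) {
    readr::write_csv(clinical, file.path(out, "clinical_correlations.csv"))
  }
  if (!is.null(roc)) {
    readr::write_csv(roc$curve, file.path(out, "roc_curve.csv"))
    jsonlite::write_json(
      roc[c("auc", "cutoff", "sensitivity", "specificity", "p_auc",
            "n_correct_patients", "n_correct_controls")],
      file.path(out, "roc.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctrlnet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stage_seeds = list(cohort = stage_seed(config$seed, 1),
                       nbs = stage_seed(config$seed, 4),
                       distance = stage_seed(config$seed, 5),
                       roc = stage_seed(config$seed, 6)),
    thresholds = thresholds[c("correlation", "sparsity")],
    n_subjects = length(groups),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(
    atlas = atlas, cohort = cohort, thresholds = thresholds,
    global_metrics = metrics_global, nodal_metrics = metrics_nodal,
    global_tests = global_tests, nodal_tests = nodal_tests,
    nbs = nbs, distance = distance, clinical = clinical, roc = roc,
    manifest = manifest, config = config
  ), class = "ctrlnet_study")
}

write_nbs_outputs <- function(nbs, dist_tab, atlas, out) {
  d <- dist_lookup(dist_tab)
  inter <- matrix(NA, nrow(d), nrow(d))
  inter[cbind(dist_tab$i, dist_tab$j)] <- dist_tab$inter_network
  inter[cbind(dist_tab$j, dist_tab$i)] <- dist_tab$inter_network
  comp_json <- lapply(nbs$components, function(comp) {
    list(n_edges = comp$n_edges, n_nodes = comp$n_nodes,
         corrected_p = comp$corrected_p,
         edges = purrr::map2(comp$edges$i, comp$edges$j, function(i, j) {
           c(atlas$label[i], atlas$label[j])
         }))
  })
  jsonlite::write_json(comp_json, file.path(out, "nbs_components.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(nbs$components) > 0) {
    comp <- nbs$components[[1]]
    edges <- comp$edges
    p_edge <- edge_pvals(edges$t, nbs$df, nbs$config$tail,
                         nbs$config$edge_p)
    tab <- tibble::tibble(
      regionA = atlas$label[edges$i], regionB = atlas$label[edges$j],
      p = round(p_edge, 3),
      distance = round(d[cbind(edges$i, edges$j)], 3),
      category = paste0(atlas$network[edges$i], "-", atlas$network[edges$j]))
    readr::write_csv(tab[order(tab$p), ],
                     file.path(out, "nbs_component_edges.csv"))
  }
  invisible(NULL)
}

#' Write the packaged atlas and component fixtures to a directory
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) {
    stop("directory not writable: ", dir, call. = FALSE)
  }
  paths <- vapply(c("control_atlas.tsv", "nbs_component_edges.csv"),
                  function(f) {
                    dest <- file.path(dir, f)
                    file.copy(ctrlnet_file(f), dest, overwrite = TRUE)
                    dest
                  }, character(1))
  invisible(unname(paths))
}

#' Load a study configuration from a YAML or JSON file
#'
#' Top-level keys mirror [study_config()] arguments; a `cohort` block is
#' passed to [cohort_config()].
#'
#' @param path YAML or JSON file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$cohort)) {
    vals$cohort <- do.call(cohort_config, vals$cohort)
  }
  do.call(study_config, vals)
}
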