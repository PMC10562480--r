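#' Pipeline configuration
#'
#' Collects the tunable settings of the end-to-end pipeline with the
#' published defaults: 8-pixel centroid grid, unbounded run-length window,
#' path cap 10, 10,000-tree random forest, 5-fold cross-validation.
#'
#' @param grid_spacing_pixels Centroid grid cell edge in pixels.
#' @param gmm_seed Seed for the mixture fits.
#' @param window_radius_mm Run-length circular window radius (`Inf` =
#'   whole map).
#' @param L_max Run path-length cap.
#' @param rf_trees Trees per random forest.
#' @param cv_folds Cross-validation folds.
#' @param rf_seed Seed for fold assignment and forests.
#' @param slice_selection `"max-area"` or an explicit slice index.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_spacing_pixels = 8, gmm_seed = 1L,
                            window_radius_mm = Inf, L_max = 10,
                            rf_trees = 10000, cv_folds = 5, rf_seed = 1L,
                            slice_selection = "max-area") {
  hg_assert(grid_spacing_pixels >= 1 && L_max >= 1 && rf_trees >= 1 &&
              cv_folds >= 2 && window_radius_mm > 0,
            "all numeric configuration fields must be positive")
  structure(list(grid_spacing_pixels = grid_spacing_pixels,
                 gmm_seed = as.integer(gmm_seed),
                 window_radius_mm = window_radius_mm,
                 L_max = as.integer(L_max),
                 rf_trees = as.integer(rf_trees),
                 cv_folds = as.integer(cv_folds),
                 rf_seed = as.integer(rf_seed),
                 slice_selection = slice_selection),
            class = "pipeline_config")
}

#' Names of all 52 subject features in table order
#' @return Character vector: 28 MST feature names then 24 run-length
#'   feature names.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(habitat_labels(), mst_stat_names(), paste, sep = "_"))),
    grlm_feature_names())
}

#' All 52 features for one subject
#'
#' Habitat segmentation, then the 28 MST features and 24 run-length
#' features. Failures of a stage are recorded as missing values and noted
#' in the attached log, never raised: missingness is data here.
#'
#' @param slices A [slice_pair()].
#' @param config A [pipeline_config()].
#' @return Named numeric vector of length 52 with attribute `log` (list
#'   with the subject id, fitted thresholds, centroid counts and any
#'   warnings).
#' @export
subject_features <- function(slices, config = pipeline_config()) {
  log <- list(subject_id = slices$subject_id, warnings = character(0))
  feats <- stats::setNames(rep(NA_real_, 52), feature_names())
  masks <- tryCatch(make_habitat_masks(slices, seed = config$gmm_seed),
                    habitatgraph_error = function(e) {
                      log$warnings <<- c(log$warnings, conditionMessage(e))
                      NULL
                    })
  if (!is.null(masks)) {
    log$thresholds <- as.list(masks$thresholds)
    pts <- subject_centroids(masks, config$grid_spacing_pixels)
    log$centroid_counts <- as.list(table(factor(pts$habitat,
                                                levels = habitat_labels())))
    mst <- subject_mst_features(masks, config$grid_spacing_pixels)
    feats[names(mst)] <- mst
    grl <- tryCatch(
      subject_grlm_features(masks, config$grid_spacing_pixels,
                            config$window_radius_mm, config$L_max),
      habitatgraph_error = function(e) {
        log$warnings <<- c(log$warnings, conditionMessage(e))
        NULL
      })
    if (!is.null(grl)) feats[names(grl)] <- grl
  }
  log$n_missing <- sum(is.na(feats))
  attr(feats, "log") <- log
  feats
}

#' Feature table for an in-memory cohort
#'
#' @param cohort List of `list(slices =, label =)` as returned by
#'   [generate_cohort()].
#' @param config A [pipeline_config()].
#' @return List with `features` (subjects x 52 matrix, rownames = subject
#'   ids), `labels` (integer vector or `NULL`) and `logs`.
#' @export
cohort_features <- function(cohort, config = pipeline_config()) {
  rows <- lapply(cohort, function(s) subject_features(s$slices, config))
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(cohort, function(s) s$slices$subject_id, "")
  labels <- vapply(cohort, function(s) {
    if (is.null(s$label)) NA_integer_ else as.integer(s$label)
  }, 0L)
  list(features = features,
       labels = if (all(is.na(labels))) NULL else labels,
       logs = lapply(rows, attr, "log"))
}

#' Run the full pipeline over a cohort manifest
#'
#' Reads every subject listed in the manifest, extracts the 52 features,
#' writes the feature table, a JSON-lines log and the materialized
#' configuration to `out_dir`, and — when a binary `label` column with
#' both classes present is available — runs the cross-validated
#' random-forest evaluation and writes its report and ROC curve.
#' Per-subject failures are logged and produce rows of missing values,
#' not a pipeline failure.
#'
#' @param manifest Path to a cohort CSV (columns `subject_id`, `t1c`,
#'   `flair`, `roi_t1`, `roi_flair`, optional `label`) or an equivalent
#'   data.frame, or an in-memory cohort list.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, list with `features`, `labels`, `report` (or
#'   `NULL`) and output `paths`.
#' @export
run_pipeline <- function(manifest, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (is.list(manifest) && !is.data.frame(manifest)) {
    manifest
  } else {
    tbl <- if (is.character(manifest)) {
      utils::read.csv(manifest, stringsAsFactors = FALSE)
    } else manifest
    lapply(seq_len(nrow(tbl)), function(r) {
      slices <- tryCatch(
        read_subject(as.list(tbl[r, c("t1c", "flair", "roi_t1", "roi_flair")]),
                     slice_selection = config$slice_selection,
                     subject_id = tbl$subject_id[r]),
        habitatgraph_error = function(e) e)
      list(slices = slices,
           label = if ("label" %in% names(tbl)) tbl$label[r] else NULL)
    })
  }
  # subjects whose files could not be read become all-missing rows
  readable <- vapply(cohort, function(s) inherits(s$slices, "slice_pair"),
                     TRUE)
  res <- cohort_features(cohort[readable], config)
  features <- matrix(NA_real_, length(cohort), 52,
                     dimnames = list(
                       vapply(seq_along(cohort), function(k) {
                         s <- cohort[[k]]
                         if (inherits(s$slices, "slice_pair")) {
                           s$slices$subject_id
                         } else sprintf("unreadable_%d", k)
                       }, ""),
                       feature_names()))
  features[readable, ] <- res$features
  labels <- res$labels

  paths <- list(features = file.path(out_dir, "features.csv"),
                config = file.path(out_dir, "config.json"),
                log = file.path(out_dir, "log.jsonl"))
  utils::write.csv(data.frame(subject_id = rownames(features), features,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   paths$features, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  writeLines(vapply(res$logs, function(l) {
    jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA)
  }, ""), paths$log)

  report <- NULL
  if (!is.null(labels) && length(unique(labels[readable])) == 2) {
    report <- tryCatch(
      evaluate_features(res$features, labels,
                        n_trees = config$rf_trees,
                        k = config$cv_folds, seed = config$rf_seed),
      habitatgraph_error = function(e) {
        warning("classification skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  if (!is.null(report)) {
    paths$report <- file.path(out_dir, "report.json")
    paths$roc <- file.path(out_dir, "roc.csv")
    jsonlite::write_json(
      list(auc = report$auc, tpr = report$tpr, tnr = report$tnr,
           acc = report$acc, mae = report$mae, cutoff = report$cutoff,
           fold_assignments = report$fold, seed = report$seed,
           importance = as.list(report$importance)),
      paths$report, auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$roc, paths$roc, row.names = FALSE)
  }
  invisible(list(features = features, labels = labels, report = report,
                 paths = paths))
}
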