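# End-to-end pipeline configuration and driver.

.run_config_defaults <- function() {
  list(
    version = "1",
    seed = 1L,
    n_green = 44L, n_yellow = 43L, n_red = 56L,
    n_frames = 16L,
    n_alines = 256L, n_depth_px = 256L,
    aline_count = 100L,
    offset_px = 10L, window_um = 320,
    smooth_width_px = 5L,
    roi_width_px = 200L, roi_height_px = 200L,
    glcm_levels = 64L, glcm_distance = 1L,
    knn_k = 5L, cv_scheme = "loocv",
    feature_set = c("energy", "inverse_difference_moment",
                    "skewness", "sum_variance"),
    chlorophyll_wavelengths_nm = c(645, 663),
    chlorophyll_coefficients = c(20.2, 8.02)
  )
}

#' Declarative configuration of a full pipeline run
#'
#' All module defaults (geometry, fit window, GLCM parameters, classifier
#' settings, coefficient sets) in one document; unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see `leafoct:::.run_config_defaults`).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- .run_config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown run_config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full phantom analysis pipeline
#'
#' Simulates the labeled cohort, estimates the attenuation coefficient of
#' every sample, extracts the texture feature table, cross-validates the
#' k-NN stager, and writes per-stage group summaries with pairwise t-tests —
#' all into `out_dir` (attenuation.csv, features.csv, classification.json,
#' stats_attenuation.csv, stats_features.csv, run_config.json, run.log).
#' A fixed seed makes the run fully reproducible.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return list with the in-memory results (`attenuation`, `features`,
#'   `classification`, `stats`), invisibly.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                    sprintf(...)), file = log_path, append = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("simulating %d/%d/%d samples at %dx%d px, seed %d",
       config$n_green, config$n_yellow, config$n_red,
       config$n_depth_px, config$n_alines, config$seed)
  dataset <- generate_labeled_dataset(config$n_green, config$n_yellow,
                                      config$n_red, seed = config$seed,
                                      n_frames = config$n_frames,
                                      n_alines = config$n_alines,
                                      n_depth_px = config$n_depth_px)
  labels <- dataset_labels(dataset)

  att <- lapply(seq_along(dataset), function(i) {
    fit <- tryCatch(
      estimate_attenuation(dataset[[i]], n_alines = config$aline_count,
                           offset_px = config$offset_px,
                           window_um = config$window_um,
                           smooth_width_px = config$smooth_width_px),
      error = function(e) {
        logf("attenuation failed for sample %d: %s", i, conditionMessage(e))
        NULL
      })
    data.frame(sample_id = i, label = labels[i],
               slope_db_per_um = fit$slope_db_per_um %||% NA_real_,
               intercept_db = fit$intercept_db %||% NA_real_,
               r_squared = fit$r_squared %||% NA_real_,
               n_points = fit$n_points %||% NA_integer_)
  })
  att <- do.call(rbind, att)
  utils::write.csv(att, file.path(out_dir, "attenuation.csv"), row.names = FALSE)

  logf("extracting texture features")
  tcfg <- texture_config(levels = config$glcm_levels,
                         distance = config$glcm_distance)
  feats <- batch_features(dataset, config = tcfg,
                          width_px = config$roi_width_px,
                          height_px = config$roi_height_px)
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)

  logf("cross-validating k-NN (k = %d, %s)", config$knn_k, config$cv_scheme)
  ok <- stats::complete.cases(feats[, config$feature_set, drop = FALSE])
  res <- cross_validate(feats[ok, ], labels[ok], k = config$knn_k,
                        scheme = config$cv_scheme, seed = config$seed,
                        features = config$feature_set)
  jsonlite::write_json(
    list(confusion = as.matrix(unclass(res$confusion)),
         accuracy = res$accuracy,
         macro_sensitivity = res$macro_sensitivity,
         macro_specificity = res$macro_specificity,
         auc = res$roc$auc, k = res$k, cv_scheme = res$cv_scheme),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$roc$points, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)

  logf("group statistics")
  stage_stats <- function(values, labels) {
    by_stage <- split(values, labels)[c("green", "yellow", "red")]
    summ <- do.call(rbind, lapply(names(by_stage), function(s)
      data.frame(stage = s, as.list(group_summary(by_stage[[s]])))))
    cbind_rows <- stage_change_report(by_stage)
    list(summary = summ, changes = cbind_rows)
  }
  att_stats <- stage_stats(att$slope_db_per_um, att$label)
  utils::write.csv(cbind(quantity = "slope_db_per_um", att_stats$summary),
                   file.path(out_dir, "stats_attenuation.csv"), row.names = FALSE)
  feat_stats <- do.call(rbind, lapply(config$feature_set, function(f) {
    st <- stage_stats(feats[[f]], feats$label)
    cbind(feature = f, st$changes)
  }))
  utils::write.csv(feat_stats, file.path(out_dir, "stats_features.csv"),
                   row.names = FALSE)
  logf("done")
  invisible(list(attenuation = att, features = feats, classification = res,
                 stats = list(attenuation = att_stats, features = feat_stats)))
}
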