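#' Normalise one subject and extract its radiomic features
#'
#' Resamples the rCBV map (trilinear) and both masks (nearest-neighbour) to
#' isotropic spacing, sanitizes the reference region to the tumour-free
#' hemisphere, z-scores the map against it, and extracts the requested
#' feature groups over the tumour mask.
#'
#' @param case A `subject_case`.
#' @param iso_mm Target isotropic spacing (mm), default 1.
#' @param n_bins Grey levels for texture quantization.
#' @param groups Feature groups to extract.
#' @return Named numeric feature vector.
#' @export
process_case <- function(case, iso_mm = 1.0, n_bins = 32L,
                         groups = c("shape", "histogram", "texture")) {
  rcbv <- resample_isotropic(case$rcbv, iso_mm, "trilinear")
  tmask <- resample_isotropic(case$tumour_mask, iso_mm, "nearest")
  ref <- resample_isotropic(case$reference_mask, iso_mm, "nearest")
  clean <- sanitize_reference(ref, tmask, case$tumour_hemisphere)
  z <- zscore_normalise(rcbv, tmask, clean)
  tryCatch(extract_features(z, tmask, n_bins = n_bins, groups = groups),
           error = function(e) stop("subject '", case$subject_id, "': ",
                                    conditionMessage(e)))
}

#' Feature table for a whole cohort
#'
#' @param cohort Output of [generate_cohort()] (or a compatible list with
#'   `cases` and `manifest`).
#' @param iso_mm,n_bins,groups Passed to [process_case()].
#' @return data.frame: manifest columns followed by feature columns.
#' @export
extract_cohort <- function(cohort, iso_mm = 1.0, n_bins = 32L,
                           groups = c("shape", "histogram", "texture")) {
  fmat <- do.call(rbind, lapply(cohort$cases, process_case,
                                iso_mm = iso_mm, n_bins = n_bins,
                                groups = groups))
  cbind(cohort$manifest, as.data.frame(fmat))
}

feature_cols <- function(df) df[, intersect(feature_names(), names(df)),
                                drop = FALSE]

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> normalise -> extract -> covariate correction ->
#' group comparison -> random-forest classification (both tasks) ->
#' error-by-parameter analysis -> misclassification introspection, writing
#' every table under `out_dir`. A rerun with the same configuration
#' reproduces all CSV/JSON outputs byte-identically.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param iso_mm,n_bins Normalisation / quantization settings.
#' @param correct_shape Whether shape features are covariate-corrected too.
#' @param n_repeats CV repeats for both tasks (default 250).
#' @param write_volumes Also write per-subject NIfTI files (default FALSE).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir, iso_mm = 1.0, n_bins = 32L,
                         correct_shape = TRUE, n_repeats = 250L,
                         write_volumes = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  # stage-labelled failure; the log and any outputs written so far survive
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfg_file <- tempfile(); saveRDS(config, cfg_file, version = 2)
  say("config md5: %s", unname(tools::md5sum(cfg_file)))
  unlink(cfg_file)
  say("master seed: %d", config$seed)
  say("cohort: n = %d, grid = %s @ %s mm, centres = %d",
      config$n_subjects, paste(config$grid_shape, collapse = "x"),
      paste(config$voxel_spacing_mm, collapse = "x"), config$n_centres)

  cohort <- stage("simulate", generate_cohort(config))
  wcsv(cohort$manifest, "manifest.csv")
  if (write_volumes) write_cohort(cohort, file.path(out_dir, "volumes"))
  say("stage simulate: %d cases", length(cohort$cases))

  feats <- stage("extract", extract_cohort(cohort, iso_mm = iso_mm, n_bins = n_bins))
  wcsv(feats, "features.csv")
  say("stage extract: %d features per subject", ncol(feature_cols(feats)))

  fx <- feature_cols(feats)
  withCallingHandlers(
    fx_corr <- stage("correct",
                     residualize(fx, cohort$manifest,
                                 correct_shape = correct_shape)),
    warning = function(w) {
      say("stage correct [warning]: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  wcsv(cbind(cohort$manifest[, c("subject_id", "grade", "idh")], fx_corr),
       "features_corrected.csv")

  comparisons <- stage("compare", compare_all_groups(fx_corr, cohort$manifest))
  wcsv(comparisons, "comparisons.csv")
  say("stage compare: %d significant of %d tests",
      sum(comparisons$significant), nrow(comparisons))

  metrics <- list(seed = config$seed, n_subjects = config$n_subjects,
                  n_repeats = as.integer(n_repeats))
  results <- list(cohort = cohort, features = feats, corrected = fx_corr,
                  comparisons = comparisons)
  for (task in c("idh", "grade")) {
    settings <- rf_settings(task, n_repeats = n_repeats,
                            master_seed = config$seed)
    labels <- if (task == "idh") cohort$manifest$idh else cohort$manifest$grade
    cv <- stage(paste0("classify-", task),
                repeated_stratified_cv(fx, labels, settings,
                                       manifest = cohort$manifest))
    cs <- consensus_confusion(cv)
    wcsv(as.data.frame.matrix(cs$confusion), paste0("confusion_", task, ".csv"))
    wcsv(data.frame(subject_id = cohort$manifest$subject_id,
                    truth = as.character(labels),
                    consensus = cs$consensus,
                    round(cv$votes, 6)),
         paste0("predictions_", task, ".csv"))
    ebp <- withCallingHandlers(
      error_by_parameter(cv, cohort$manifest),
      warning = function(w) {
        say("stage error-by-parameter [warning]: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    wcsv(ebp, paste0("error_by_parameter_", task, ".csv"))
    contrasts <- withCallingHandlers(
      misclassification_contrast(fx_corr, cs$consensus, as.character(labels)),
      warning = function(w) {
        say("stage introspect [warning]: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    wcsv(contrasts, paste0("contrasts_", task, ".csv"))
    metrics[[task]] <- c(list(accuracy = cs$accuracy),
                         if (task == "idh")
                           list(sensitivity = cs$sensitivity,
                                specificity = cs$specificity)
                         else list(within_distance_1 = cs$within_distance_1))
    say("stage classify [%s]: accuracy %.3f", task, cs$accuracy)
    results[[paste0("cv_", task)]] <- cv
    results[[paste0("confusion_", task)]] <- cs
    results[[paste0("contrasts_", task)]] <- contrasts
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  results$metrics <- metrics
  invisible(results)
}
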