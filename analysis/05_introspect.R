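#!/usr/bin/env Rscript
# Misclassification introspection: for every error category (e.g. true
# grade II predicted grade IV), contrast the covariate-corrected features
# of the misclassified subjects against their correctly classified
# counterparts, as cohort z-scores.

source("analysis/00_config.R")

corrected <- read.csv(file.path(RESULTS_DIR, "features_corrected.csv"))
fx <- corrected[, feature_names()]

for (task in c("idh", "grade")) {
  preds <- read.csv(file.path(RESULTS_DIR,
                              paste0("predictions_", task, ".csv")))
  stopifnot(identical(preds$subject_id, corrected$subject_id))
  contrasts <- suppressWarnings(
    misclassification_contrast(fx, as.character(preds$consensus),
                               as.character(preds$truth)))
  out <- file.path(RESULTS_DIR, paste0("contrasts_", task, ".csv"))
  write.csv(contrasts, out, row.names = FALSE)
  cat("\n==", task, "task:", length(unique(contrasts$error_category)),
      "error categories with enough subjects ->", out, "==\n")
  if (nrow(contrasts) > 0) {
    for (cat_nm in unique(contrasts$error_category)) {
      sub <- contrasts[contrasts$error_category == cat_nm, ]
      sig <- sub[sub$p_value <= 0.05, ]
      cat(sprintf("  %-18s (n=%d): %d/%d features differ at p <= 0.05\n",
                  cat_nm, sub$n_error[1], nrow(sig), nrow(sub)))
      if (nrow(sig) > 0) {
        top <- sig[order(-abs(sig$mean_z_diff)), ][seq_len(min(3, nrow(sig))), ]
        for (i in seq_len(nrow(top)))
          cat(sprintf("      %-20s mean z-diff %+.2f (p = %.3f)\n",
                      top$feature[i], top$mean_z_diff[i], top$p_value[i]))
      }
    }
  } else {
    cat("  no misclassification category large enough to contrast\n")
  }
}
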