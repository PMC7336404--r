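#!/usr/bin/env Rscript
# Correct the feature table for acquisition covariates, age and sex, then
# compare groups (IDH status and each grade pair) with the two-sample
# rank-sum test and Cliff's delta.

source("analysis/00_config.R")

features <- read.csv(file.path(RESULTS_DIR, "features.csv"))
fx <- features[, feature_names()]
fx_corr <- residualize(fx, features)
write.csv(cbind(features[, c("subject_id", "grade", "idh")], fx_corr),
          file.path(RESULTS_DIR, "features_corrected.csv"), row.names = FALSE)

comparisons <- compare_all_groups(fx_corr, features)
out <- file.path(RESULTS_DIR, "comparisons.csv")
write.csv(comparisons, out, row.names = FALSE)
cat("Wrote", out, "\n\n")

for (ctr in unique(comparisons$contrast)) {
  sub <- comparisons[comparisons$contrast == ctr, ]
  cat(sprintf("%-14s %2d of %2d features significant (p <= 0.05)\n",
              ctr, sum(sub$significant), nrow(sub)))
}
cat("\nLargest IDH effect sizes (|Cliff's delta|):\n")
idh <- comparisons[comparisons$contrast == "wt_vs_mutant", ]
top <- idh[order(-abs(idh$cliffs_delta)), ][1:5, ]
print(top[, c("feature", "median_a", "median_b", "p_value", "cliffs_delta")],
      row.names = FALSE, digits = 3)
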