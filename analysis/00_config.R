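# Shared settings for the analysis scripts. Sourced by 01-05.
#
# The study conditions: a 60-subject, 2-centre synthetic cohort on a 64^3
# 1 mm grid with the default class effects (IDH-mutant: lower mean rCBV,
# higher skew, smoother shapes; higher grades: higher mean, heterogeneity
# and boundary irregularity), classified with 2-fold CV x 250 repeats.

suppressPackageStartupMessages(library(dscradiomics))

MASTER_SEED <- 20260921L
COHORT_DIR <- "results/cohort"
RESULTS_DIR <- "results"
N_REPEATS <- 250L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function(seed = MASTER_SEED) {
  cohort_config(n_subjects = 60, seed = seed)
}
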