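#' Contrast features between misclassified and correctly classified subjects
#'
#' For each misclassification category (truth = a, consensus prediction = b,
#' a != b) with at least `min_n` members whose correctly classified
#' counterpart (truth = a, prediction = a by default) also has at least
#' `min_n` members, every feature is contrasted between the two groups:
#' features are first standardized to cohort-wide z-scores (mean 0, sd 1 per
#' feature over all subjects), then the mean z-score difference
#' (error group minus correct group) and a two-sided Mann-Whitney p-value
#' are reported. With `reference = "predicted"` the comparison group is
#' instead the correctly classified subjects of the predicted class b.
#'
#' @param features data.frame of (residualized) feature columns.
#' @param predictions Consensus predicted labels, aligned with rows.
#' @param truth True labels, aligned with rows.
#' @param reference "true" (default): correct subjects of the true class;
#'   "predicted": correct subjects of the predicted class.
#' @param min_n Minimum group size (default 2); smaller categories are
#'   skipped with a warning.
#' @return data.frame with columns `error_category`, `truth`, `predicted`,
#'   `feature`, `n_error`, `n_correct`, `mean_z_diff`, `p_value`. Empty (0
#'   rows) when there are no misclassifications.
#' @export
misclassification_contrast <- function(features, predictions, truth,
                                       reference = c("true", "predicted"),
                                       min_n = 2L) {
  reference <- match.arg(reference)
  features <- as.data.frame(features)
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  stopifnot(nrow(features) == length(predictions),
            length(predictions) == length(truth))
  z <- as.data.frame(scale(features))           # cohort z-scores per feature
  z[vapply(z, function(x) any(!is.finite(x)), TRUE)] <- 0  # constant features
  correct <- predictions == truth
  cats <- unique(data.frame(truth = truth, predicted = predictions,
                            stringsAsFactors = FALSE)[!correct, , drop = FALSE])
  rows <- list()
  if (nrow(cats) > 0) for (ci in seq_len(nrow(cats))) {
    a <- cats$truth[ci]; b <- cats$predicted[ci]
    err_idx <- which(truth == a & predictions == b)
    ref_class <- if (reference == "true") a else b
    cor_idx <- which(truth == ref_class & correct)
    if (length(err_idx) < min_n || length(cor_idx) < min_n) {
      warning("category ", a, "->", b, " skipped (error n = ",
              length(err_idx), ", correct n = ", length(cor_idx), ")")
      next
    }
    for (fn in names(z)) {
      ze <- z[[fn]][err_idx]; zc <- z[[fn]][cor_idx]
      rows[[length(rows) + 1L]] <- data.frame(
        error_category = paste0(a, "->", b), truth = a, predicted = b,
        feature = fn, n_error = length(err_idx), n_correct = length(cor_idx),
        mean_z_diff = mean(ze) - mean(zc),
        p_value = mann_whitney(ze, zc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(error_category = character(0), truth = character(0),
                      predicted = character(0), feature = character(0),
                      n_error = integer(0), n_correct = integer(0),
                      mean_z_diff = numeric(0), p_value = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
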