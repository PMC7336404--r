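#' Random-forest settings for a stratification task
#'
#' Defaults follow the tuned per-task values: the binary IDH task uses 200
#' trees, maximum depth 10, minimum 4 samples per leaf; the 3-class grade
#' task uses 800 trees, maximum depth 50, minimum 4 samples per leaf. Both
#' run stratified 2-fold cross-validation repeated 250 times.
#'
#' @param task "idh" or "grade".
#' @param n_trees,max_depth,min_samples_leaf Forest hyperparameters.
#' @param n_repeats,n_folds Cross-validation scheme.
#' @param master_seed Seed from which all per-repeat/per-fold seeds derive.
#' @return An `rf_settings` list.
#' @export
rf_settings <- function(task = c("idh", "grade"),
                        n_trees = NULL, max_depth = NULL,
                        min_samples_leaf = 4L,
                        n_repeats = 250L, n_folds = 2L,
                        master_seed = 1L) {
  task <- match.arg(task)
  if (is.null(n_trees)) n_trees <- if (task == "idh") 200L else 800L
  if (is.null(max_depth)) max_depth <- if (task == "idh") 10L else 50L
  structure(list(task = task, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 master_seed = as.integer(master_seed)),
            class = "rf_settings")
}

# Stratified fold assignment: within each class, shuffle subjects and deal
# them to folds cyclically, so per-fold class counts differ by at most 1.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Ordinal numeric encoding used for the prediction-error metric.
encode_label <- function(labels, task) {
  if (task == "grade") as.numeric(as.character(labels))
  else ifelse(as.character(labels) == "mutant", 1, 0)
}

#' Repeated stratified cross-validated random-forest classification
#'
#' Per repeat: a stratified `n_folds`-fold split; a probability forest is
#' trained on each training fold and class-vote proportions recorded for the
#' held-out subjects, so every subject is predicted exactly once per repeat.
#' Acquisition covariates (dichotomized, indicator-coded), age and sex are
#' appended to the radiomic features as classifier inputs when a manifest is
#' supplied. The numeric error is predicted minus true on the ordinal
#' encoding (grade II/III/IV as 2/3/4; IDH wildtype/mutant as 0/1).
#'
#' @param features data.frame/matrix of radiomic features (subjects in rows).
#' @param labels Class labels (grade in {2,3,4} or idh in
#'   {mutant, wildtype}).
#' @param settings An [rf_settings()] object.
#' @param manifest Optional manifest of acquisition covariates to append as
#'   model inputs.
#' @return A `cv_result`: `votes` (n_subjects x n_classes mean vote matrix),
#'   `pred` (n_repeats x n_subjects predicted ordinal codes), `errors`
#'   (same shape, predicted - true), `classes`, `labels`, `settings`.
#' @export
repeated_stratified_cv <- function(features, labels, settings,
                                   manifest = NULL) {
  X <- as.data.frame(features)
  if (!all(vapply(X, is.numeric, TRUE))) stop("features must be numeric")
  if (any(!is.finite(as.matrix(X)))) stop("features must be finite")
  labels <- factor(labels)
  n <- nrow(X)
  if (length(labels) != n) stop("labels/features length mismatch")
  tab <- table(labels)
  if (any(tab < 2L * settings$n_folds))
    stop("every class needs at least ", 2L * settings$n_folds,
         " subjects for stratified ", settings$n_folds, "-fold CV; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  if (!is.null(manifest)) {
    cov <- dichotomize_covariates(manifest)
    cov <- cov[, vapply(cov, function(x) length(unique(x)) > 1L, TRUE),
               drop = FALSE]
    if (ncol(cov) > 0) {
      mm <- stats::model.matrix(~ . - 1, data = cov)
      colnames(mm) <- make.names(colnames(mm))
      X <- cbind(X, as.data.frame(mm))
    }
  }
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  classes <- levels(labels)
  k <- length(classes)
  code <- encode_label(classes, settings$task)
  true_code <- code[as.integer(labels)]

  vote_sum <- matrix(0, n, k, dimnames = list(NULL, classes))
  pred <- matrix(NA_real_, settings$n_repeats, n)
  dat <- cbind(X, .y = labels)
  for (r in seq_len(settings$n_repeats)) {
    set.seed(subject_seed(settings$master_seed, 7919L + r))
    fold <- stratified_folds(labels, settings$n_folds)
    prob <- matrix(NA_real_, n, k, dimnames = list(NULL, classes))
    for (f in seq_len(settings$n_folds)) {
      tr <- fold != f; te <- fold == f
      fit <- ranger::ranger(
        dependent.variable.name = ".y",
        data = dat[tr, , drop = FALSE],
        num.trees = settings$n_trees,
        max.depth = settings$max_depth,
        min.node.size = settings$min_samples_leaf,
        probability = TRUE,
        num.threads = 1L,
        seed = subject_seed(settings$master_seed, 104729L + r * 10L + f))
      p <- stats::predict(fit, dat[te, , drop = FALSE],
                          num.threads = 1L)$predictions
      prob[te, colnames(p)] <- p
    }
    vote_sum <- vote_sum + prob
    pred[r, ] <- code[max.col(prob, ties.method = "first")]
  }
  structure(list(votes = vote_sum / settings$n_repeats,
                 pred = pred,
                 errors = sweep(pred, 2, true_code),
                 classes = classes, class_code = code,
                 labels = labels, true_code = true_code,
                 settings = settings),
            class = "cv_result")
}

#' Consensus confusion matrix and summary rates
#'
#' A subject's consensus label is the class with the highest mean vote
#' proportion across all repeats (ties to the lower ordinal class). Reports
#' the consensus-vs-truth confusion matrix (rows = truth), overall accuracy,
#' and, for the binary task, sensitivity and specificity with IDH-mutant as
#' the positive class; for the grade task, the fraction of subjects whose
#' consensus grade is within one grade of the truth.
#'
#' @param result A `cv_result`.
#' @return A `confusion_summary` list.
#' @export
consensus_confusion <- function(result) {
  v <- result$votes
  # ties broken toward the lower ordinal class: scan columns in code order
  ord <- order(result$class_code)
  consensus_idx <- apply(v[, ord, drop = FALSE], 1, which.max)  # first max
  consensus <- result$classes[ord][consensus_idx]
  truth <- as.character(result$labels)
  cm <- table(truth = factor(truth, levels = result$classes),
              predicted = factor(consensus, levels = result$classes))
  acc <- sum(diag(cm)) / sum(cm)
  out <- list(confusion = cm, accuracy = acc, consensus = consensus)
  if (result$settings$task == "idh") {
    pos <- "mutant"; neg <- "wildtype"
    tp <- cm[pos, pos]; fn <- sum(cm[pos, ]) - tp
    tn <- cm[neg, neg]; fp <- sum(cm[neg, ]) - tn
    out$sensitivity <- tp / (tp + fn)
    out$specificity <- tn / (tn + fp)
  } else {
    pc <- result$class_code[match(consensus, result$classes)]
    tc <- result$true_code
    out$within_distance_1 <- mean(abs(pc - tc) <= 1)
  }
  structure(out, class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Consensus confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat(sprintf("accuracy = %.3f\n", x$accuracy))
  if (!is.null(x$sensitivity))
    cat(sprintf("sensitivity = %.3f, specificity = %.3f\n",
                x$sensitivity, x$specificity))
  if (!is.null(x$within_distance_1))
    cat(sprintf("within-1-grade fraction = %.3f\n", x$within_distance_1))
  invisible(x)
}

#' Prediction error by acquisition parameter
#'
#' For each dichotomized acquisition parameter, compares per-subject mean
#' signed error and mean absolute error (averaged over repeats) between the
#' parameter's bins with Welch's two-sample t-test. Parameters with fewer
#' than 2 subjects in a bin are skipped with a warning. Three-level
#' parameters (in-plane resolution) are compared over their two most
#' populated bins.
#'
#' @param result A `cv_result`.
#' @param manifest Manifest aligned with the subjects.
#' @return data.frame: parameter, bins, per-bin mean error and mean |error|,
#'   Welch p-values for both.
#' @export
error_by_parameter <- function(result, manifest) {
  cov <- dichotomize_covariates(manifest)
  cov$age <- NULL; cov$sex <- NULL
  mean_err <- colMeans(result$errors)
  mean_abs <- colMeans(abs(result$errors))
  rows <- list()
  for (par in names(cov)) {
    f <- droplevels(cov[[par]])
    lv <- names(sort(table(f), decreasing = TRUE))
    if (length(lv) < 2L) { warning("parameter '", par, "' has one bin; skipped"); next }
    lv <- sort(lv[1:2])
    ia <- which(f == lv[1]); ib <- which(f == lv[2])
    if (length(ia) < 2L || length(ib) < 2L) {
      warning("parameter '", par, "' has a bin with < 2 subjects; skipped")
      next
    }
    welch_p <- function(x, y) {
      if (isTRUE(all.equal(var(c(x, y)), 0))) return(1)
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    }
    rows[[par]] <- data.frame(
      parameter = par, bin_a = lv[1], bin_b = lv[2],
      n_a = length(ia), n_b = length(ib),
      mean_error_a = mean(mean_err[ia]), mean_error_b = mean(mean_err[ib]),
      mean_abs_error_a = mean(mean_abs[ia]),
      mean_abs_error_b = mean(mean_abs[ib]),
      p_error = welch_p(mean_err[ia], mean_err[ib]),
      p_abs_error = welch_p(mean_abs[ia], mean_abs[ib]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
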