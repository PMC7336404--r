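#' Dichotomize acquisition covariates into standard bins
#'
#' Bins: field strength {1.5, 3} T; TR <=1499 / >=1500 ms; TE 25-44 / 45-55
#' ms; FA 90 / <90 degrees; slice thickness <5 / >=5 mm; matrix <128 /
#' >=128; in-plane resolution <=1 / (1,2) / >=2 mm. Manufacturer stays
#' categorical; centre is carried through as a factor.
#'
#' @param manifest data.frame with columns `field_T`, `TR_ms`, `TE_ms`,
#'   `FA_deg`, `slice_mm`, `matrix_size`, `inplane_mm`, `manufacturer`
#'   (and optionally `centre`, `age`, `sex`).
#' @return data.frame of factors (plus numeric `age` if present), one row
#'   per subject.
#' @export
dichotomize_covariates <- function(manifest) {
  out <- data.frame(row.names = seq_len(nrow(manifest)))
  has <- function(col) !is.null(manifest[[col]])
  if (has("manufacturer")) out$manufacturer <- factor(manifest$manufacturer)
  if (has("field_T"))
    out$field <- factor(ifelse(manifest$field_T >= 3, "3T", "1.5T"))
  if (has("TR_ms"))
    out$tr <- factor(ifelse(manifest$TR_ms <= 1499, "le1499", "ge1500"))
  if (has("TE_ms"))
    out$te <- factor(ifelse(manifest$TE_ms <= 44, "25-44", "45-55"))
  if (has("FA_deg"))
    out$fa <- factor(ifelse(manifest$FA_deg >= 90, "90", "lt90"))
  if (has("slice_mm"))
    out$slice <- factor(ifelse(manifest$slice_mm < 5, "lt5", "ge5"))
  if (has("matrix_size"))
    out$matrix <- factor(ifelse(manifest$matrix_size < 128, "lt128", "ge128"))
  if (has("inplane_mm"))
    out$inplane <- factor(ifelse(manifest$inplane_mm <= 1, "le1",
                          ifelse(manifest$inplane_mm < 2, "1to2", "ge2")),
                          levels = c("le1", "1to2", "ge2"))
  if (!is.null(manifest$centre)) out$centre <- factor(manifest$centre)
  if (!is.null(manifest$age)) out$age <- as.numeric(manifest$age)
  if (!is.null(manifest$sex)) out$sex <- factor(manifest$sex)
  droplevels(out)
}

#' Residualize features on acquisition covariates, age and sex
#'
#' Each feature is regressed by ordinary least squares on the dichotomized
#' acquisition covariates (indicator coding), manufacturer, age (continuous)
#' and sex, and replaced by the model residuals, which have mean zero over
#' the fitting cohort. Constant or aliased design columns are dropped by the
#' fit (with a warning for constant covariates). Shape features can be
#' exempted from correction; the default corrects all features.
#'
#' @param features data.frame/matrix of feature columns (subjects in rows).
#' @param manifest data.frame of raw covariates (see
#'   [dichotomize_covariates()]); rows aligned with `features`.
#' @param correct_shape If `FALSE`, shape features pass through uncorrected.
#' @return data.frame of residualized features, same shape and names.
#' @export
residualize <- function(features, manifest, correct_shape = TRUE) {
  features <- as.data.frame(features)
  cov <- dichotomize_covariates(manifest)
  constant <- vapply(cov, function(x) length(unique(x)) < 2L, TRUE)
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(cov)[constant], collapse = ", "))
    cov <- cov[, !constant, drop = FALSE]
  }
  if (ncol(cov) == 0L) stop("no usable covariates")
  X <- stats::model.matrix(~ ., data = cov)
  if (nrow(X) <= qr(X)$rank)
    stop("need more subjects than model parameters to residualize")
  skip <- if (correct_shape) character(0) else
    intersect(names(features), feature_names("shape"))
  out <- features
  fit0 <- stats::lm.fit(X, as.matrix(features[, setdiff(names(features), skip),
                                              drop = FALSE]))
  out[, setdiff(names(features), skip)] <- fit0$residuals
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null distribution when the pooled sample has at most 12 untied
#' values; otherwise the normal approximation with mid-ranks and tie
#' correction. Two samples sharing a single common value give p = 1.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- any(duplicated(pooled))
  exact <- !ties && length(pooled) <= 12L
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}

#' Cliff's delta effect size
#'
#' `delta = (#[a_i > b_j] - #[a_i < b_j]) / (n_a * n_b)`, in [-1, 1];
#' positive when the first sample is stochastically larger. Invariant under
#' strictly monotone transforms of both samples; antisymmetric in its
#' arguments.
#'
#' @param a,b Numeric samples.
#' @return Cliff's delta.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  # rank-based O((n+m) log(n+m)) evaluation of the pair counts
  r <- rank(c(a, b))
  ra <- r[seq_along(a)]
  n_a <- length(a); n_b <- length(b)
  # sum of ranks of a = #{a>b} + #{a<b}/0 ... use dominance via ranks with ties:
  # U = sum(ra) - n_a(n_a+1)/2 counts pairs a>b as 1 and ties as 1/2
  U <- sum(ra) - n_a * (n_a + 1) / 2
  (2 * U - n_a * n_b) / (n_a * n_b)
}

#' Feature-wise group comparison (medians, IQRs, Mann-Whitney p, Cliff's delta)
#'
#' Reproduces the group-comparison table layout: for each feature, the
#' median and IQR per group, the two-sided Mann-Whitney p-value and Cliff's
#' delta for the pair. Delta is oriented so that a positive value means the
#' first group is stochastically larger; p-values are unadjusted with
#' significance flagged at p <= 0.05.
#'
#' @param features data.frame of (typically residualized) feature columns.
#' @param group Vector of group labels aligned with rows.
#' @param pair Character vector of 2: which groups to compare, in order.
#' @return data.frame with one row per feature.
#' @export
group_compare <- function(features, group, pair) {
  features <- as.data.frame(features)
  group <- as.character(group)
  stopifnot(length(pair) == 2L)
  ia <- which(group == pair[1]); ib <- which(group == pair[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 subjects per group (", pair[1], ": ", length(ia), ", ",
         pair[2], ": ", length(ib), ")")
  res <- lapply(names(features), function(fn) {
    a <- features[[fn]][ia]; b <- features[[fn]][ib]
    data.frame(feature = fn, group_a = pair[1], group_b = pair[2],
               median_a = stats::median(a), iqr_a = stats::IQR(a),
               median_b = stats::median(b), iqr_b = stats::IQR(b),
               p_value = mann_whitney(a, b),
               cliffs_delta = cliffs_delta(a, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value <= 0.05
  out
}

#' All standard group comparisons of a cohort feature table
#'
#' Runs [group_compare()] for IDH status (wildtype vs mutant) and the three
#' grade pairs (II vs III, II vs IV, III vs IV), mirroring the standard
#' contrast layout.
#'
#' @param features Residualized feature data.frame.
#' @param manifest Manifest with `idh` and `grade` columns, rows aligned.
#' @return data.frame stacking all four comparisons with a `contrast` column.
#' @export
compare_all_groups <- function(features, manifest) {
  cmp <- list(
    wt_vs_mutant = group_compare(features, manifest$idh,
                                 c("wildtype", "mutant")),
    II_vs_III = group_compare(features, manifest$grade, c("2", "3")),
    II_vs_IV = group_compare(features, manifest$grade, c("2", "4")),
    III_vs_IV = group_compare(features, manifest$grade, c("3", "4")))
  out <- do.call(rbind, Map(function(d, nm) {
    d$contrast <- nm; d
  }, cmp, names(cmp)))
  rownames(out) <- NULL
  out
}
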