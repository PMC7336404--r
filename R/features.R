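#' Canonical radiomic feature names
#'
#' The 29 features the pipeline extracts, by group: 4 shape, 13 histogram,
#' 12 Haralick texture. Column order of every feature table in the package.
#'
#' @param group Optionally restrict to "shape", "histogram" or "texture".
#' @return Character vector of feature names.
#' @export
feature_names <- function(group = c("all", "shape", "histogram", "texture")) {
  group <- match.arg(group)
  shape <- c("volume_mm3", "surface_mm2", "sav", "non_compactness")
  hist <- c("mean", "skewness", "kurtosis", "std", "min", "max",
            "p1", "p5", "p25", "p50", "p75", "p95", "p99")
  tex <- c("asm", "contrast", "correlation", "sum_square", "sum_average",
           "idm", "sum_entropy", "entropy", "difference_variance",
           "sum_variance", "difference_entropy", "imc1")
  switch(group,
         all = c(shape, hist, tex),
         shape = shape, histogram = hist, texture = tex)
}

#' Extract radiomic features from a z-scored map over a tumour mask
#'
#' Shape features come from the mask geometry; histogram features from the
#' multiset of masked z-values; texture features from 13-direction GLCMs of
#' the masked values quantized to `n_bins` equal-width grey levels on the
#' per-tumour [min, max] range, with feature-level averaging across
#' directions for rotation invariance.
#'
#' @param z_map `image_volume` of z-scored intensities (isotropic grid).
#' @param tumour_mask `label_mask` on the same grid.
#' @param n_bins Grey levels for texture quantization (default 32).
#' @param groups Which feature groups to compute (default all three).
#' @return Named numeric vector (29 values when all groups are requested).
#' @export
extract_features <- function(z_map, tumour_mask, n_bins = 32L,
                             groups = c("shape", "histogram", "texture")) {
  groups <- match.arg(groups, several.ok = TRUE)
  stopifnot_same_grid(z_map, tumour_mask, "z-map and tumour mask")
  if (!any(tumour_mask$values)) stop("empty tumour mask")
  out <- numeric(0)
  if ("shape" %in% groups)
    out <- c(out, shape_features(tumour_mask))
  if (any(c("histogram", "texture") %in% groups))
    zv <- z_map$values[tumour_mask$values]
  if ("histogram" %in% groups)
    out <- c(out, histogram_features(zv))
  if ("texture" %in% groups) {
    lev <- array(NA_integer_, dim = dim(z_map$values))
    lev[tumour_mask$values] <- quantize(zv, n_bins)
    glcms <- glcm_3d(lev, tumour_mask, n_bins)
    out <- c(out, haralick_features(glcms))
  }
  out
}

#' Full 29-feature vector for one subject
#'
#' @param case A `subject_case` (see [generate_cohort()]); used for error
#'   context and its tumour mask.
#' @param z_map The subject's z-scored map on the mask grid.
#' @param n_bins Grey levels for texture quantization.
#' @return Named numeric vector of exactly 29 features in canonical order.
#' @export
extract_all <- function(case, z_map, n_bins = 32L) {
  fv <- tryCatch(
    extract_features(z_map, case$tumour_mask, n_bins = n_bins),
    error = function(e) stop("feature extraction failed for subject '",
                             case$subject_id, "': ", conditionMessage(e)))
  stopifnot(identical(names(fv), feature_names()))
  fv
}
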