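#' Hemisphere half-space mask
#'
#' The brain is split at the mid-plane of the first array axis: "left" is
#' indices 1..floor(n/2), "right" the remainder. Synthetic cohorts and the
#' reference-region logic both use this convention.
#'
#' @param grid_dim Integer vector of 3 grid dimensions.
#' @param side "left" or "right".
#' @return Logical 3D array marking the half-space.
#' @export
hemisphere_half <- function(grid_dim, side = c("left", "right")) {
  side <- match.arg(side)
  n1 <- grid_dim[1]
  half <- floor(n1 / 2)
  idx <- if (side == "left") seq_len(half) else seq(half + 1L, n1)
  out <- array(FALSE, dim = grid_dim)
  out[idx, , ] <- TRUE
  out
}

opposite_hemisphere <- function(side) if (side == "left") "right" else "left"

#' Resample a volume or mask to isotropic spacing
#'
#' The output grid is anchored at the input origin and its size is
#' `ceiling(physical_extent / target)` per axis, so the output always covers
#' the input's physical extent. Voxel centres sit at `(i - 0.5) * spacing`.
#' Scalar volumes are interpolated trilinearly; masks must use
#' `mode = "nearest"` and are re-binarized, so they stay strictly binary.
#' Resampling at the input's own spacing is an exact identity.
#'
#' @param vol An `image_volume` or `label_mask`.
#' @param target_mm Positive target isotropic spacing (mm), default 1.
#' @param mode "trilinear" (volumes) or "nearest" (masks).
#' @return Object of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0,
                               mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a single positive number")
  is_mask <- inherits(vol, "label_mask")
  if (is_mask && mode != "nearest")
    stop("masks must be resampled with mode = 'nearest'")
  sp <- vol$spacing_mm
  d <- dim(vol$values)
  if (all(abs(sp - target_mm) < 1e-12)) return(vol)  # exact identity

  out_dim <- as.integer(ceiling(d * sp / target_mm - 1e-9))
  # continuous (1-based) input index of each output voxel centre, per axis
  coord <- lapply(seq_len(3), function(ax) {
    p <- (seq_len(out_dim[ax]) - 0.5) * target_mm   # physical position
    pmin(pmax(p / sp[ax] + 0.5, 1), d[ax])          # clamp to grid
  })
  vals <- vol$values
  if (is_mask) vals <- array(as.numeric(vals), dim = d)

  if (mode == "nearest") {
    ix <- lapply(coord, round)
    out <- vals[as.matrix(expand.grid(ix[[1]], ix[[2]], ix[[3]]))]
  } else {
    lo <- lapply(seq_len(3), function(ax)
      pmax(pmin(floor(coord[[ax]]), d[ax] - 1L), 1L))
    fr <- lapply(seq_len(3), function(ax) coord[[ax]] - lo[[ax]])
    g <- expand.grid(i = seq_len(out_dim[1]), j = seq_len(out_dim[2]),
                     k = seq_len(out_dim[3]))
    x0 <- lo[[1]][g$i]; y0 <- lo[[2]][g$j]; z0 <- lo[[3]][g$k]
    fx <- fr[[1]][g$i]; fy <- fr[[2]][g$j]; fz <- fr[[3]][g$k]
    x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
    out <-
      vals[cbind(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
      vals[cbind(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
      vals[cbind(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
      vals[cbind(x1, y1, z0)] * fx       * fy       * (1 - fz) +
      vals[cbind(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
      vals[cbind(x1, y0, z1)] * fx       * (1 - fy) * fz +
      vals[cbind(x0, y1, z1)] * (1 - fx) * fy       * fz +
      vals[cbind(x1, y1, z1)] * fx       * fy       * fz
  }
  out <- array(out, dim = out_dim)
  if (is_mask) {
    label_mask(out > 0.5, rep(target_mm, 3))
  } else {
    image_volume(out, rep(target_mm, 3))
  }
}

#' Restrict the reference region to tumour-free contralateral tissue
#'
#' The basal-ganglia reference mask covers both hemispheres; normalisation
#' must use only the hemisphere opposite the tumour, and any tumour voxels
#' extending across the midline are removed from it.
#'
#' @param reference_mask `label_mask` with reference voxels in both hemispheres.
#' @param tumour_mask `label_mask` of the tumour on the same grid.
#' @param tumour_hemisphere "left" or "right": where the tumour bulk lies.
#' @return A `label_mask` of the sanitized (contralateral, tumour-free)
#'   reference region.
#' @export
sanitize_reference <- function(reference_mask, tumour_mask,
                               tumour_hemisphere = c("left", "right")) {
  tumour_hemisphere <- match.arg(tumour_hemisphere)
  stopifnot_same_grid(reference_mask, tumour_mask, "masks")
  contralateral <- hemisphere_half(dim(reference_mask$values),
                                   opposite_hemisphere(tumour_hemisphere))
  keep <- reference_mask$values & contralateral & !tumour_mask$values
  if (!any(keep))
    stop("no valid reference voxels remain after removing tumour tissue")
  label_mask(keep, reference_mask$spacing_mm)
}

#' z-score an rCBV map against the clean reference region
#'
#' Each voxel value becomes `(v - mean_ref) / sd_ref`, where the mean and the
#' sample standard deviation (n-1 denominator) are taken over the sanitized
#' reference region. Only tumour-mask voxels are meaningful downstream, but
#' the map is defined everywhere for convenience. The map is invariant under
#' affine changes `a + b * rcbv` (b > 0) of the raw intensities.
#'
#' @param rcbv `image_volume` of rCBV intensities.
#' @param tumour_mask `label_mask` (carried through for grid checking).
#' @param clean_reference `label_mask` from [sanitize_reference()].
#' @return `image_volume` of z-scores on the same grid.
#' @export
zscore_normalise <- function(rcbv, tumour_mask, clean_reference) {
  stopifnot_same_grid(rcbv, clean_reference, "volume and reference mask")
  if (!is.null(tumour_mask)) stopifnot_same_grid(rcbv, tumour_mask, "volume and tumour mask")
  ref_vals <- rcbv$values[clean_reference$values]
  if (length(ref_vals) < 2L) stop("reference region too small to estimate spread")
  m <- mean(ref_vals)
  s <- stats::sd(ref_vals)
  if (!is.finite(s) || s <= 0) stop("degenerate reference region: sd is zero")
  image_volume((rcbv$values - m) / s, rcbv$spacing_mm)
}
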