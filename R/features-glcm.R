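#' Quantize masked intensities into equal-width grey levels
#'
#' Bins span the per-tumour [min, max] range; outputs are integer levels in
#' `0..n_bins-1`, with the maximum value assigned to the top bin. A constant
#' region maps entirely to level 0 (degenerate but valid: downstream texture
#' then reports ASM = 1, entropies 0).
#'
#' @param values Numeric vector of masked values.
#' @param n_bins Number of grey levels (>= 2).
#' @return Integer vector of levels, same length as `values`.
#' @export
quantize <- function(values, n_bins = 32L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (length(values) == 0L) stop("quantize: empty input")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(rep(0L, length(values)))
  lev <- floor((values - lo) / (hi - lo) * n_bins)
  as.integer(pmin(lev, n_bins - 1L))
}

# The 13 unique 1-voxel 3D offsets (half of the 26-neighbourhood, up to sign).
glcm_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

#' Grey-level co-occurrence matrices over a masked 3D region
#'
#' For each of the 13 unique 1-voxel 3D direction offsets, accumulates
#' symmetric pair counts over voxel pairs with both endpoints inside the
#' mask, then normalizes to a joint probability matrix. Directions with no
#' valid pair are flagged empty and excluded from feature averaging.
#'
#' @param levels Integer 3D array of quantized levels (values `0..n_levels-1`
#'   inside the mask; anything outside the mask is ignored).
#' @param mask `label_mask` (or logical array) selecting the region.
#' @param n_levels Number of grey levels Ng.
#' @return List of 13 elements, each `list(P = Ng x Ng probability matrix,
#'   direction = offset, n_pairs = count)`; `P` is `NULL` when empty.
#' @export
glcm_3d <- function(levels, mask, n_levels) {
  m <- if (inherits(mask, "label_mask")) mask$values else mask
  if (!any(m)) stop("glcm_3d: empty mask")
  d <- dim(levels)
  stopifnot(identical(d, dim(m)))
  ng <- as.integer(n_levels)
  dirs <- glcm_directions()
  out <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    rng <- lapply(1:3, function(ax) {
      if (off[ax] >= 0) seq_len(max(d[ax] - off[ax], 0L))
      else seq(1L - off[ax], d[ax])
    })
    if (any(lengths(rng) == 0L)) {
      out[[k]] <- list(P = NULL, direction = off, n_pairs = 0L)
      next
    }
    rng2 <- lapply(1:3, function(ax) rng[[ax]] + off[ax])
    a_in <- m[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] &
            m[rng2[[1]], rng2[[2]], rng2[[3]], drop = FALSE]
    if (!any(a_in)) {
      out[[k]] <- list(P = NULL, direction = off, n_pairs = 0L)
      next
    }
    la <- levels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE][a_in]
    lb <- levels[rng2[[1]], rng2[[2]], rng2[[3]], drop = FALSE][a_in]
    tab <- tabulate(la * ng + lb + 1L, nbins = ng * ng)
    counts <- matrix(tab, ng, ng, byrow = TRUE)   # row = la, col = lb
    counts <- counts + t(counts)                   # symmetric accumulation
    out[[k]] <- list(P = counts / sum(counts), direction = off,
                     n_pairs = as.integer(2L * length(la)))
  }
  out
}

log2_0 <- function(p) ifelse(p > 0, log2(p), 0)  # 0 * log 0 := 0

#' Haralick statistics of a single co-occurrence probability matrix
#'
#' Grey levels are 0-based (`0..Ng-1`). Entropies use log base 2 with
#' `0 log 0 := 0`. Correlation with a zero marginal variance is defined as 0;
#' IMC1 = (HXY - HXY1) / max(HX, HY) with 0/0 := 0. Sum variance is the
#' variance of the level-sum distribution about the sum average; difference
#' variance is the variance of the absolute level-difference distribution.
#'
#' @param P Square symmetric probability matrix (sums to 1).
#' @return Named numeric vector of 12 texture statistics.
#' @export
haralick_from_glcm <- function(P) {
  ng <- nrow(P)
  lev <- 0:(ng - 1)
  I <- matrix(lev, ng, ng)          # row level
  J <- t(I)                         # col level
  px <- rowSums(P)                  # == colSums for symmetric P
  py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  # level-sum and |level-difference| distributions
  s_idx <- as.vector(I + J)         # 0 .. 2(Ng-1)
  d_idx <- as.vector(abs(I - J))    # 0 .. Ng-1
  p_sum <- vapply(0:(2 * ng - 2), function(k) sum(P[s_idx == k]), 0)
  p_diff <- vapply(0:(ng - 1), function(k) sum(P[d_idx == k]), 0)
  ks <- 0:(2 * ng - 2); kd <- 0:(ng - 1)

  asm <- sum(P^2)
  contrast <- sum(kd^2 * p_diff)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (sum(I * J * P) - mu_x * mu_y) / (sd_x * sd_y) else 0
  mu <- mu_x                        # symmetric P: mu_x == mu_y
  sum_square <- sum((I - mu)^2 * P)
  idm <- sum(P / (1 + (I - J)^2))
  sum_average <- sum(ks * p_sum)
  sum_variance <- sum((ks - sum_average)^2 * p_sum)
  sum_entropy <- -sum(p_sum * log2_0(p_sum))
  entropy <- -sum(P * log2_0(P))
  mu_d <- sum(kd * p_diff)
  difference_variance <- sum((kd - mu_d)^2 * p_diff)
  difference_entropy <- -sum(p_diff * log2_0(p_diff))

  hx <- -sum(px * log2_0(px))
  hy <- -sum(py * log2_0(py))
  hxy1 <- -sum(P * log2_0(outer(px, py)))
  denom <- max(hx, hy)
  imc1 <- if (denom > 0) (entropy - hxy1) / denom else 0

  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_square = sum_square, sum_average = sum_average, idm = idm,
    sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance, sum_variance = sum_variance,
    difference_entropy = difference_entropy, imc1 = imc1)
}

#' Rotation-invariant Haralick texture features
#'
#' Each of the 12 statistics is computed per direction from that direction's
#' probability matrix, then averaged arithmetically across all non-empty
#' directions. Averaging features (not matrices) across the 13 unique 3D
#' offsets on an isotropic grid gives rotation invariance under grid-exact
#' 90-degree rotations.
#'
#' @param glcms Output of [glcm_3d()].
#' @return Named numeric vector of 12 rotation-invariant texture features.
#' @export
haralick_features <- function(glcms) {
  keep <- Filter(function(g) !is.null(g$P), glcms)
  if (length(keep) == 0L) stop("haralick_features: all directions empty")
  per_dir <- vapply(keep, function(g) haralick_from_glcm(g$P), numeric(12))
  rowMeans(per_dir)
}
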