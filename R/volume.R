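#' 3D image volume with voxel spacing
#'
#' Lightweight container for a 3D scalar lattice (e.g. an rCBV map or a
#' z-score map) together with its per-axis voxel spacing in millimetres.
#'
#' @param values Numeric 3D array.
#' @param spacing_mm Numeric vector of 3 positive voxel spacings (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("image_volume requires a 3D array, got ", length(dim(values)), "D")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "image_volume")
}

#' Binary label mask on a voxel grid
#'
#' @param values Logical (or 0/1 numeric) 3D array.
#' @param spacing_mm Numeric vector of 3 positive voxel spacings (mm).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("label_mask requires a 3D array")
  if (is.numeric(values)) {
    bad <- !(values %in% c(0, 1))
    if (any(bad)) stop("mask values must be 0/1")
    values <- array(values == 1, dim = dim(values))
  }
  if (!is.logical(values)) stop("mask values must be logical or 0/1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "label_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$values), collapse = "x"),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = "x"),
      " mm, ", sum(x$values), " foreground\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-9))
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " must share grid shape and voxel spacing")
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a NIfTI file (.nii or .nii.gz).
#' @return An `image_volume`; spacing taken from the header pixdim.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D in ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  image_volume(array(as.numeric(img), dim = d), sp)
}

#' Write a volume as NIfTI-1
#'
#' Values are stored as float32; spacing goes into the header pixdim.
#'
#' @param vol An `image_volume` or `label_mask`.
#' @param path Output path (.nii or .nii.gz).
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  if (is.logical(vals)) vals <- array(as.numeric(vals), dim = dim(vals))
  hdr <- RNifti::niftiHeader(RNifti::asNifti(vals, datatype = "float"))
  hdr$pixdim[2:4] <- vol$spacing_mm
  img <- RNifti::asNifti(vals, reference = hdr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI, coercing nonzero values to 1
#'
#' Files written by some tools encode foreground as 255; any nonzero value is
#' coerced to foreground, with a warning when values beyond {0,1} are present.
#'
#' @param path Path to a NIfTI mask file.
#' @return A `label_mask`.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  v <- vol$values
  extra <- setdiff(unique(as.vector(v)), c(0, 1))
  if (length(extra) > 0)
    warning("mask ", basename(path), " has values beyond {0,1}; binarizing (nonzero -> 1)")
  label_mask(array(v != 0, dim = dim(v)), vol$spacing_mm)
}
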