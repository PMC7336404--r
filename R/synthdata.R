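# Per-subject RNG stream seed derived from the master seed. Arithmetic
# derivation keeps a subject's volume reproducible regardless of how many
# subjects the cohort holds.
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 2654435 + i * 97) %% 2147483647)
}

# Periodic Gaussian smoothing of a 3D array via FFT; returns the field
# normalized to zero mean and unit sd (degenerate fields returned as-is).
gaussian_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (sigma_vox <= 0) return(arr)
  kern1 <- function(n, s) {
    x <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
    if (n == 1) x <- 0
    k <- exp(-0.5 * (x / s)^2)
    k / sum(k)
  }
  kx <- kern1(d[1], sigma_vox); ky <- kern1(d[2], sigma_vox)
  kz <- kern1(d[3], sigma_vox)
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- d
  sm <- Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
  s <- stats::sd(as.vector(sm))
  if (s > 0) (sm - mean(sm)) / s else sm
}

# sinh-based monotone skewing transform; lambda = 0 is the identity.
# Positive lambda yields positive sample skewness and raises kurtosis.
skew_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) return(x)
  (exp(lambda * x) - 1) / lambda
}

#' Generate a tumour mask as a perturbed digitized ellipsoid
#'
#' The mask is the positive set of the ellipsoid implicit function
#' `1 - sum(((x - c)/r)^2)` plus `irregularity` times a unit-variance
#' Gaussian-smoothed random field, clipped to the designated hemisphere and
#' reduced to its largest connected component (6-connectivity). At
#' irregularity 0 this is exactly the digitized ellipsoid; increasing
#' irregularity roughens the boundary, raising surface-to-volume ratio and
#' non-compactness.
#'
#' @param grid_dim 3 integers, grid shape (isotropic 1 mm voxels assumed
#'   unless `spacing_mm` given).
#' @param centre_mm Physical ellipsoid centre (mm).
#' @param base_radii_mm 3 positive semi-axis lengths (mm).
#' @param irregularity Nonnegative boundary-perturbation amplitude.
#' @param hemisphere "left" or "right": half-space the tumour must stay in.
#' @param spacing_mm Voxel spacing (default 1 mm isotropic).
#' @param smooth_sigma_mm Correlation length of the boundary noise (mm).
#' @return A `label_mask`.
#' @export
generate_tumour_mask <- function(grid_dim, centre_mm, base_radii_mm,
                                 irregularity = 0,
                                 hemisphere = c("left", "right"),
                                 spacing_mm = c(1, 1, 1),
                                 smooth_sigma_mm = 2) {
  hemisphere <- match.arg(hemisphere)
  if (irregularity < 0) stop("irregularity must be >= 0")
  if (any(base_radii_mm <= 0)) stop("radii must be positive")
  grid_dim <- as.integer(grid_dim)
  half_extent <- grid_dim[1] * spacing_mm[1] / 2
  # the base ellipsoid must fit inside the designated hemisphere
  lo <- centre_mm - base_radii_mm; hi <- centre_mm + base_radii_mm
  ext <- grid_dim * spacing_mm
  if (any(lo < 0) || any(hi > ext))
    stop("ellipsoid exceeds the grid")
  if (hemisphere == "left" && hi[1] > half_extent)
    stop("ellipsoid exceeds the left hemisphere")
  if (hemisphere == "right" && lo[1] < half_extent)
    stop("ellipsoid exceeds the right hemisphere")

  ax <- lapply(1:3, function(a) ((seq_len(grid_dim[a]) - 0.5) * spacing_mm[a] -
                                   centre_mm[a]) / base_radii_mm[a])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  f <- 1 - q
  if (irregularity > 0) {
    noise <- array(stats::rnorm(prod(grid_dim)), dim = grid_dim)
    field <- gaussian_smooth_3d(noise, smooth_sigma_mm / mean(spacing_mm))
    f <- f + irregularity * 0.35 * field
  }
  m <- f > 0
  m <- m & hemisphere_half(grid_dim, hemisphere)
  m <- largest_component(m)
  if (!any(m)) {
    # extreme perturbation wiped the mask; fall back to the ellipsoid core
    m <- (q < 0.5) & hemisphere_half(grid_dim, hemisphere)
  }
  label_mask(m, spacing_mm)
}

# Largest 6-connected component of a logical array (iterative flood fill).
largest_component <- function(m) {
  d <- dim(m)
  lab <- array(0L, dim = d)
  idx_fg <- which(m)
  if (length(idx_fg) == 0L) return(m)
  nxyz <- prod(d)
  comp <- 0L
  best_sz <- 0L; best <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  coord_ok <- function(i, ax, dir) {
    # whether stepping dir along ax from linear index i stays on the grid
    c3 <- arrayInd(i, d)
    v <- c3[, ax] + dir
    v >= 1L & v <= d[ax]
  }
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start; lab[start] <- comp
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue
      members <- c(members, cur)
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (ax in 1:3) for (dir in c(-1L, 1L)) {
        ok <- ci[, ax] + dir >= 1L & ci[, ax] + dir <= d[ax]
        if (!any(ok)) next
        nb <- cur[ok] + dir * strides[ax]
        nb <- nb[m[nb] & lab[nb] == 0L]
        if (length(nb) > 0) {
          lab[nb] <- comp
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
    if (length(members) > best_sz) { best_sz <- length(members); best <- members }
  }
  out <- array(FALSE, dim = d)
  out[best] <- TRUE
  out
}

#' Generate a synthetic rCBV-like volume for one subject
#'
#' Background is low-level Gaussian noise; reference-region voxels are drawn
#' around `mu_ref` with spread `sigma_ref`; tumour voxels are
#' `mu + centre_offset + g(heterogeneity * iid + sigma_corr * correlated)`
#' where the correlated field has Gaussian correlation length `corlen_vox`
#' voxels and `g` is a monotone sinh-based skewing transform with parameter
#' `skew`. `heterogeneity` is the spread of the unstructured voxel-wise
#' component, so a larger value yields more grey-level disorder between
#' neighbouring voxels and hence higher realized GLCM entropy on the
#' z-scored tumour; a larger `corlen_vox` makes neighbours more alike and
#' raises the realized GLCM correlation.
#'
#' @param tumour_mask,reference_mask `label_mask`s on a common grid.
#' @param class_params List or one-row data.frame with `mu`, `heterogeneity`,
#'   `skew`, `corlen_vox`.
#' @param centre_offset Additive intensity offset of the acquiring centre.
#' @param mu_ref,sigma_ref Reference-region location and spread.
#' @param sigma_corr Spread of the spatially correlated tumour component.
#' @return An `image_volume` of synthetic rCBV intensities.
#' @export
generate_rcbv <- function(tumour_mask, reference_mask, class_params,
                          centre_offset = 0, mu_ref = 1.0, sigma_ref = 0.5,
                          sigma_corr = 0.35) {
  stopifnot_same_grid(tumour_mask, reference_mask, "masks")
  p <- as.list(class_params)
  for (nm in c("mu", "heterogeneity", "skew", "corlen_vox"))
    if (is.null(p[[nm]])) stop("class_params missing '", nm, "'")
  if (sigma_ref <= 0) stop("sigma_ref must be positive")
  if (p$heterogeneity < 0) stop("heterogeneity must be >= 0")
  d <- dim(tumour_mask$values)
  vals <- 0.3 + 0.05 * array(stats::rnorm(prod(d)), dim = d)  # background
  rv <- reference_mask$values
  vals[rv] <- mu_ref + sigma_ref * stats::rnorm(sum(rv))
  tm <- tumour_mask$values
  n_t <- sum(tm)
  field <- p$heterogeneity * stats::rnorm(n_t)
  if (sigma_corr > 0) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    corr <- gaussian_smooth_3d(noise, p$corlen_vox)
    field <- field + sigma_corr * corr[tm]
  }
  vals[tm] <- p$mu + centre_offset + skew_transform(field, p$skew)
  image_volume(vals, tumour_mask$spacing_mm)
}

#' Default per-class intensity and shape effects
#'
#' One row per (grade, IDH) cell. Signs mirror the reported group contrasts:
#' IDH-mutant tumours get lower mean rCBV, higher skew, lower heterogeneity
#' and smoother boundaries (lower SAV / non-compactness); higher grades get
#' higher mean, higher heterogeneity (higher texture entropy / sum variance)
#' and rougher shapes; grade IV gets a shorter texture correlation length.
#'
#' @param effect_scale Multiplier on all class-difference magnitudes
#'   (1 = default conditions; 0 = null generator with identical classes).
#' @return data.frame keyed by `grade` and `idh`.
#' @export
default_class_effects <- function(effect_scale = 1) {
  grid <- expand.grid(grade = c(2L, 3L, 4L),
                      idh = c("mutant", "wildtype"),
                      stringsAsFactors = FALSE)
  base_mu <- 1.6; base_het <- 0.45; base_irr <- 0.7; base_cor <- 2.2
  mu_g <- c(`2` = -0.30, `3` = -0.10, `4` = 0.40)
  het_g <- c(`2` = -0.15, `3` = -0.05, `4` = 0.20)
  irr_g <- c(`2` = -0.30, `3` = 0.10, `4` = 0.30)
  cor_g <- c(`2` = 0.30, `3` = 0.30, `4` = -0.20)
  transform(grid,
    mu = base_mu + effect_scale * (mu_g[as.character(grade)] +
           ifelse(idh == "mutant", -0.35, 0)),
    heterogeneity = pmax(0.05, base_het + effect_scale *
           (het_g[as.character(grade)] + ifelse(idh == "mutant", -0.08, 0))),
    skew = pmax(0, 0.05 + effect_scale * ifelse(idh == "mutant", 0.45, 0)),
    corlen_vox = pmax(0.5, base_cor + effect_scale *
           (cor_g[as.character(grade)] + ifelse(idh == "mutant", 0.3, 0))),
    irregularity = pmax(0, base_irr + effect_scale *
           (irr_g[as.character(grade)] + ifelse(idh == "mutant", -0.25, 0))),
    radius_lo_mm = 8, radius_hi_mm = 12)
}

#' Default acquisition profiles for synthetic centres
#'
#' Each centre gets an additive rCBV intensity offset and a scanner profile
#' (manufacturer, field strength, TR/TE/FA, slice thickness, matrix,
#' in-plane resolution) chosen so that the standard dichotomization bins are
#' populated on both sides across centres.
#'
#' @param n_centres Number of centres.
#' @return data.frame with one row per centre.
#' @export
default_centre_profiles <- function(n_centres = 2) {
  pool <- data.frame(
    manufacturer = c("Siemens", "Philips", "GE", "Siemens", "Philips", "GE"),
    field_T = c(1.5, 3.0, 1.5, 3.0, 1.5, 3.0),
    TR_ms = c(1400, 1600, 1450, 1550, 1300, 1700),
    TE_ms = c(30, 50, 35, 48, 40, 46),
    FA_deg = c(90, 60, 90, 75, 90, 65),
    slice_mm = c(5, 4, 6, 3, 5, 4),
    matrix_size = c(128, 96, 256, 128, 96, 192),
    inplane_mm = c(1.8, 0.9, 1.2, 2.2, 0.8, 1.5),
    offset = c(-0.10, 0.10, -0.05, 0.15, 0.00, 0.05))
  pool[((seq_len(n_centres) - 1L) %% nrow(pool)) + 1L, , drop = FALSE]
}

#' Cohort generator configuration
#'
#' @param n_subjects Cohort size.
#' @param grid_shape 3 integers; default 64^3.
#' @param voxel_spacing_mm 3 positive reals; default 1 mm isotropic.
#' @param class_mix Named proportions over the 6 (grade, IDH) cells in the
#'   order of [default_class_effects()]; must sum to 1. The default mirrors a
#'   mixed-grade glioma cohort in which grade II tumours are mostly
#'   IDH-mutant and grade IV mostly wildtype.
#' @param class_effects data.frame per [default_class_effects()].
#' @param n_centres Number of acquiring centres.
#' @param centre_effects data.frame per [default_centre_profiles()].
#' @param seed Master seed; per-subject streams are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 60,
                          grid_shape = c(64, 64, 64),
                          voxel_spacing_mm = c(1, 1, 1),
                          class_mix = c(0.26, 0.13, 0.07, 0.04, 0.09, 0.41),
                          class_effects = default_class_effects(),
                          n_centres = 2,
                          centre_effects = default_centre_profiles(n_centres),
                          seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (abs(sum(class_mix) - 1) > 1e-12) stop("class_mix must sum to 1")
  if (length(class_mix) != nrow(class_effects))
    stop("class_mix length must match class_effects rows")
  max_r <- max(class_effects$radius_hi_mm)
  half_mm <- grid_shape[1] * voxel_spacing_mm[1] / 2
  if (2 * max_r >= half_mm)
    stop("tumour radii too large for one hemisphere of this grid")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = voxel_spacing_mm,
                 class_mix = class_mix,
                 class_effects = class_effects,
                 n_centres = as.integer(n_centres),
                 centre_effects = centre_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Largest-remainder apportionment of n into cells with proportions p.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Mirrored basal-ganglia-like reference ellipsoids (both hemispheres).
make_reference_mask <- function(grid_dim, spacing_mm, radius_mm = 6) {
  ext <- grid_dim * spacing_mm
  ctr_l <- c(ext[1] * 0.25, ext[2] * 0.5, ext[3] * 0.5)
  ctr_r <- c(ext[1] * 0.75, ext[2] * 0.5, ext[3] * 0.5)
  ell <- function(ctr) {
    ax <- lapply(1:3, function(a)
      (((seq_len(grid_dim[a]) - 0.5) * spacing_mm[a] - ctr[a]) / radius_mm)^2)
    outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) < 1
  }
  label_mask(ell(ctr_l) | ell(ctr_r), spacing_mm)
}

#' Generate a synthetic multi-centre cohort
#'
#' Produces `n_subjects` cases with class labels apportioned to `class_mix`
#' by largest remainder, centres assigned cyclically, and per-subject rCBV
#' volumes, tumour masks and two-hemisphere reference masks drawn from
#' per-subject RNG streams. Age is drawn per grade (higher grades older),
#' sex with P(male) = 0.6.
#'
#' @param config A `cohort_config`.
#' @return List with `cases` (list of `subject_case`) and `manifest`
#'   (data.frame, one row per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  eff <- config$class_effects
  counts <- apportion(n, config$class_mix)
  cls_idx <- rep(seq_len(nrow(eff)), counts)
  centre <- ((seq_len(n) - 1L) %% config$n_centres) + 1L

  set.seed(config$seed)
  cls_idx <- sample(cls_idx)            # shuffle class assignment
  ref <- make_reference_mask(config$grid_shape, config$voxel_spacing_mm)
  ext <- config$grid_shape * config$voxel_spacing_mm
  half_mm <- ext[1] / 2

  cases <- vector("list", n)
  rows <- vector("list", n)
  age_mu <- c(`2` = 40, `3` = 48, `4` = 58)
  for (i in seq_len(n)) {
    e <- eff[cls_idx[i], ]
    prof <- config$centre_effects[centre[i], ]
    set.seed(subject_seed(config$seed, i))
    hemi <- sample(c("left", "right"), 1)
    radii <- stats::runif(3, e$radius_lo_mm, e$radius_hi_mm)
    margin <- radii + 2
    ctr <- numeric(3)
    ctr[1] <- if (hemi == "left")
      stats::runif(1, margin[1], half_mm - margin[1])
    else stats::runif(1, half_mm + margin[1], ext[1] - margin[1])
    ctr[2] <- stats::runif(1, margin[2], ext[2] - margin[2])
    ctr[3] <- stats::runif(1, margin[3], ext[3] - margin[3])
    tmask <- generate_tumour_mask(config$grid_shape, ctr, radii,
                                  irregularity = e$irregularity,
                                  hemisphere = hemi,
                                  spacing_mm = config$voxel_spacing_mm)
    rcbv <- generate_rcbv(tmask, ref,
                          class_params = list(mu = e$mu,
                                              heterogeneity = e$heterogeneity,
                                              skew = e$skew,
                                              corlen_vox = e$corlen_vox),
                          centre_offset = prof$offset)
    age <- round(min(max(stats::rnorm(1, age_mu[as.character(e$grade)], 10),
                         20), 81))
    sex <- sample(c("M", "F"), 1, prob = c(0.6, 0.4))
    sid <- sprintf("sub%03d", i)
    cov <- list(manufacturer = prof$manufacturer, field_T = prof$field_T,
                TR_ms = prof$TR_ms, TE_ms = prof$TE_ms, FA_deg = prof$FA_deg,
                slice_mm = prof$slice_mm, matrix_size = prof$matrix_size,
                inplane_mm = prof$inplane_mm, centre = centre[i])
    cases[[i]] <- structure(list(subject_id = sid, rcbv = rcbv,
                                 tumour_mask = tmask, reference_mask = ref,
                                 tumour_hemisphere = hemi,
                                 grade = e$grade, idh = e$idh,
                                 age = age, sex = sex, covariates = cov),
                            class = "subject_case")
    rows[[i]] <- data.frame(subject_id = sid, grade = e$grade, idh = e$idh,
                            hemisphere = hemi, age = age, sex = sex,
                            manufacturer = prof$manufacturer,
                            field_T = prof$field_T, TR_ms = prof$TR_ms,
                            TE_ms = prof$TE_ms, FA_deg = prof$FA_deg,
                            slice_mm = prof$slice_mm,
                            matrix_size = prof$matrix_size,
                            inplane_mm = prof$inplane_mm,
                            centre = centre[i],
                            stringsAsFactors = FALSE)
  }
  list(cases = cases, manifest = do.call(rbind, rows))
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort$cases) {
    write_volume(cs$rcbv, file.path(dir, paste0(cs$subject_id, "_rcbv.nii.gz")))
    write_volume(cs$tumour_mask,
                 file.path(dir, paste0(cs$subject_id, "_tumour.nii.gz")))
    write_volume(cs$reference_mask,
                 file.path(dir, paste0(cs$subject_id, "_ref.nii.gz")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort back from NIfTI volumes and a manifest CSV
#'
#' Counterpart of [write_cohort()]: reconstructs the list of `subject_case`
#' objects from `<id>_rcbv.nii.gz`, `<id>_tumour.nii.gz`, `<id>_ref.nii.gz`
#' and `manifest.csv` in `dir`.
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `cases` and `manifest`, as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    sid <- row$subject_id
    structure(list(
      subject_id = sid,
      rcbv = read_volume(file.path(dir, paste0(sid, "_rcbv.nii.gz"))),
      tumour_mask = read_mask(file.path(dir, paste0(sid, "_tumour.nii.gz"))),
      reference_mask = read_mask(file.path(dir, paste0(sid, "_ref.nii.gz"))),
      tumour_hemisphere = row$hemisphere,
      grade = row$grade, idh = row$idh, age = row$age, sex = row$sex,
      covariates = as.list(row[c("manufacturer", "field_T", "TR_ms", "TE_ms",
                                 "FA_deg", "slice_mm", "matrix_size",
                                 "inplane_mm", "centre")])),
      class = "subject_case")
  })
  list(cases = cases, manifest = manifest)
}
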