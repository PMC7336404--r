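grid64 <- c(64, 64, 64)

test_that("unperturbed generator yields the digitized ellipsoid, confined to its hemisphere", {
  m <- generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10), 0, "left")
  # direct digitization of the same ellipsoid
  ax <- lapply(1:3, function(a) ((1:64 - 0.5) - c(16, 32, 32)[a])^2 / 100)
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  expect_equal(m$values, (q < 1) & hemisphere_half(grid64, "left"))
  expect_false(any(m$values & hemisphere_half(grid64, "right")))

  # non-compactness of the unperturbed mask is the minimum over a sweep
  nc <- vapply(c(0, 0.5, 1, 2), function(irr) {
    set.seed(42)
    shape_features(generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10),
                                        irr, "left"))[["non_compactness"]]
  }, 0)
  expect_equal(which.min(nc), 1L)
})

test_that("irregularity sweep at a fixed seed gives nondecreasing SAV", {
  for (s in 1:3) {
    sav <- vapply(c(0, 0.5, 1, 1.5, 2), function(irr) {
      set.seed(100 + s)
      shape_features(generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10),
                                          irr, "left"))[["sav"]]
    }, 0)
    expect_true(all(diff(sav) >= 0))
  }
})

test_that("mask generation is deterministic and validates its geometry", {
  set.seed(7)
  m1 <- generate_tumour_mask(grid64, c(16, 32, 32), c(9, 11, 10), 1.2, "left")
  set.seed(7)
  m2 <- generate_tumour_mask(grid64, c(16, 32, 32), c(9, 11, 10), 1.2, "left")
  expect_identical(m1$values, m2$values)
  expect_true(any(m1$values))
  # ellipsoid crossing the midline or the grid border is a parameter error
  expect_error(generate_tumour_mask(grid64, c(30, 32, 32), c(10, 10, 10),
                                    0, "left"), "hemisphere")
  expect_error(generate_tumour_mask(grid64, c(5, 32, 32), c(10, 10, 10),
                                    0, "left"), "grid")
  expect_error(generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10),
                                    -1, "left"), ">= 0")
})

test_that("degenerate intensity parameters give a symmetric Gaussian tumour histogram", {
  ref <- dscradiomics:::make_reference_mask(grid64, c(1, 1, 1))
  for (s in 1:3) {
    set.seed(200 + s)
    m <- generate_tumour_mask(grid64, c(16, 32, 32), c(14, 14, 14), 0, "left")
    v <- generate_rcbv(m, ref, list(mu = 1.5, heterogeneity = 0, skew = 0,
                                    corlen_vox = 0.7))
    zz <- v$values[m$values]
    expect_gte(length(zz), 1e4)
    expect_lt(abs(e1071::skewness(zz)), 0.1)
  }
  expect_error(generate_rcbv(m, ref, list(mu = 1, heterogeneity = -1,
                                          skew = 0, corlen_vox = 1)), ">= 0")
  expect_error(generate_rcbv(m, ref, list(mu = 1, heterogeneity = 1,
                                          skew = 0, corlen_vox = 1),
                             sigma_ref = 0), "positive")
})

test_that("longer texture correlation length raises realized GLCM correlation", {
  ref <- dscradiomics:::make_reference_mask(grid64, c(1, 1, 1))
  tex <- function(corlen, seed) {
    set.seed(seed)
    m <- generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10), 0.5, "left")
    v <- generate_rcbv(m, ref, list(mu = 1.5, heterogeneity = 0.2, skew = 0,
                                    corlen_vox = corlen), sigma_corr = 0.5)
    z <- zscore_normalise(v, m, sanitize_reference(ref, m, "left"))
    extract_features(z, m, groups = "texture")
  }
  for (s in 1:5)
    expect_gt(tex(2.5, s)[["correlation"]], tex(1, s)[["correlation"]])
})

test_that("larger heterogeneity raises realized GLCM entropy on the z-scored tumour", {
  ref <- dscradiomics:::make_reference_mask(grid64, c(1, 1, 1))
  ent <- function(het, seed) {
    set.seed(seed)
    m <- generate_tumour_mask(grid64, c(16, 32, 32), c(10, 10, 10), 0.5, "left")
    v <- generate_rcbv(m, ref, list(mu = 1.5, heterogeneity = het, skew = 0,
                                    corlen_vox = 2))
    z <- zscore_normalise(v, m, sanitize_reference(ref, m, "left"))
    extract_features(z, m, groups = "texture")[["entropy"]]
  }
  for (s in 1:5) expect_gt(ent(1, s), ent(0.1, s))
})

test_that("cohort class counts follow largest-remainder apportionment", {
  cfg <- small_cohort_config(1, 20, mix = rep(1 / 6, 6))
  coh <- generate_cohort(cfg)
  counts <- table(factor(paste(coh$manifest$grade, coh$manifest$idh),
                         levels = paste(rep(c(2, 3, 4), 2),
                                        rep(c("mutant", "wildtype"), each = 3))))
  expect_true(all(abs(as.numeric(counts) - 20 / 6) <= 1))
  expect_equal(sum(counts), 20)
})

test_that("a fixed cohort seed reproduces volumes and manifest bit-for-bit", {
  cfg <- small_cohort_config(77, 6, mix = rep(1 / 6, 6))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  for (i in seq_along(a$cases)) {
    expect_identical(a$cases[[i]]$rcbv$values, b$cases[[i]]$rcbv$values)
    expect_identical(a$cases[[i]]$tumour_mask$values,
                     b$cases[[i]]$tumour_mask$values)
  }
  # every tumour is confined to its designated hemisphere, masks non-empty,
  # reference covers both hemispheres
  for (cs in a$cases) {
    expect_true(any(cs$tumour_mask$values))
    h <- hemisphere_half(dim(cs$tumour_mask$values), cs$tumour_hemisphere)
    expect_false(any(cs$tumour_mask$values & !h))
    expect_true(any(cs$reference_mask$values &
                      hemisphere_half(dim(h), "left")))
    expect_true(any(cs$reference_mask$values &
                      hemisphere_half(dim(h), "right")))
  }
})

test_that("distinct centre offsets make centre a significant covariate of the raw mean", {
  prof <- default_centre_profiles(2)
  prof$offset <- c(-0.4, 0.4)
  eff <- default_class_effects(0)
  eff$radius_lo_mm <- 4.5; eff$radius_hi_mm <- 6
  cfg <- cohort_config(n_subjects = 40, grid_shape = c(32, 32, 32),
                       class_mix = c(0, 0, 0.5, 0, 0, 0.5),
                       class_effects = eff, n_centres = 2,
                       centre_effects = prof, seed = 5)
  coh <- generate_cohort(cfg)
  f <- extract_cohort(coh, groups = "histogram")
  p <- mann_whitney(f$mean[coh$manifest$centre == 1],
                    f$mean[coh$manifest$centre == 2])
  expect_lt(p, 0.05)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(class_mix = rep(0.2, 6)), "sum to 1")
  expect_error(cohort_config(n_subjects = 0), "positive")
  eff <- default_class_effects()
  eff$radius_hi_mm <- 40
  expect_error(cohort_config(class_effects = eff), "radii")
})

test_that("a cohort round-trips through NIfTI files and a manifest CSV", {
  cfg <- small_cohort_config(3, 2, mix = c(0, 0, 1, 0, 0, 0))
  coh <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sub001_rcbv.nii.gz")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  v <- read_volume(file.path(dir, "sub001_rcbv.nii.gz"))
  expect_equal(v$values, coh$cases[[1]]$rcbv$values, tolerance = 1e-6)
  m <- read_mask(file.path(dir, "sub001_tumour.nii.gz"))
  expect_identical(m$values, coh$cases[[1]]$tumour_mask$values)
  # full cohort loader reconstructs cases that flow through the pipeline
  coh2 <- read_cohort(dir)
  expect_equal(length(coh2$cases), 2)
  expect_equal(coh2$cases[[1]]$tumour_hemisphere,
               coh$cases[[1]]$tumour_hemisphere)
  fv_disk <- process_case(coh2$cases[[1]])
  fv_mem <- process_case(coh$cases[[1]])
  expect_equal(fv_disk, fv_mem, tolerance = 1e-4)  # float32 storage
  unlink(dir, recursive = TRUE)
})
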