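# Independent brute-force oracles. These deliberately use naive double-loop
# transcriptions of the defining formulas, sharing no code with the package.

# Pair-counting GLCM for one offset: loop over every voxel, look at its
# neighbour, accumulate symmetrically.
bf_glcm <- function(lev, mask, off, ng) {
  d <- dim(mask)
  counts <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    if (!mask[x2, y2, z2]) next
    i <- lev[x, y, z] + 1L; j <- lev[x2, y2, z2] + 1L
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# Literal loop transcription of the 12 texture statistics (0-based levels,
# log base 2, 0 log 0 = 0).
bf_haralick <- function(P) {
  ng <- nrow(P)
  lg <- function(p) if (p > 0) log2(p) else 0
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) { mu_x <- mu_x + (i - 1) * px[i]; mu_y <- mu_y + (i - 1) * py[i] }
  var_x <- 0; var_y <- 0
  for (i in 1:ng) {
    var_x <- var_x + (i - 1 - mu_x)^2 * px[i]
    var_y <- var_y + (i - 1 - mu_y)^2 * py[i]
  }
  p_sum <- numeric(2 * ng - 1)   # index k+1 holds P(i+j = k), k in 0..2ng-2
  p_dif <- numeric(ng)           # index k+1 holds P(|i-j| = k)
  for (i in 1:ng) for (j in 1:ng) {
    p_sum[(i - 1) + (j - 1) + 1] <- p_sum[(i - 1) + (j - 1) + 1] + P[i, j]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + P[i, j]
  }
  asm <- 0; contrast <- 0; corr_num <- 0; ssq <- 0; idm <- 0; ent <- 0
  for (i in 1:ng) for (j in 1:ng) {
    asm <- asm + P[i, j]^2
    contrast <- contrast + (i - j)^2 * P[i, j]
    corr_num <- corr_num + (i - 1) * (j - 1) * P[i, j]
    ssq <- ssq + (i - 1 - mu_x)^2 * P[i, j]
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    ent <- ent - P[i, j] * lg(P[i, j])
  }
  correlation <- if (var_x > 0 && var_y > 0)
    (corr_num - mu_x * mu_y) / sqrt(var_x * var_y) else 0
  sum_avg <- 0
  for (k in 0:(2 * ng - 2)) sum_avg <- sum_avg + k * p_sum[k + 1]
  sum_var <- 0; sum_ent <- 0
  for (k in 0:(2 * ng - 2)) {
    sum_var <- sum_var + (k - sum_avg)^2 * p_sum[k + 1]
    sum_ent <- sum_ent - p_sum[k + 1] * lg(p_sum[k + 1])
  }
  mu_d <- 0
  for (k in 0:(ng - 1)) mu_d <- mu_d + k * p_dif[k + 1]
  dif_var <- 0; dif_ent <- 0
  for (k in 0:(ng - 1)) {
    dif_var <- dif_var + (k - mu_d)^2 * p_dif[k + 1]
    dif_ent <- dif_ent - p_dif[k + 1] * lg(p_dif[k + 1])
  }
  hx <- 0; hy <- 0; hxy1 <- 0
  for (i in 1:ng) hx <- hx - px[i] * lg(px[i])
  for (j in 1:ng) hy <- hy - py[j] * lg(py[j])
  for (i in 1:ng) for (j in 1:ng) hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_square = ssq, sum_average = sum_avg, idm = idm,
    sum_entropy = sum_ent, entropy = ent, difference_variance = dif_var,
    sum_variance = sum_var, difference_entropy = dif_ent, imc1 = imc1)
}

# Exhaustive pair counting for Cliff's delta.
bf_cliffs <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments of
# the pooled (untied) sample.
bf_mann_whitney_exact <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(n_a + n_b, n_a)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Digitized sphere mask of radius r (voxel units) centred in a cube grid.
make_sphere <- function(r, pad = 2L) {
  n <- as.integer(2 * ceiling(r) + 1 + 2 * pad)
  c0 <- (n + 1) / 2
  ax <- (seq_len(n) - c0)^2
  q <- outer(outer(ax, ax, `+`), ax, `+`)
  label_mask(q <= r^2, c(1, 1, 1))
}

# Reduced-scale cohort configuration used by the statistical suites: 32^3
# grid, 4.5-6 mm tumour radii, grade-IV-only two-class mix unless given.
small_cohort_config <- function(seed, n, mix = c(0, 0, 0.5, 0, 0, 0.5),
                                effect_scale = 1, irregularity = NULL) {
  eff <- default_class_effects(effect_scale = effect_scale)
  eff$radius_lo_mm <- 4.5
  eff$radius_hi_mm <- 6
  if (!is.null(irregularity))
    eff$irregularity <- ifelse(eff$idh == "mutant", irregularity[1],
                               irregularity[2])
  cohort_config(n_subjects = n, grid_shape = c(32, 32, 32), class_mix = mix,
                class_effects = eff, seed = seed)
}

# Cohort -> residualized feature table for the named groups.
corrected_features <- function(cohort, groups = c("shape", "histogram")) {
  f <- extract_cohort(cohort, groups = groups)
  fx <- f[, intersect(feature_names(), names(f)), drop = FALSE]
  suppressWarnings(residualize(fx, cohort$manifest))
}
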