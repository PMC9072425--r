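# Independent brute-force oracles, deliberately written as plain R loops,
# structurally unlike the package implementations they check.

oracle_sphere_offsets <- function(radius_mm, spacing) {
  r <- ceiling(radius_mm / spacing) + 1L
  rows <- list()
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    d <- sqrt((dx * spacing[1])^2 + (dy * spacing[2])^2 +
                (dz * spacing[3])^2)
    if (d <= radius_mm) rows[[length(rows) + 1L]] <- c(dx, dy, dz)
  }
  do.call(rbind, rows)
}

sort_rows <- function(m) {
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Per-voxel evaluation of candidate criteria (a)-(c). Assumes every sphere
# around an evaluated voxel lies inside the volume (tests arrange this by
# insetting the WM mask), which keeps the gather a pure linear-index add.
oracle_candidate_mask <- function(vol, wm, brain, crit) {
  d <- dim(vol$data)
  strip_centre <- function(off) off[rowSums(abs(off)) > 0, , drop = FALSE]
  off_r <- strip_centre(oracle_sphere_offsets(crit$rank_radius_mm,
                                              vol$spacing))
  off_c <- strip_centre(oracle_sphere_offsets(crit$contrast_radius_mm,
                                              vol$spacing))
  lin <- function(off) off[, 1] + d[1] * off[, 2] + d[1] * d[2] * off[, 3]
  dl_r <- lin(off_r); dl_c <- lin(off_c)
  br <- as.vector(brain$data != 0)
  v <- as.vector(vol$data)
  cand <- array(FALSE, d)
  for (i in which(wm$data != 0)) {
    nb <- i + dl_c
    nb <- nb[br[nb]]
    if (!length(nb)) next
    m <- sum(v[nb]) / length(nb)
    if (m <= 0) next
    if (!(100 * (m - v[i]) / m > crit$contrast_threshold_pct)) next
    nb <- i + dl_r
    nb <- nb[br[nb]]
    if (!length(nb)) next
    rk <- sum(v[nb] < v[i]) / length(nb)
    if (rk <= crit$rank_percentile / 100) cand[i] <- TRUE
  }
  cand
}

# Covariance eigen-decomposition by explicit summation.
oracle_shape <- function(voxels, spacing) {
  n <- nrow(voxels)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) xyz[i, ] <- (voxels[i, ] - 1) * spacing
  ctr <- colSums(xyz) / n
  cv <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    dd <- xyz[i, ] - ctr
    cv <- cv + outer(dd, dd)
  }
  cv <- cv / n
  eg <- eigen(cv, symmetric = TRUE)
  edge <- prod(spacing)^(1 / 3)
  p1 <- xyz %*% eg$vectors[, 1]
  p2 <- xyz %*% eg$vectors[, 2]
  list(linearity = eg$values[1] / sum(eg$values),
       length_mm = max(p1) - min(p1) + edge,
       width_mm = max(p2) - min(p2) + edge,
       volume_mm3 = n * prod(spacing))
}

# Two-way sums-of-squares ICC(3,k) oracle.
oracle_icc3k <- function(wide) {
  wide <- as.matrix(wide)
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  row_m <- rowMeans(wide); col_m <- colMeans(wide)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / msr
}

# A phantom whose WM box is inset far enough that no evaluated sphere is
# truncated at the volume border (oracle precondition).
interior_phantom <- function(seed, dim = c(48, 48, 48), n_tubules = 2,
                             wm_margin = 14L, noise_sd = 2,
                             contrast_range = c(0.25, 0.4)) {
  set.seed(seed)
  spacing <- c(0.5, 0.5, 0.5)
  lo <- wm_margin * spacing + 0.6
  hi <- (dim - wm_margin - 1) * spacing - 0.6
  tubs <- list()
  for (i in seq_len(n_tubules)) {
    repeat {
      len <- runif(1, 3, 6)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ctr <- runif(3, lo + len / 2, hi - len / 2)
      a <- ctr - dir * len / 2; b <- ctr + dir * len / 2
      if (all(a > lo) && all(a < hi) && all(b > lo) && all(b < hi)) break
    }
    tubs[[i]] <- tubule_spec(a, b, runif(1, 0.5, 1),
                             runif(1, contrast_range[1], contrast_range[2]))
  }
  phantom_truth(dim = dim, spacing = spacing, tubules = tubs,
                wm_margin_vox = wm_margin, brain_margin_vox = 4L,
                noise_sd = noise_sd, seed = seed + 1000L)
}

# Minimal metric-level cohort table builders for the statistics tests.
make_cohort_rows <- function(subject_id, cohort, group, sessions, values,
                             age = 45, sex = "M", duration = 180,
                             scan_delay = 4, prior_days = 0, sans = NA) {
  data.frame(subject_id = subject_id, cohort = cohort, group = group,
             sans = sans, session = sessions, value = values,
             age_at_launch_yr = age, sex = sex,
             mission_duration_d = duration,
             days_landing_to_scan_d = scan_delay,
             prior_flight_days_d = prior_days, prior_missions = 0,
             stringsAsFactors = FALSE)
}
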