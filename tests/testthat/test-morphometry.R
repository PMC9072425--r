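sp05 <- rep(0.5, 3)

test_that("collinear clusters are perfectly linear with additive extent", {
  line <- cbind(3:12, 5, 5)  # 10 voxels along x at 0.5 mm steps
  d <- shape_descriptors(line, sp05)
  expect_equal(d$linearity, 1, tolerance = 1e-12)
  expect_equal(d$length_mm, 4.5 + 0.5)
  expect_equal(d$width_mm, 0.5)
  expect_equal(d$volume_mm3, 10 * 0.125)
  ## single voxel: defined as a point structure of one voxel edge
  s <- shape_descriptors(cbind(4, 4, 4), sp05)
  expect_equal(s$linearity, 1)
  expect_equal(s$length_mm, 0.5)
  expect_equal(s$width_mm, 0.5)
})

test_that("isotropic cubes have linearity 1/3 and equal extents", {
  cube <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  d <- shape_descriptors(cube, sp05)
  expect_equal(d$linearity, 1 / 3, tolerance = 1e-12)
  expect_equal(d$length_mm, d$width_mm, tolerance = 1e-9)
})

test_that("descriptors match the explicit covariance oracle on random clusters", {
  set.seed(31)
  for (rep in 1:5) {
    ## grow an elongated random cluster of ~30 voxels
    vox <- matrix(c(10, 10, 10), 1)
    dir <- c(1, 0.3, -0.2)
    while (nrow(vox) < 30) {
      base <- vox[sample(nrow(vox), 1), ]
      step <- sign(dir) * (runif(3) < abs(dir) / max(abs(dir)))
      cand <- base + step
      if (!any(apply(vox, 1, function(r) all(r == cand))))
        vox <- rbind(vox, cand)
    }
    d <- shape_descriptors(vox, sp05)
    o <- oracle_shape(vox, sp05)
    expect_equal(d$linearity, o$linearity, tolerance = 1e-9)
    expect_equal(d$length_mm, o$length_mm, tolerance = 1e-9)
    expect_equal(d$width_mm, o$width_mm, tolerance = 1e-9)
    expect_equal(d$volume_mm3, o$volume_mm3)
  }
})

test_that("descriptors are invariant to translation, permutation and 90-degree rotation", {
  set.seed(32)
  vox <- unique(cbind(sample(1:12, 40, TRUE), sample(1:5, 40, TRUE),
                      sample(1:3, 40, TRUE)))
  d0 <- shape_descriptors(vox, sp05)
  ## translation
  d1 <- shape_descriptors(sweep(vox, 2, c(5L, 7L, 2L), `+`), sp05)
  ## voxel order permutation
  d2 <- shape_descriptors(vox[sample(nrow(vox)), ], sp05)
  ## rotation by 90 degrees about z: (x, y) -> (y, -x), shifted positive
  d3 <- shape_descriptors(cbind(vox[, 2], max(vox[, 1]) + 1L - vox[, 1],
                                vox[, 3]), sp05)
  for (d in list(d1, d2, d3)) {
    expect_equal(d$linearity, d0$linearity, tolerance = 1e-9)
    expect_equal(d$length_mm, d0$length_mm, tolerance = 1e-9)
    expect_equal(d$width_mm, d0$width_mm, tolerance = 1e-9)
  }
  ## eigenvalue ordering: top eigenvalue at least the mean
  expect_gte(d0$linearity, 1 / 3 - 1e-12)
})

test_that("morphological constraints use inclusive linearity and strict width", {
  rec <- data.frame(cluster_id = 1:4, n_voxels = 10, volume_mm3 = 1.25,
                    length_mm = 5, width_mm = c(1.2, 16.41, 1.2, 16.40),
                    linearity = c(0.8, 0.95, 0.79, 0.95))
  kept <- apply_morphological_constraints(rec, pvs_criteria())
  expect_equal(kept$cluster_id, c(1L, 4L))  # 0.8 kept; 16.41 dropped
  ## filter monotonicity: stricter criteria never keep more clusters
  n_loose <- nrow(apply_morphological_constraints(
    rec, pvs_criteria(min_linearity = 0.5, max_width_mm = 20)))
  n_tight <- nrow(apply_morphological_constraints(
    rec, pvs_criteria(min_linearity = 0.9, max_width_mm = 10)))
  expect_lte(n_tight, n_loose)
})

test_that("session metrics compute totals and medians with missing-safe empties", {
  rec <- data.frame(cluster_id = 1:3, volume_mm3 = c(2, 4, 6),
                    length_mm = c(1, 2, 3), width_mm = c(1, 1, 2))
  m <- session_metrics(rec, wm_volume_cm3 = 480, ventricular_volume_mL = 30,
                       tiv_mL = 1500, subject_id = "A01", session = "L-60")
  expect_equal(m$total_pvs_volume_mL, 0.012)
  expect_equal(m$total_pvs_number, 3)
  expect_equal(m$median_pvs_volume_mm3, 4)
  ## even count: midpoint of the central order statistics
  rec4 <- data.frame(cluster_id = 1:4, volume_mm3 = 1,
                     length_mm = c(1, 2, 3, 10), width_mm = 1)
  expect_equal(session_metrics(rec4)$median_pvs_length_mm, 2.5)
  ## empty record list: totals zero, medians undefined
  e <- session_metrics(rec[0, ])
  expect_equal(e$total_pvs_volume_mL, 0)
  expect_equal(e$total_pvs_number, 0)
  expect_true(is.na(e$median_pvs_length_mm))
  ## additivity of totals under disjoint union
  m2 <- session_metrics(rbind(rec, rec4))
  expect_equal(m2$total_pvs_volume_mL,
               session_metrics(rec)$total_pvs_volume_mL +
                 session_metrics(rec4)$total_pvs_volume_mL)
  expect_error(session_metrics(rec, wm_volume_cm3 = -1), "non-negative")
})

test_that("normalization divides totals by baseline denominators, medians untouched", {
  m <- session_metrics(data.frame(cluster_id = 1:2, volume_mm3 = c(50, 70),
                                  length_mm = c(2, 3), width_mm = c(1, 1)),
                       wm_volume_cm3 = 500, ventricular_volume_mL = 30,
                       tiv_mL = 1500)
  n <- normalize_metrics(m, baseline_wm_cm3 = 480, baseline_tiv_mL = 1500)
  expect_equal(n$norm_total_pvs_volume, 120 / 480)  # mm^3 per cm^3 WM
  expect_equal(n$norm_total_pvs_number, 2 / 480)
  expect_equal(n$norm_ventricular_volume, 30 / 1500)
  expect_equal(n$median_pvs_length_mm, m$median_pvs_length_mm)
  expect_error(normalize_metrics(m, 0, 1500), "positive")
})
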