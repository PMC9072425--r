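# A uniform slab with full brain support, used by the single-voxel tests.
uniform_setting <- function(dim = c(15, 15, 15), value = 100) {
  sp <- rep(0.5, 3)
  list(vol = pvs_volume(array(value, dim), sp),
       brain = pvs_mask(array(TRUE, dim), sp),
       wm = pvs_mask(array(TRUE, dim), sp))
}

test_that("local rank fraction counts strictly darker neighbours", {
  u <- uniform_setting()
  ctr <- c(8, 8, 8)
  ## strict minimum of its neighbourhood -> rank 0, passes the percentile
  u$vol$data[8, 8, 8] <- 10
  expect_equal(local_rank_fraction(u$vol, u$brain, ctr, 1.5), 0)
  ## all neighbours equal to the centre: ties are not darker -> rank 0,
  ## but the joint criteria still reject (contrast is 0, not > 15%)
  u$vol$data[8, 8, 8] <- 100
  expect_equal(local_rank_fraction(u$vol, u$brain, ctr, 1.5), 0)
  expect_equal(local_mean_contrast(u$vol, u$brain, ctr, 1.5), 0)

  ## random patch: matches a sort-based enumeration oracle
  set.seed(42)
  u$vol$data <- array(rnorm(15^3, 100, 15), c(15, 15, 15))
  off <- oracle_sphere_offsets(1.5, rep(0.5, 3))
  off <- off[rowSums(abs(off)) > 0, ]
  nb <- sweep(off, 2, c(8L, 8L, 8L), `+`)
  vals <- u$vol$data[nb]
  cv <- u$vol$data[8, 8, 8]
  expect_equal(local_rank_fraction(u$vol, u$brain, c(8, 8, 8), 1.5),
               sum(sort(vals) < cv) / length(vals))
})

test_that("local mean contrast is the percent deficit against the surround mean", {
  u <- uniform_setting()
  u$vol$data[8, 8, 8] <- 80
  expect_equal(local_mean_contrast(u$vol, u$brain, c(8, 8, 8), 2), 20)
  u$vol$data[8, 8, 8] <- 95
  expect_equal(local_mean_contrast(u$vol, u$brain, c(8, 8, 8), 2), 5)
  ## empty neighbourhood -> undefined
  lone <- pvs_mask(array(FALSE, c(15, 15, 15)), rep(0.5, 3))
  lone$data[8, 8, 8] <- 1
  expect_true(is.na(local_rank_fraction(u$vol, lone, c(8, 8, 8), 1.5)))
  expect_true(is.na(local_mean_contrast(u$vol, lone, c(8, 8, 8), 1.5)))
})

test_that("candidate detection applies the three criteria jointly", {
  u <- uniform_setting()
  crit <- pvs_criteria()
  ## uniform intensity -> no candidates anywhere
  cand <- detect_candidates(u$vol, u$wm, u$brain, crit)
  expect_equal(sum(cand$mask$data), 0)
  ## one dark voxel: contrast 50% > 15%, rank 0 <= 5% -> candidate
  u$vol$data[8, 8, 8] <- 50
  cand <- detect_candidates(u$vol, u$wm, u$brain, crit)
  expect_equal(which(cand$mask$data != 0),
               which(array(seq_len(15^3), c(15, 15, 15)) ==
                       (8 + 15 * 7 + 225 * 7)))
  ## candidates confined to the eroded WM mask (criterion a)
  wm2 <- pvs_mask(array(FALSE, c(15, 15, 15)), rep(0.5, 3))
  wm2$data[1:4, , ] <- 1
  cand2 <- detect_candidates(u$vol, wm2, u$brain, crit)
  expect_equal(sum(cand2$mask$data * (1 - wm2$data)), 0)
  expect_equal(sum(cand2$mask$data), 0)  # the dark voxel is outside wm2
  ## grid mismatch rejected
  expect_error(detect_candidates(u$vol, pvs_mask(array(TRUE, c(4, 4, 4)),
                                                 rep(0.5, 3)),
                                 u$brain, crit), "grid")
})

test_that("fast detection equals the brute-force per-voxel oracle", {
  for (seed in 1:3) {
    gt <- interior_phantom(seed, dim = c(40, 40, 40), n_tubules = 2,
                           wm_margin = 12L)
    b <- render_phantom(gt)
    crit <- pvs_criteria()
    cand <- detect_candidates(b$vol, b$wm, b$brain, crit)
    expect_equal(cand$mask$data != 0,
                 oracle_candidate_mask(b$vol, b$wm, b$brain, crit),
                 info = paste("seed", seed))
    ## every implanted tubule is hit, and a solid share of tubule voxels
    ## pass the joint criteria (boundary voxels of thick tubules may not)
    for (tm in b$truth_masks)
      expect_gt(sum(cand$mask$data[tm]), 0)
    all_tub <- Reduce(`|`, b$truth_masks)
    expect_gt(sum(cand$mask$data[all_tub]) / sum(all_tub), 0.3)
  }
})

test_that("candidates are invariant to positive rescaling of intensities", {
  gt <- interior_phantom(9, dim = c(36, 36, 36), n_tubules = 1,
                         wm_margin = 11L)
  b <- render_phantom(gt)
  cand1 <- detect_candidates(b$vol, b$wm, b$brain)
  v2 <- pvs_volume(b$vol$data * 3.7, b$vol$spacing)
  cand2 <- detect_candidates(v2, b$wm, b$brain)
  expect_equal(cand1$mask$data, cand2$mask$data)
})

test_that("clustering uses corner-to-corner connectivity and a strict volume rule", {
  sp <- rep(0.5, 3)
  crit <- pvs_criteria()
  ## two voxels touching only at a corner form one cluster
  m <- array(FALSE, c(10, 10, 10))
  m[4, 4, 4] <- TRUE; m[5, 5, 5] <- TRUE
  cl <- cluster_candidates(pvs_mask(m, sp),
                           pvs_criteria(min_cluster_volume_mm3 = 0.2))
  expect_equal(cl$n_clusters, 1L)
  ## 8 voxels = 1.0 mm^3 exactly: NOT > 1 -> dropped; 9 voxels retained
  m8 <- array(FALSE, c(10, 10, 10)); m8[3:4, 3:4, 3:4] <- TRUE
  expect_equal(cluster_candidates(pvs_mask(m8, sp), crit)$n_clusters, 0L)
  m9 <- m8; m9[5, 4, 4] <- TRUE
  cl9 <- cluster_candidates(pvs_mask(m9, sp), crit)
  expect_equal(cl9$n_clusters, 1L)
  expect_equal(sum(cl9$labels == 1L), 9L)
})

test_that("cluster retention is monotone in the volume threshold", {
  set.seed(11)
  m <- array(runif(20^3) > 0.7, c(20, 20, 20))
  thresholds <- c(0.2, 0.5, 1, 2, 5, 20)
  ns <- vapply(thresholds, function(th)
    cluster_candidates(pvs_mask(m, rep(0.5, 3)),
                       pvs_criteria(min_cluster_volume_mm3 = th))$n_clusters,
    integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("review export/import round-trips and filters rejects", {
  gt <- interior_phantom(5, dim = c(40, 40, 40), n_tubules = 3,
                         wm_margin = 12L)
  b <- render_phantom(gt)
  rec <- detect_pvs(b$vol, b$wm, b$brain)
  expect_gte(nrow(rec), 2)
  f <- tempfile(fileext = ".tsv")
  export_review_table(rec, f)
  ## untouched file -> identical record set
  expect_equal(apply_review_table(rec, f)$cluster_id, rec$cluster_id)
  ## reject one -> it is dropped
  rv <- read.delim(f)
  rv$decision[1] <- "reject"
  write.table(rv, f, sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- apply_review_table(rec, f)
  expect_equal(nrow(kept), nrow(rec) - 1L)
  expect_false(rv$cluster_id[1] %in% kept$cluster_id)
  ## unknown label -> error
  rv$cluster_id[1] <- 999L
  write.table(rv, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(apply_review_table(rec, f), "unknown")
})

test_that("criteria constructor validates its thresholds", {
  expect_error(pvs_criteria(rank_percentile = 0), "rank_percentile")
  expect_error(pvs_criteria(min_linearity = 1.2), "min_linearity")
  expect_error(pvs_criteria(contrast_threshold_pct = -5), "> 0")
  expect_output(print(pvs_criteria()), "16.41")
})
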