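#' Specify synthetic structures for a digital phantom
#'
#' `tubule_spec` describes a PVS-like tubular hypointensity as a centreline
#' segment with a physical radius and a fractional intensity deficit
#' relative to white matter (e.g. `contrast_frac = 0.3` renders the tubule
#' at 70% of the white-matter intensity). `blob_spec` describes a roughly
#' isotropic distractor sphere — dark enough to pass the voxelwise
#' criteria but rejected by the linearity constraint.
#'
#' @param start_mm,end_mm Physical endpoints of the tubule centreline (mm).
#' @param centre_mm Physical centre of a blob (mm).
#' @param radius_mm Structure radius in mm (> 0).
#' @param contrast_frac Fraction of WM intensity removed, in (0, 1).
#' @return A list of class `tubule_spec` / `blob_spec`.
#' @export
tubule_spec <- function(start_mm, end_mm, radius_mm, contrast_frac) {
  start_mm <- as.numeric(start_mm); end_mm <- as.numeric(end_mm)
  stopifnot(length(start_mm) == 3L, length(end_mm) == 3L,
            radius_mm > 0, contrast_frac > 0, contrast_frac < 1)
  if (sqrt(sum((end_mm - start_mm)^2)) <= 0)
    stop("tubule segment must have positive length", call. = FALSE)
  structure(list(start_mm = start_mm, end_mm = end_mm,
                 radius_mm = radius_mm, contrast_frac = contrast_frac),
            class = "tubule_spec")
}

#' @rdname tubule_spec
#' @export
blob_spec <- function(centre_mm, radius_mm, contrast_frac) {
  centre_mm <- as.numeric(centre_mm)
  stopifnot(length(centre_mm) == 3L, radius_mm > 0,
            contrast_frac > 0, contrast_frac < 1)
  structure(list(centre_mm = centre_mm, radius_mm = radius_mm,
                 contrast_frac = contrast_frac),
            class = "blob_spec")
}

#' Ground truth for a 3D digital phantom
#'
#' Defines everything needed to render a phantom deterministically: the
#' grid, a box-shaped white-matter compartment inset from the border (the
#' brain support extends `brain_margin_vox` voxels beyond it), the
#' implanted tubules and distractor blobs, the white-matter intensity, and
#' Gaussian scanner noise controlled by `seed`.
#'
#' @param dim Integer length-3 grid size.
#' @param spacing Voxel size in mm; default the 0.5 mm working grid.
#' @param tubules List of [tubule_spec()]s.
#' @param distractors List of [blob_spec()]s.
#' @param wm_margin_vox Inset of the WM box from the volume border, voxels.
#' @param brain_margin_vox Voxels of brain support beyond the WM box.
#' @param wm_intensity White-matter intensity (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD (same units).
#' @param seed Integer seed; fully determines the rendered volume.
#' @return A list of class `phantom_truth`.
#' @export
phantom_truth <- function(dim = c(48, 48, 48), spacing = c(0.5, 0.5, 0.5),
                          tubules = list(), distractors = list(),
                          wm_margin_vox = 8L, brain_margin_vox = 4L,
                          wm_intensity = 100, noise_sd = 2, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L), all(spacing > 0),
            wm_intensity > 0, noise_sd >= 0)
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 tubules = tubules, distractors = distractors,
                 wm_margin_vox = as.integer(wm_margin_vox),
                 brain_margin_vox = as.integer(brain_margin_vox),
                 wm_intensity = wm_intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

.box_mask <- function(dim, margin) {
  m <- array(FALSE, dim)
  m[(margin + 1):(dim[1] - margin),
    (margin + 1):(dim[2] - margin),
    (margin + 1):(dim[3] - margin)] <- TRUE
  m
}

# squared distance from every voxel centre to a segment [a, b] (mm)
.dist2_to_segment <- function(dim, spacing, a, b) {
  gx <- (seq_len(dim[1]) - 1) * spacing[1]
  gy <- (seq_len(dim[2]) - 1) * spacing[2]
  gz <- (seq_len(dim[3]) - 1) * spacing[3]
  px <- array(gx, dim)
  py <- array(rep(gy, each = dim[1]), dim)
  pz <- array(rep(gz, each = dim[1] * dim[2]), dim)
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 > 0)
    pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2] +
                 (pz - a[3]) * ab[3]) / len2, 0), 1)
  else 0
  (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
    (pz - (a[3] + t * ab[3]))^2
}

#' Render a phantom to an intensity volume plus masks
#'
#' White-matter voxels take `wm_intensity`; the rest of the brain support
#' takes the same base intensity so neighborhood statistics see a uniform
#' surround. A voxel belongs to a structure when its centre lies within
#' `radius_mm` of the tubule centreline (point-to-segment distance) or blob
#' centre; such voxels are attenuated to `wm_intensity * (1 -
#' contrast_frac)`. Gaussian noise (`noise_sd`) is then added over the
#' brain support, seeded by `gt$seed` so rendering is bit-reproducible.
#'
#' @param gt A [phantom_truth()].
#' @return List with `vol` ([pvs_volume()]), `brain`, `wm` ([pvs_mask()]s)
#'   and `truth_masks`: per-tubule voxel masks for scoring.
#' @export
render_phantom <- function(gt) {
  stopifnot(inherits(gt, "phantom_truth"))
  wm <- .box_mask(gt$dim, gt$wm_margin_vox)
  brain <- .box_mask(gt$dim, gt$wm_margin_vox - gt$brain_margin_vox)
  img <- array(0, gt$dim)
  img[brain] <- gt$wm_intensity

  structures <- c(gt$tubules, gt$distractors)
  truth_masks <- vector("list", length(gt$tubules))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    d2 <- if (inherits(s, "tubule_spec"))
      .dist2_to_segment(gt$dim, gt$spacing, s$start_mm, s$end_mm)
    else
      .dist2_to_segment(gt$dim, gt$spacing, s$centre_mm, s$centre_mm)
    inside <- d2 <= s$radius_mm^2
    if (any(inside & !wm))
      stop("structure ", i, " extends outside the white-matter mask",
           call. = FALSE)
    if (!any(inside))
      stop("structure ", i, " covers no voxel centre", call. = FALSE)
    img[inside] <- gt$wm_intensity * (1 - s$contrast_frac)
    if (i <= length(gt$tubules)) truth_masks[[i]] <- inside
  }

  if (gt$noise_sd > 0) {
    set.seed(gt$seed)
    img[brain] <- img[brain] + rnorm(sum(brain), 0, gt$noise_sd)
  }
  list(vol = pvs_volume(img, gt$spacing, note = "phantom"),
       brain = pvs_mask(brain, gt$spacing),
       wm = pvs_mask(wm, gt$spacing),
       truth_masks = truth_masks)
}

#' Draw a random phantom with PVS-like tubules
#'
#' Samples `n_tubules` mutually separated tubules inside the white-matter
#' box, with radii, lengths and contrasts drawn uniformly from the given
#' ranges — defaults span the regime the detector is designed for
#' (sub-3 mm caliber, 15%+ deficit). Optionally adds isotropic distractor
#' blobs.
#'
#' @param seed Integer seed (drives both sampling and rendering noise).
#' @param n_tubules Number of tubules.
#' @param dim Grid size.
#' @param contrast_range,radius_range,length_range Uniform sampling ranges.
#' @param n_blobs Number of distractor blobs (contrast 0.3, radius 1.5 mm).
#' @param min_separation_mm Minimum distance between tubule centrelines.
#' @param noise_sd Rendering noise SD.
#' @return A [phantom_truth()].
#' @export
random_phantom <- function(seed, n_tubules = 5, dim = c(48, 48, 48),
                           contrast_range = c(0.25, 0.4),
                           radius_range = c(0.5, 1),
                           length_range = c(3, 10),
                           n_blobs = 0, min_separation_mm = 4,
                           noise_sd = 2) {
  set.seed(seed)
  spacing <- c(0.5, 0.5, 0.5)
  margin <- 8L
  lo <- margin * spacing + 1.0          # keep structures inside the WM box
  hi <- (dim - margin - 1) * spacing - 1.0
  ## keep segments comfortably shorter than the box so several can coexist
  max_len <- 0.6 * min(hi - lo)
  if (max_len < length_range[1])
    stop("white-matter box too small for the requested tubule lengths",
         call. = FALSE)
  length_range[2] <- min(length_range[2], max_len)
  seg_points <- function(t1) {
    tt <- seq(0, 1, length.out = 8)
    cbind(t1$start_mm[1] + tt * (t1$end_mm[1] - t1$start_mm[1]),
          t1$start_mm[2] + tt * (t1$end_mm[2] - t1$start_mm[2]),
          t1$start_mm[3] + tt * (t1$end_mm[3] - t1$start_mm[3]))
  }
  tubules <- list()
  tries <- 0
  while (length(tubules) < n_tubules && tries < 8000) {
    tries <- tries + 1
    len <- runif(1, length_range[1], length_range[2])
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    ctr <- runif(3, lo + len / 2, hi - len / 2)
    cand <- tubule_spec(ctr - dir * len / 2, ctr + dir * len / 2,
                        radius_mm = runif(1, radius_range[1], radius_range[2]),
                        contrast_frac = runif(1, contrast_range[1],
                                              contrast_range[2]))
    if (any(cand$start_mm < lo) || any(cand$start_mm > hi) ||
        any(cand$end_mm < lo) || any(cand$end_mm > hi)) next
    pts <- seg_points(cand)
    ok <- all(vapply(tubules, function(t2) {
      min(as.matrix(stats::dist(rbind(pts, seg_points(t2))))[1:8, 9:16]) >=
        min_separation_mm
    }, logical(1)))
    if (ok) tubules[[length(tubules) + 1]] <- cand
  }
  if (length(tubules) < n_tubules)
    stop("could not place ", n_tubules, " separated tubules", call. = FALSE)

  blobs <- list()
  if (n_blobs > 0) {
    for (b in seq_len(n_blobs)) {
      repeat {
        ctr <- runif(3, lo + 2, hi - 2)
        ok <- all(vapply(tubules, function(t2) {
          min(sqrt(colSums((t(seg_points(t2)) - ctr)^2))) >= min_separation_mm
        }, logical(1)))
        if (ok) break
      }
      blobs[[b]] <- blob_spec(ctr, radius_mm = 1.5, contrast_frac = 0.3)
    }
  }
  phantom_truth(dim = dim, spacing = spacing, tubules = tubules,
                distractors = blobs, wm_margin_vox = margin,
                noise_sd = noise_sd, seed = seed)
}

.point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

#' Score detections against phantom ground truth
#'
#' A detected cluster matches a tubule when its centroid lies within
#' `match_mm` of the tubule's centreline segment. Recall is the fraction
#' of tubules matched by at least one cluster; precision the fraction of
#' clusters matching some tubule. For each matched cluster the absolute
#' errors of length and width against the tubule's nominal physical size
#' (centreline length + 2 radius; 2 radius) are reported.
#'
#' @param gt The [phantom_truth()] that produced the volume.
#' @param records Filtered cluster descriptor table ([cluster_records()]).
#' @param match_mm Matching distance in mm (default 1).
#' @return List of class `pvs_phantom_score`: `recall`, `precision`,
#'   `n_tubules`, `n_clusters`, `matches` (data.frame with per-match
#'   length/width absolute errors).
#' @export
score_detection <- function(gt, records, match_mm = 1) {
  stopifnot(inherits(gt, "phantom_truth"), is.data.frame(records))
  nt <- length(gt$tubules)
  nc <- nrow(records)
  tub_matched <- logical(nt)
  rows <- list()
  if (nc > 0 && nt > 0) {
    for (j in seq_len(nc)) {
      p <- c(records$cx_mm[j], records$cy_mm[j], records$cz_mm[j])
      dists <- vapply(gt$tubules, function(tb)
        .point_segment_dist(p, tb$start_mm, tb$end_mm), numeric(1))
      k <- which.min(dists)
      if (dists[k] <= match_mm) {
        tub_matched[k] <- TRUE
        tb <- gt$tubules[[k]]
        true_len <- sqrt(sum((tb$end_mm - tb$start_mm)^2)) + 2 * tb$radius_mm
        rows[[length(rows) + 1]] <- data.frame(
          cluster_id = records$cluster_id[j], tubule = k,
          dist_mm = dists[k],
          length_err_mm = abs(records$length_mm[j] - true_len),
          width_err_mm = abs(records$width_mm[j] - 2 * tb$radius_mm))
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), tubule = integer(),
               dist_mm = numeric(), length_err_mm = numeric(),
               width_err_mm = numeric())
  structure(list(
    recall = if (nt) sum(tub_matched) / nt else NA_real_,
    precision = if (nc) nrow(matches[!duplicated(matches$cluster_id), ]) / nc
                else NA_real_,
    n_tubules = nt, n_clusters = nc, matches = matches),
    class = "pvs_phantom_score")
}

#' @export
print.pvs_phantom_score <- function(x, ...) {
  cat(sprintf("<pvs_phantom_score> recall %.3f, precision %.3f (%d tubules, %d clusters)\n",
              x$recall, x$precision, x$n_tubules, x$n_clusters))
  invisible(x)
}

#' Run the full detection pipeline on one rendered volume
#'
#' Convenience wrapper: candidate detection, clustering, shape
#' descriptors, morphological constraints. Inputs must already be on the
#' working grid (phantoms are rendered there directly; clinical volumes go
#' through [reslice_isotropic()] and [condition_wm_mask()] first).
#'
#' @param vol Intensity [pvs_volume()].
#' @param wm Eroded/conditioned white-matter [pvs_mask()].
#' @param brain Brain-support [pvs_mask()].
#' @param crit A [pvs_criteria()].
#' @return Filtered cluster descriptor table (see [cluster_records()]),
#'   with the unfiltered table as attribute `"all_clusters"`.
#' @export
detect_pvs <- function(vol, wm, brain, crit = pvs_criteria()) {
  cand <- detect_candidates(vol, wm, brain, crit)
  cl <- cluster_candidates(cand, crit)
  rec <- cluster_records(cl)
  out <- apply_morphological_constraints(rec, crit)
  attr(out, "all_clusters") <- rec
  out
}
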