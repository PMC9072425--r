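#' Detection criteria for white-matter PVS
#'
#' Bundles every constant of the two-step morphological detector. A voxel
#' on the 0.5 mm working grid is a candidate when (a) it lies in the eroded
#' white-matter mask, (b) its intensity deficit relative to the mean of its
#' 4 mm spherical surround exceeds `contrast_threshold_pct`, and (c) its
#' intensity falls in the bottom `rank_percentile` of its 3 mm surround.
#' Candidate clusters (26-connectivity) are kept when their volume exceeds
#' `min_cluster_volume_mm3`, and putative PVS additionally require width
#' strictly below `max_width_mm` and linearity of at least `min_linearity`.
#'
#' @param rank_radius_mm Radius of the intensity-rank sphere (mm).
#' @param contrast_radius_mm Radius of the contrast sphere (mm).
#' @param contrast_threshold_pct Minimum percent intensity deficit (strict).
#' @param rank_percentile Rank cut-off as a percentile (candidate when the
#'   fraction of strictly darker neighbors is <= this / 100).
#' @param min_cluster_volume_mm3 Cluster volume threshold in mm^3 (strict >).
#' @param max_width_mm Width constraint in mm (strict <); the default 16.41
#'   is inherited from the detector's prior calibration.
#' @param min_linearity Linearity constraint in `[0, 1]` (inclusive >=).
#' @return An object of class `pvs_criteria` (a validated list).
#' @export
#' @examples
#' pvs_criteria()
pvs_criteria <- function(rank_radius_mm = 3,
                         contrast_radius_mm = 4,
                         contrast_threshold_pct = 15,
                         rank_percentile = 5,
                         min_cluster_volume_mm3 = 1,
                         max_width_mm = 16.41,
                         min_linearity = 0.8) {
  crit <- list(rank_radius_mm = rank_radius_mm,
               contrast_radius_mm = contrast_radius_mm,
               contrast_threshold_pct = contrast_threshold_pct,
               rank_percentile = rank_percentile,
               min_cluster_volume_mm3 = min_cluster_volume_mm3,
               max_width_mm = max_width_mm,
               min_linearity = min_linearity)
  num <- vapply(crit, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stop("all criteria must be single finite numbers",
                      call. = FALSE)
  pos <- c("rank_radius_mm", "contrast_radius_mm", "contrast_threshold_pct",
           "min_cluster_volume_mm3", "max_width_mm")
  if (any(unlist(crit[pos]) <= 0))
    stop("radii, thresholds and volumes must be > 0", call. = FALSE)
  if (crit$rank_percentile <= 0 || crit$rank_percentile >= 100)
    stop("rank_percentile must lie in (0, 100)", call. = FALSE)
  if (crit$min_linearity < 0 || crit$min_linearity > 1)
    stop("min_linearity must lie in [0, 1]", call. = FALSE)
  structure(crit, class = "pvs_criteria")
}

#' @export
print.pvs_criteria <- function(x, ...) {
  cat("PVS detection criteria:\n")
  cat(sprintf("  rank sphere     %g mm, bottom %g%% (rank fraction <= %g)\n",
              x$rank_radius_mm, x$rank_percentile, x$rank_percentile / 100))
  cat(sprintf("  contrast sphere %g mm, deficit > %g%%\n",
              x$contrast_radius_mm, x$contrast_threshold_pct))
  cat(sprintf("  clusters        > %g mm^3, width < %g mm, linearity >= %g\n",
              x$min_cluster_volume_mm3, x$max_width_mm, x$min_linearity))
  invisible(x)
}

.neighborhood_values <- function(vol, support, centre, radius_mm) {
  d <- dim(vol$data)
  off <- sphere_offsets(radius_mm, vol$spacing, include_centre = FALSE)$offsets
  nb <- sweep(off, 2, as.integer(centre), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
    nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  idx <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
  idx <- idx[support$data[idx] != 0]
  vol$data[idx]
}

#' Single-voxel neighborhood statistics
#'
#' Reference implementations of the two voxelwise statistics, evaluated at
#' one voxel. `local_rank_fraction` returns the fraction of neighbors
#' strictly darker than the centre; `local_mean_contrast` the percent
#' deficit `100 * (mean(neighbors) - I(centre)) / mean(neighbors)`. The
#' neighborhood is the spherical offset set intersected with `support`
#' (the skull-stripped brain), excluding the centre voxel and truncated at
#' the volume border. Both return `NA` when undefined (empty neighborhood;
#' non-positive neighborhood mean), and such voxels are never candidates.
#' [detect_candidates()] computes the same quantities for all voxels at
#' once in compiled code.
#'
#' @param vol A [pvs_volume()].
#' @param support A [pvs_mask()] of usable neighbor voxels (brain mask).
#' @param centre Integer length-3 voxel index (1-based).
#' @param radius_mm Sphere radius in mm.
#' @return A single number (fraction in `[0, 1]`, or percent), or `NA`.
#' @export
local_rank_fraction <- function(vol, support, centre, radius_mm) {
  .stopifnot_same_grid(vol, support)
  vals <- .neighborhood_values(vol, support, centre, radius_mm)
  if (length(vals) == 0L) return(NA_real_)
  cv <- vol$data[centre[1], centre[2], centre[3]]
  sum(vals < cv) / length(vals)
}

#' @rdname local_rank_fraction
#' @export
local_mean_contrast <- function(vol, support, centre, radius_mm) {
  .stopifnot_same_grid(vol, support)
  vals <- .neighborhood_values(vol, support, centre, radius_mm)
  if (length(vals) == 0L) return(NA_real_)
  m <- mean(vals)
  if (m <= 0) return(NA_real_)
  cv <- vol$data[centre[1], centre[2], centre[3]]
  100 * (m - cv) / m
}

#' Voxelwise PVS candidate detection
#'
#' Applies the three candidate criteria jointly to every voxel of the
#' eroded white-matter mask (see [pvs_criteria()]). Neighborhood statistics
#' use the brain mask as support, so local rank and contrast are computed
#' on the skull-stripped image before the white-matter membership test.
#'
#' @param vol Intensity [pvs_volume()] on the working grid.
#' @param eroded_wm Conditioned white-matter [pvs_mask()]
#'   (see [condition_wm_mask()]).
#' @param brain Brain-support [pvs_mask()].
#' @param crit A [pvs_criteria()].
#' @return An object of class `pvs_candidates`: list with `mask` (candidate
#'   [pvs_mask()]), `rank_fraction` and `contrast_pct` (3D arrays, `NA`
#'   outside the eroded white matter), and `criteria`.
#' @export
detect_candidates <- function(vol, eroded_wm, brain, crit = pvs_criteria()) {
  stopifnot(inherits(vol, "pvs_volume"), inherits(crit, "pvs_criteria"))
  .stopifnot_same_grid(vol, eroded_wm)
  .stopifnot_same_grid(vol, brain)
  d <- dim(vol$data)
  eval_mask <- eroded_wm$data != 0

  rank_off <- sphere_offsets(crit$rank_radius_mm, vol$spacing,
                             include_centre = FALSE)$offsets
  con_off <- sphere_offsets(crit$contrast_radius_mm, vol$spacing,
                            include_centre = FALSE)$offsets
  rk <- cpp_local_stats(as.numeric(vol$data), brain$data != 0,
                        eval_mask, rank_off, d)
  ct <- cpp_local_stats(as.numeric(vol$data), brain$data != 0,
                        eval_mask, con_off, d)
  rank_fraction <- array(rk$rank_fraction, d)
  contrast_pct <- array(ct$contrast_pct, d)

  cand <- eval_mask &
    !is.na(contrast_pct) & contrast_pct > crit$contrast_threshold_pct &
    !is.na(rank_fraction) & rank_fraction <= crit$rank_percentile / 100
  structure(list(mask = pvs_mask(cand, vol$spacing, note = vol$note),
                 rank_fraction = rank_fraction,
                 contrast_pct = contrast_pct,
                 criteria = crit),
            class = "pvs_candidates")
}

#' @export
print.pvs_candidates <- function(x, ...) {
  cat(sprintf("<pvs_candidates> %d candidate voxels on a %s grid\n",
              sum(x$mask$data), paste(dim(x$mask$data), collapse = "x")))
  invisible(x)
}

#' Cluster candidate voxels into putative PVS components
#'
#' Labels the candidate mask under 26-connectivity (3D corner-to-corner)
#' and keeps components whose volume `n_voxels * voxel_volume` is strictly
#' greater than `min_cluster_volume_mm3`; on the 0.5 mm grid the 1 mm^3
#' default therefore requires at least 9 voxels. Surviving components are
#' relabeled 1..n in scan order.
#'
#' @param cand A `pvs_candidates` object (or a candidate [pvs_mask()]).
#' @param crit A [pvs_criteria()].
#' @return An object of class `pvs_clusters`: list with `labels` (3D
#'   integer array, 0 = background), `n_clusters`, `spacing`, `criteria`.
#' @export
cluster_candidates <- function(cand, crit = pvs_criteria()) {
  mask <- if (inherits(cand, "pvs_candidates")) cand$mask else cand
  stopifnot(inherits(mask, "pvs_mask"), inherits(crit, "pvs_criteria"))
  d <- dim(mask$data)
  lab <- array(cpp_label_components(mask$data != 0, d, 26L), d)
  voxvol <- prod(mask$spacing)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes * voxvol > crit$min_cluster_volume_mm3)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  } else n <- 0L
  structure(list(labels = lab, n_clusters = n, spacing = mask$spacing,
                 criteria = crit),
            class = "pvs_clusters")
}

#' @export
print.pvs_clusters <- function(x, ...) {
  cat(sprintf("<pvs_clusters> %d clusters (> %g mm^3) on a %s grid\n",
              x$n_clusters, x$criteria$min_cluster_volume_mm3,
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Export putative PVS for manual review, and re-import decisions
#'
#' The detector's false alarms are traditionally removed by a trained
#' rater. `export_review_table` writes one TSV row per putative PVS with an
#' editable `decision` column defaulting to `"accept"`;
#' `apply_review_table` reads the (possibly edited) file back and drops the
#' records marked `"reject"` before metric computation.
#'
#' @param records Cluster descriptor table from [cluster_records()] (after
#'   [apply_morphological_constraints()]).
#' @param path TSV path to write / read.
#' @return `export_review_table` returns `path` invisibly;
#'   `apply_review_table` returns the filtered record table.
#' @export
export_review_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- data.frame(cluster_id = records$cluster_id,
                    x = records$cx_mm, y = records$cy_mm, z = records$cz_mm,
                    n_voxels = records$n_voxels,
                    volume_mm3 = records$volume_mm3,
                    length_mm = records$length_mm,
                    width_mm = records$width_mm,
                    linearity = records$linearity,
                    decision = "accept")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_review_table
#' @export
apply_review_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  rev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "decision") %in% names(rev)))
    stop("review file must contain cluster_id and decision columns",
         call. = FALSE)
  unknown <- setdiff(rev$cluster_id, records$cluster_id)
  if (length(unknown))
    stop("review file references unknown cluster labels: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  bad <- setdiff(rev$decision, c("accept", "reject"))
  if (length(bad))
    stop("decision must be accept/reject, got: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  rejected <- rev$cluster_id[rev$decision == "reject"]
  records[!records$cluster_id %in% rejected, , drop = FALSE]
}
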