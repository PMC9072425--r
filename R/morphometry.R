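#' Shape descriptors for one voxel cluster
#'
#' Summarises a connected voxel set by the eigen-structure of the
#' covariance of its voxel-centre physical coordinates. With eigenvalues
#' `l1 >= l2 >= l3`:
#' * `linearity = l1 / (l1 + l2 + l3)` — 1 for a perfect line, 1/3 for an
#'   isotropic blob;
#' * `length_mm` — extent of the projections onto the first principal axis
#'   plus one voxel edge (so a single voxel has physical size);
#' * `width_mm`  — likewise on the second principal axis.
#'
#' A single-voxel cluster has zero covariance and is defined to have
#' linearity 1 and length = width = one voxel edge. The voxel edge is the
#' geometric mean of the spacing (equal to the edge on the isotropic
#' working grid).
#'
#' @param voxels Integer `n x 3` matrix of 1-based voxel indices.
#' @param spacing Per-axis voxel size in mm.
#' @param cluster_id Optional integer label carried into the result.
#' @return One-row data.frame: `cluster_id`, `n_voxels`, `volume_mm3`,
#'   `length_mm`, `width_mm`, `linearity`, centroid `cx_mm, cy_mm, cz_mm`,
#'   and principal axis `ax_x, ax_y, ax_z` (unit vector).
#' @export
#' @examples
#' line <- cbind(1:10, 1, 1)
#' shape_descriptors(line, c(0.5, 0.5, 0.5))$linearity  # 1
shape_descriptors <- function(voxels, spacing, cluster_id = 1L) {
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  n <- nrow(voxels)
  stopifnot(n >= 1L, length(spacing) == 3L, all(spacing > 0))
  edge <- prod(spacing)^(1 / 3)
  xyz <- sweep(voxels - 1, 2, spacing, `*`)  # voxel-centre coordinates, mm
  centroid <- colMeans(xyz)

  if (n == 1L) {
    len <- wid <- edge
    lin <- 1
    axis1 <- c(1, 0, 0)
  } else {
    cc <- sweep(xyz, 2, centroid)
    cv <- crossprod(cc) / n
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    lin <- if (sum(ev) > 0) ev[1] / sum(ev) else 1
    axis1 <- eg$vectors[, 1]
    p1 <- cc %*% eg$vectors[, 1]
    p2 <- cc %*% eg$vectors[, 2]
    len <- diff(range(p1)) + edge
    wid <- diff(range(p2)) + edge
  }
  data.frame(cluster_id = as.integer(cluster_id), n_voxels = n,
             volume_mm3 = n * prod(spacing),
             length_mm = len, width_mm = wid, linearity = lin,
             cx_mm = centroid[1], cy_mm = centroid[2], cz_mm = centroid[3],
             ax_x = axis1[1], ax_y = axis1[2], ax_z = axis1[3],
             row.names = NULL)
}

#' Shape descriptors for every cluster in a label map
#'
#' @param clusters A `pvs_clusters` object from [cluster_candidates()].
#' @return Data.frame with one [shape_descriptors()] row per cluster,
#'   ordered by label.
#' @export
cluster_records <- function(clusters) {
  stopifnot(inherits(clusters, "pvs_clusters"))
  if (clusters$n_clusters == 0L)
    return(shape_descriptors(cbind(1, 1, 1), clusters$spacing)[0, ])
  idx <- which(clusters$labels > 0L, arr.ind = TRUE)
  lab <- clusters$labels[clusters$labels > 0L]
  do.call(rbind, lapply(seq_len(clusters$n_clusters), function(k) {
    shape_descriptors(idx[lab == k, , drop = FALSE], clusters$spacing, k)
  }))
}

#' Morphological constraint filter for putative PVS
#'
#' Keeps clusters that are strictly narrower than `max_width_mm` and have
#' linearity of at least `min_linearity` (inclusive); everything else —
#' isotropic blobs, wide sheets — is discarded. Record order is preserved.
#'
#' @param records Cluster descriptor table ([cluster_records()]).
#' @param crit A [pvs_criteria()].
#' @return The filtered record table.
#' @export
apply_morphological_constraints <- function(records, crit = pvs_criteria()) {
  stopifnot(is.data.frame(records), inherits(crit, "pvs_criteria"))
  keep <- records$width_mm < crit$max_width_mm &
    records$linearity >= crit$min_linearity
  records[keep, , drop = FALSE]
}

#' Subject-session PVS outcome metrics
#'
#' Reduces a filtered (and, if a review file was applied, reviewed) record
#' table to the five standard outcomes: total PVS volume (mL), total PVS
#' number, and the median per-PVS volume (mm^3), length (mm) and width
#' (mm). Medians of an even count are the mean of the two central order
#' statistics; with zero detected PVS the totals are 0 and the medians are
#' `NA` (propagated, not zero-filled, so downstream models drop those
#' sessions explicitly).
#'
#' @param records Filtered cluster descriptor table.
#' @param wm_volume_cm3 White-matter volume of this session (cm^3).
#' @param ventricular_volume_mL Lateral + third ventricular volume (mL).
#' @param tiv_mL Total intracranial volume (mL).
#' @param subject_id,session Identifiers carried into the row.
#' @return One-row data.frame of class `pvs_session_metrics` with columns
#'   `subject_id`, `session`, `total_pvs_volume_mL`, `total_pvs_number`,
#'   `median_pvs_volume_mm3`, `median_pvs_length_mm`, `median_pvs_width_mm`,
#'   `wm_volume_cm3`, `ventricular_volume_mL`, `tiv_mL`.
#' @export
session_metrics <- function(records, wm_volume_cm3 = NA_real_,
                            ventricular_volume_mL = NA_real_,
                            tiv_mL = NA_real_,
                            subject_id = NA_character_,
                            session = NA_character_) {
  stopifnot(is.data.frame(records))
  for (v in c(wm_volume_cm3, ventricular_volume_mL, tiv_mL))
    if (!is.na(v) && v < 0) stop("volumes must be non-negative", call. = FALSE)
  n <- nrow(records)
  out <- data.frame(
    subject_id = subject_id, session = session,
    total_pvs_volume_mL = if (n) sum(records$volume_mm3) / 1000 else 0,
    total_pvs_number = n,
    median_pvs_volume_mm3 = if (n) median(records$volume_mm3) else NA_real_,
    median_pvs_length_mm = if (n) median(records$length_mm) else NA_real_,
    median_pvs_width_mm = if (n) median(records$width_mm) else NA_real_,
    wm_volume_cm3 = wm_volume_cm3,
    ventricular_volume_mL = ventricular_volume_mL,
    tiv_mL = tiv_mL,
    stringsAsFactors = FALSE)
  class(out) <- c("pvs_session_metrics", class(out))
  out
}

#' Head-size normalization of session metrics
#'
#' For between-subject comparison, total PVS volume (converted to mm^3) and
#' total PVS number are divided by the subject's average pre-flight
#' white-matter volume (cm^3), and ventricular volume by the average
#' baseline total intracranial volume (mL/mL). The median per-PVS metrics
#' are size-invariant and are not normalized.
#'
#' @param m A [session_metrics()] row (or a data.frame of them).
#' @param baseline_wm_cm3 Average pre-flight white-matter volume (cm^3).
#' @param baseline_tiv_mL Average baseline total intracranial volume (mL).
#' @return `m` with columns `norm_total_pvs_volume` (mm^3 / cm^3 WM),
#'   `norm_total_pvs_number` (count / cm^3 WM) and
#'   `norm_ventricular_volume` (mL / mL TIV) appended.
#' @export
normalize_metrics <- function(m, baseline_wm_cm3, baseline_tiv_mL) {
  stopifnot(is.data.frame(m))
  if (any(!is.finite(c(baseline_wm_cm3, baseline_tiv_mL))) ||
      baseline_wm_cm3 <= 0 || baseline_tiv_mL <= 0)
    stop("normalization denominators must be positive", call. = FALSE)
  m$norm_total_pvs_volume <- m$total_pvs_volume_mL * 1000 / baseline_wm_cm3
  m$norm_total_pvs_number <- m$total_pvs_number / baseline_wm_cm3
  m$norm_ventricular_volume <- m$ventricular_volume_mL / baseline_tiv_mL
  m
}
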