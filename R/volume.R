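#' Intensity volumes and voxel masks
#'
#' A `pvs_volume` is a 3D scalar image plus its voxel spacing in mm; a
#' `pvs_mask` is the binary counterpart on the same grid. These are the
#' containers every pipeline stage works on. Voxel indices are 1-based (R
#' convention); the physical coordinate of voxel `i` along an axis is
#' `(i - 1) * spacing` mm, so voxel centres define the grid.
#'
#' @param data 3D numeric array (mask: values coercible to 0/1).
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param note Free-text provenance tag.
#' @return An object of class `pvs_volume` or `pvs_mask`: a list with
#'   elements `data`, `spacing`, `note`.
#' @export
#' @examples
#' v <- pvs_volume(array(rnorm(27), c(3, 3, 3)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$data)
pvs_volume <- function(data, spacing, note = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), "D", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, note = as.character(note)[1]),
            class = "pvs_volume")
}

#' @rdname pvs_volume
#' @export
pvs_mask <- function(data, spacing, note = "") {
  data <- as.array(data)
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0/1", call. = FALSE)
  v <- pvs_volume(data, spacing, note)
  class(v) <- c("pvs_mask", "pvs_volume")
  v
}

#' @export
print.pvs_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm%s\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

.stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(what, " are not on the same grid (shape/spacing mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti}. Spacing is taken from the header
#' `pixdim`; only 3D images are accepted. Masks are written as unsigned
#' 8-bit, intensities as 32-bit float.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol,mask A [pvs_volume()] / [pvs_mask()].
#' @return `read_volume`/`read_mask` return a `pvs_volume`/`pvs_mask`;
#'   the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D: ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (any(sp <= 0)) stop("non-positive voxel spacing in header: ", path,
                         call. = FALSE)
  pvs_volume(array(as.numeric(img), d), sp, note = basename(path))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  pvs_mask(v$data != 0, v$spacing, note = v$note)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pvs_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  dt <- if (inherits(vol, "pvs_mask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pvs_mask"))
  write_volume(mask, path)
}

#' Reslice a volume to an isotropic grid
#'
#' Resamples onto a `target_mm` isotropic grid aligned to the input's first
#' voxel centre. The output size per axis is
#' `round(n_in * spacing_in / target_mm)`, preserving the physical
#' field of view to within one output voxel. Intensities are interpolated
#' trilinearly; masks must use `mode = "nearest"`, which preserves binary
#' labels. Detection operates on the 0.5 mm isotropic working grid.
#'
#' @param vol A [pvs_volume()] (or [pvs_mask()] with `mode = "nearest"`).
#' @param target_mm Target isotropic voxel size in mm (> 0); default 0.5.
#' @param mode `"linear"` (intensities) or `"nearest"` (labels/masks).
#' @return A `pvs_volume` (or `pvs_mask`) on the isotropic grid.
#' @export
#' @examples
#' v <- pvs_volume(array(1, c(10, 10, 10)), c(1, 1, 1))
#' dim(reslice_isotropic(v, 0.5)$data)  # 20 20 20
reslice_isotropic <- function(vol, target_mm = 0.5,
                              mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "pvs_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a single positive length in mm", call. = FALSE)
  is_mask <- inherits(vol, "pvs_mask")
  if (is_mask && mode != "nearest")
    stop("masks must be resliced with mode = \"nearest\"", call. = FALSE)

  din <- dim(vol$data)
  dout <- pmax(1L, as.integer(round(din * vol$spacing / target_mm)))
  # continuous input index of each output voxel centre, per axis
  ax <- lapply(1:3, function(a) {
    (seq_len(dout[a]) - 1) * target_mm / vol$spacing[a] + 1
  })

  if (mode == "nearest") {
    ia <- lapply(1:3, function(a) pmin(pmax(round(ax[[a]]), 1L), din[a]))
    out <- vol$data[ia[[1]], ia[[2]], ia[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 1L), din[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, din[a]))
    w <- lapply(1:3, function(a) pmin(pmax(ax[[a]] - lo[[a]], 0), 1))
    out <- array(0, dout)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wx <- if (cx) w[[1]] else 1 - w[[1]]
      wy <- if (cy) w[[2]] else 1 - w[[2]]
      wz <- if (cz) w[[3]] else 1 - w[[3]]
      wt <- outer(outer(wx, wy), wz)
      if (all(wt == 0)) next
      corner <- vol$data[if (cx) hi[[1]] else lo[[1]],
                         if (cy) hi[[2]] else lo[[2]],
                         if (cz) hi[[3]] else lo[[3]], drop = FALSE]
      out <- out + wt * corner
    }
  }
  sp <- rep(target_mm, 3)
  if (is_mask) pvs_mask(out != 0, sp, note = vol$note)
  else pvs_volume(out, sp, note = vol$note)
}

## 6-connected (face-adjacent) unit-ball morphology via array shifts.
.shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.dilate6 <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    m <- m | .shift3(m, 1, 0, 0) | .shift3(m, -1, 0, 0) |
      .shift3(m, 0, 1, 0) | .shift3(m, 0, -1, 0) |
      .shift3(m, 0, 0, 1) | .shift3(m, 0, 0, -1)
  }
  m
}

.erode6 <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    m <- m & .shift3(m, 1, 0, 0, TRUE) & .shift3(m, -1, 0, 0, TRUE) &
      .shift3(m, 0, 1, 0, TRUE) & .shift3(m, 0, -1, 0, TRUE) &
      .shift3(m, 0, 0, 1, TRUE) & .shift3(m, 0, 0, -1, TRUE)
  }
  m
}
# erosion treats out-of-volume as foreground so a mask touching the border
# is not eaten from outside the field of view

.fill_holes <- function(m) {
  array(cpp_fill_holes(as.logical(m), dim(m)), dim(m))
}

#' Condition a white-matter mask for PVS detection
#'
#' Cleans a resliced white-matter mask before detection: dilate by two
#' voxels, fill interior holes, then erode by two voxels. The closing
#' bridges small gaps and fills cavities left by tissue segmentation; the
#' final erosion pulls the mask away from tissue boundaries to avoid
#' partial-volume voxels. "Two voxels" means two iterations of a
#' face-connected (6-neighbour) unit ball on the working grid; holes are
#' background components not 6-connected to the volume border.
#'
#' @param wm A binary [pvs_mask()] on the working (0.5 mm isotropic) grid.
#' @return The conditioned `pvs_mask` on the same grid.
#' @export
condition_wm_mask <- function(wm) {
  stopifnot(inherits(wm, "pvs_mask"))
  m <- wm$data != 0
  if (!any(m)) {
    warning("empty white-matter mask")
    return(wm)
  }
  m <- .erode6(.fill_holes(.dilate6(m, 2L)), 2L)
  pvs_mask(m, wm$spacing, note = wm$note)
}

#' Integer voxel offsets within a physical sphere
#'
#' Enumerates all integer displacements `(dx, dy, dz)` whose physical length
#' `||(dx, dy, dz) * spacing||` is at most `radius_mm` (inclusive). These
#' define the spherical neighborhoods used by the detector: a 3 mm sphere
#' for the intensity-rank criterion and a 4 mm sphere for the contrast
#' criterion. Distances are between voxel centres.
#'
#' @param radius_mm Sphere radius in mm (>= 0).
#' @param spacing Per-axis voxel size in mm.
#' @param include_centre Keep the `(0,0,0)` offset? Default `TRUE`; the
#'   detector drops it because neighborhood statistics exclude the centre.
#' @return List with `radius_mm`, `spacing` and `offsets`, an `n x 3`
#'   integer matrix symmetric under negation.
#' @export
#' @examples
#' nrow(sphere_offsets(0, c(0.5, 0.5, 0.5))$offsets)  # 1: just the centre
sphere_offsets <- function(radius_mm, spacing, include_centre = TRUE) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm < 0)
    stop("radius_mm must be a single non-negative length", call. = FALSE)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  off <- as.matrix(g[keep, , drop = FALSE])
  if (!include_centre) off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  dimnames(off) <- NULL
  list(radius_mm = radius_mm, spacing = spacing,
       offsets = matrix(as.integer(off), ncol = 3))
}
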