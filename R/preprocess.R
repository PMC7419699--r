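#' 3D median filter with a spherical neighbourhood
#'
#' Replaces each voxel by the median of the Euclidean ball of the given
#' radius (the convention of the common image-processing suites, where the
#' filter is parameterised by "radius").  `NaN` voxels stay `NaN` so that
#' phase masks survive filtering, and `NaN` neighbours are excluded from
#' the median sample; the neighbourhood is truncated at the boundary.
#' Radius 0 returns the volume unchanged.
#'
#' @param vol a [bone_volume()].
#' @param radius_vox neighbourhood radius in voxels (integer >= 0).
#' @return the filtered [bone_volume()].
#' @export
median_filter3d <- function(vol, radius_vox) {
  .check_scalar(radius_vox, "radius_vox", lower = 0, integer = TRUE)
  out <- array(.cpp_median3d(as.numeric(vol), dim(vol), as.integer(radius_vox),
                             FALSE), dim(vol))
  .rewrap(out, vol)
}

#' IsoData automatic threshold
#'
#' Iterates `t <- (mean(values < t) + mean(values >= t)) / 2` from the
#' global mean until the update is below `tol` gray levels, the classic
#' intermeans fixed point used to binarise bone from background.
#' `NaN` voxels are ignored.
#'
#' @param vol a [bone_volume()] or numeric vector/array.
#' @param tol convergence tolerance in gray levels.
#' @return the threshold gray value: voxels `>= t` are the bright class.
#' @export
isodata_threshold <- function(vol, tol = 0.5) {
  v <- as.numeric(vol)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    .stopf("IsoData threshold undefined: volume is constant")
  t <- mean(v)
  for (i in 1:200) {
    lo <- v[v < t]
    hi <- v[v >= t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Align the screw axis with +z
#'
#' Estimates the screw's long axis as the first principal component of the
#' screw-mask voxel coordinates and rotates the volume (trilinear
#' resampling about the volume centre) so that this axis maps onto +z.
#' Refuses masks without a clearly dominant axis.
#'
#' @param vol a [bone_volume()].
#' @param screw_mask logical array congruent with `vol`; defaults to the
#'   mask attached to the volume.
#' @param min_axis_ratio minimum ratio of first to second principal
#'   standard deviation for the axis to count as well defined.
#' @return list with `volume` (rotated) and `rotation` (3x3 matrix applied
#'   to `(z, y, x)` coordinate vectors) and `angle_deg` (rotation angle).
#' @export
align_screw_axis <- function(vol, screw_mask = attr(vol, "screw_mask"),
                             min_axis_ratio = 1.2) {
  if (is.null(screw_mask) || !any(screw_mask))
    .stopf("screw mask is empty")
  idx <- which(array(screw_mask, dim(vol)))
  d <- dim(vol)
  z <- (idx - 1) %% d[1]
  y <- ((idx - 1) %/% d[1]) %% d[2]
  x <- (idx - 1) %/% (d[1] * d[2])
  co <- cbind(z, y, x)
  pc <- eigen(stats::cov(co), symmetric = TRUE)
  sdevs <- sqrt(pmax(pc$values, 0))
  if (sdevs[2] <= 0 || sdevs[1] / sdevs[2] < min_axis_ratio)
    .stopf("screw axis ill-defined: principal axis ratio %.2f < %.2f",
           ifelse(sdevs[2] > 0, sdevs[1] / sdevs[2], Inf), min_axis_ratio)
  axis <- pc$vectors[, 1]
  if (axis[1] < 0) axis <- -axis  # orient towards +z
  target <- c(1, 0, 0)
  v <- c(axis[2] * target[3] - axis[3] * target[2],
         axis[3] * target[1] - axis[1] * target[3],
         axis[1] * target[2] - axis[2] * target[1])
  s <- sqrt(sum(v^2))
  ang <- atan2(s, sum(axis * target))
  R <- if (s < 1e-12) diag(3) else .rotation_matrix(v / s, ang * 180 / pi)
  ctr <- (d - 1) / 2
  idx_all <- cbind(as.vector(slice.index(array(0, d), 1)) - 1,
                   as.vector(slice.index(array(0, d), 2)) - 1,
                   as.vector(slice.index(array(0, d), 3)) - 1)
  src <- t(solve(R) %*% (t(idx_all) - ctr) + ctr)
  out <- array(.cpp_trilinear(as.numeric(vol), d, src), d)
  new_mask <- NULL
  mk <- .cpp_trilinear(as.numeric(screw_mask), d, src)
  new_mask <- array(!is.na(mk) & mk >= 0.5, d)
  list(volume = .rewrap(out, vol, screw_mask = new_mask),
       rotation = R, angle_deg = ang * 180 / pi)
}

#' Mask background and screw phases to NaN
#'
#' Sets voxels below `t_background` (air / pore space outside the analysed
#' phase) and at or above `t_screw` (implant metal) to `NaN`, so they are
#' excluded from the DVC correlation windows; unmasked intensities are
#' never altered.
#'
#' @param vol a [bone_volume()].
#' @param t_background,t_screw gray thresholds, `t_background < t_screw`.
#' @return list with `volume` (masked) and `masks` (list
#'   `background_mask`, `screw_mask`, `thresholds`).
#' @export
mask_phases <- function(vol, t_background, t_screw) {
  .check_scalar(t_background, "t_background")
  .check_scalar(t_screw, "t_screw")
  if (t_background >= t_screw)
    .stopf("t_background (%g) must be below t_screw (%g)",
           t_background, t_screw)
  a <- .as_array(vol)
  bg <- !is.nan(a) & a < t_background
  sc <- !is.nan(a) & a >= t_screw
  a[bg | sc] <- NaN
  list(volume = .rewrap(a, vol),
       masks = list(background_mask = bg, screw_mask = sc,
                    thresholds = c(t_background = t_background,
                                   t_screw = t_screw)))
}
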