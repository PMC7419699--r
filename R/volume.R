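#' Tomographic volume container
#'
#' A `bone_volume` is a 3D numeric array with axis order `[z, y, x]` (the
#' first index runs along the screw / pullout axis) plus the physical voxel
#' size in micrometres.  Masked voxels (background, implant metal, voxels
#' mapped from outside the grid by a warp) are `NaN` and are excluded from
#' every downstream computation.  Intensities are dimensionless gray values;
#' all coordinates are held in voxel units internally and converted to
#' micrometres only when results are reported.
#'
#' @param data numeric 3D array, dim `(nz, ny, nx)`, at least 2 voxels per
#'   axis.
#' @param voxel_size_um physical voxel edge length in micrometres (> 0).
#' @param screw_mask optional logical array congruent with `data` marking
#'   implant voxels.
#' @return An object of class `bone_volume`: the array with attributes
#'   `voxel_size_um` and (optionally) `screw_mask`.
#' @examples
#' v <- bone_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), voxel_size_um = 25)
#' dim(v)
#' @export
bone_volume <- function(data, voxel_size_um = 25, screw_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    .stopf("volume needs at least 2 voxels per axis, got %s",
           paste(dim(data), collapse = "x"))
  .check_scalar(voxel_size_um, "voxel_size_um", lower = .Machine$double.eps)
  storage.mode(data) <- "double"
  attr(data, "voxel_size_um") <- as.numeric(voxel_size_um)
  if (!is.null(screw_mask)) {
    if (!identical(dim(screw_mask), dim(data)))
      .stopf("'screw_mask' must be congruent with 'data'")
    attr(data, "screw_mask") <- screw_mask
  }
  class(data) <- c("bone_volume", "array")
  data
}

#' @export
print.bone_volume <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  n_nan <- sum(is.nan(x))
  cat(sprintf("<bone_volume> %d x %d x %d voxels (z, y, x), %.3g um/voxel\n",
              d[1], d[2], d[3], vs))
  cat(sprintf("  extent: %.2f x %.2f x %.2f mm\n",
              d[1] * vs / 1000, d[2] * vs / 1000, d[3] * vs / 1000))
  fin <- x[is.finite(x)]
  if (length(fin))
    cat(sprintf("  intensity: [%.4g, %.4g], masked (NaN): %d (%.1f%%)\n",
                min(fin), max(fin), n_nan, 100 * n_nan / length(x)))
  if (!is.null(attr(x, "screw_mask")))
    cat(sprintf("  screw mask: %d voxels\n", sum(attr(x, "screw_mask"))))
  invisible(x)
}

#' Voxel size of a volume
#' @param vol a [bone_volume()].
#' @return voxel edge length in micrometres.
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size_um")
  if (is.null(vs)) .stopf("not a bone_volume: no voxel size attribute")
  vs
}

# rebuild a volume around a new data array, keeping metadata
.rewrap <- function(data, template, screw_mask = attr(template, "screw_mask")) {
  bone_volume(data, voxel_size_um = voxel_size(template),
              screw_mask = screw_mask)
}

.as_array <- function(vol) {
  a <- unclass(vol)
  attr(a, "voxel_size_um") <- NULL
  attr(a, "screw_mask") <- NULL
  a
}

#' Sample a volume at fractional voxel coordinates
#'
#' Trilinear interpolation at 0-based fractional `(z, y, x)` positions.
#' Positions outside the grid, or whose 8-voxel interpolation cell touches a
#' `NaN` voxel, return `NaN`.  Integer positions read the voxel exactly.
#'
#' @param vol a [bone_volume()].
#' @param pts numeric matrix, one row per point, columns `(z, y, x)` in
#'   0-based voxel coordinates.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, pts) {
  if (!is.matrix(pts) || ncol(pts) != 3L)
    .stopf("'pts' must be an n x 3 matrix of (z, y, x) positions")
  .cpp_trilinear(as.numeric(vol), dim(vol), pts)
}
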