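#' DVC error report from a repeated-scan experiment
#'
#' Quantifies systematic and random measurement error from a DVC run
#' between two scans of the same, unmoved object: for each displacement
#' component the mean over ok nodes (accuracy) and the standard deviation
#' (precision), converted to micrometres; for strain, the absolute values
#' of all six Green-Lagrange components are pooled over valid elements and
#' their mean (accuracy) and standard deviation (precision) reported in
#' microstrain.  Standard deviations are population ones (divide by n).
#'
#' @param field a `dvc_field` between the two repeated scans.
#' @param strain the matching `strain_field`; `NULL` to skip strain error.
#' @param voxel_size_um voxel size (um); defaults to the field's.
#' @return an `error_report` list: `displacement` (per-component data
#'   frame with `accuracy_um`, `precision_um`), `strain`
#'   (`accuracy_ue`, `precision_ue`), and the node/element counts used.
#' @export
dvc_error_report <- function(field, strain = NULL,
                             voxel_size_um = field$voxel_size_um) {
  ok <- field$status == "ok"
  if (!any(ok)) .stopf("no ok nodes: error report undefined")
  u <- field$u[ok, , drop = FALSE]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  disp <- data.frame(component = c("u_z", "u_y", "u_x"),
                     accuracy_um = colMeans(u) * voxel_size_um,
                     precision_um = apply(u, 2, pop_sd) * voxel_size_um,
                     row.names = NULL)
  strain_err <- NULL
  n_elem <- 0L
  if (!is.null(strain)) {
    okk <- strain$status == "ok"
    n_elem <- sum(okk)
    if (n_elem > 0) {
      pooled <- abs(as.vector(strain$E[okk, , drop = FALSE])) * 1e6
      strain_err <- c(accuracy_ue = mean(pooled),
                      precision_ue = pop_sd(pooled))
    }
  }
  structure(list(displacement = disp, strain = strain_err,
                 n_nodes = sum(ok), n_elements = n_elem,
                 voxel_size_um = voxel_size_um),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("DVC error report (%d nodes, %d elements)\n",
              x$n_nodes, x$n_elements))
  cat("displacement error (um):\n")
  print(x$displacement, digits = 4)
  if (!is.null(x$strain))
    cat(sprintf("strain error (pooled |e_ij|): accuracy %.0f ue, precision %.0f ue\n",
                x$strain[["accuracy_ue"]], x$strain[["precision_ue"]]))
  invisible(x)
}

#' Bone volume fraction in a cylindrical peri-implant ROI
#'
#' Measures BV/TV in the annular cylinder extending radially from the
#' screw maximal diameter by `radial_extent_um`, over an axial span
#' centred in the stack: `TV` counts voxels with
#' `screw_max_radius < r <= screw_max_radius + radial_extent` and
#' `|z - z0| <= axial_span / 2`; `BV` counts the solid voxels among them.
#' Membership is decided on voxel-centre coordinates.  A ROI that does
#' not fit inside the volume is refused (no partial ROIs).
#'
#' @param vol_binary logical (or 0/1) array of solid voxels, or a
#'   [bone_volume()] already binarised.
#' @param screw_max_radius_um radius of the screw maximal diameter (um).
#' @param radial_extent_um radial thickness of the ROI shell (um,
#'   default 500).
#' @param axial_span_um axial length of the ROI (um, default 2200,
#'   spanning the threaded region).
#' @param voxel_size_um voxel size (um); taken from the volume if absent.
#' @param center_zyx optional 0-based `(z, y, x)` axis point; defaults to
#'   the volume centre.
#' @return a `morphometry` list with `BV`, `TV` (voxel counts times voxel
#'   volume, mm^3), `bvtv`, and the ROI definition.
#' @export
bvtv_cylinder <- function(vol_binary, screw_max_radius_um,
                          radial_extent_um = 500, axial_span_um = 2200,
                          voxel_size_um = NULL, center_zyx = NULL) {
  vs <- voxel_size_um %||% attr(vol_binary, "voxel_size_um")
  if (is.null(vs)) .stopf("'voxel_size_um' is required")
  .check_scalar(screw_max_radius_um, "screw_max_radius_um", lower = 0)
  .check_scalar(radial_extent_um, "radial_extent_um", lower = 1e-9)
  .check_scalar(axial_span_um, "axial_span_um", lower = 1e-9)
  d <- dim(vol_binary)
  ctr <- center_zyx %||% ((d - 1) / 2)
  r_in <- screw_max_radius_um / vs
  r_out <- (screw_max_radius_um + radial_extent_um) / vs
  half_span <- axial_span_um / 2 / vs
  if (ctr[2] - r_out < 0 || ctr[2] + r_out > d[2] - 1 ||
      ctr[3] - r_out < 0 || ctr[3] + r_out > d[3] - 1 ||
      ctr[1] - half_span < 0 || ctr[1] + half_span > d[1] - 1)
    .stopf("cylindrical ROI (outer radius %.1f vox, span %.1f vox) leaves the volume",
           r_out, 2 * half_span)
  r2 <- outer((seq_len(d[2]) - 1 - ctr[2])^2,
              (seq_len(d[3]) - 1 - ctr[3])^2, `+`)
  in_ring <- r2 > r_in^2 & r2 <= r_out^2
  zs <- which(abs(seq_len(d[1]) - 1 - ctr[1]) <= half_span)
  solid <- array(vol_binary, d)
  tv <- 0L
  bv <- 0L
  for (z in zs) {
    sl <- solid[z, , ][in_ring]
    tv <- tv + length(sl)
    bv <- bv + sum(sl != 0, na.rm = TRUE)
  }
  voxvol_mm3 <- (vs / 1000)^3
  structure(list(BV = bv * voxvol_mm3, TV = tv * voxvol_mm3,
                 bvtv = bv / tv, n_solid = bv, n_total = tv,
                 roi = list(screw_max_radius_um = screw_max_radius_um,
                            radial_extent_um = radial_extent_um,
                            axial_span_um = axial_span_um)),
            class = "morphometry")
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf("peri-implant morphometry: BV/TV = %.1f%% (BV %.3f mm^3 / TV %.3f mm^3)\n",
              100 * x$bvtv, x$BV, x$TV))
  cat(sprintf("  ROI: %g um radial shell from screw radius %g um, %g um axial span\n",
              x$roi$radial_extent_um, x$roi$screw_max_radius_um,
              x$roi$axial_span_um))
  invisible(x)
}

#' Screw insertion geometry relative to the tibial plateau
#'
#' From 2D annotations on a radiograph: the screw-plateau distance is the
#' orthogonal projection distance of the screw-thread midpoint onto the
#' tibial plateau line, and the tilt is the acute angle between the screw
#' long axis and the plateau line.
#'
#' @param screw_axis_2d list `(point =, dir =)` of 2-vectors defining the
#'   screw long axis.
#' @param plateau_2d list `(point =, dir =)` defining the plateau line.
#' @param thread_mid 2-vector: midpoint of the screw threads.
#' @param units_per_mm annotation units per millimetre (default 1:
#'   annotations already in mm).
#' @return a `geometry_measure` list with `plateau_distance_mm` and
#'   `tilt_deg`.
#' @export
screw_plateau_geometry <- function(screw_axis_2d, plateau_2d, thread_mid,
                                   units_per_mm = 1) {
  dirs <- list(screw = screw_axis_2d$dir, plateau = plateau_2d$dir)
  for (nm in names(dirs))
    if (is.null(dirs[[nm]]) || sqrt(sum(dirs[[nm]]^2)) == 0)
      .stopf("zero-length direction vector for the %s line", nm)
  ds <- dirs$screw / sqrt(sum(dirs$screw^2))
  dp <- dirs$plateau / sqrt(sum(dirs$plateau^2))
  cosang <- abs(sum(ds * dp))
  tilt <- acos(pmin(cosang, 1)) * 180 / pi
  rel <- thread_mid - plateau_2d$point
  dist <- abs(rel[1] * dp[2] - rel[2] * dp[1]) / units_per_mm
  structure(list(plateau_distance_mm = dist, tilt_deg = tilt),
            class = "geometry_measure")
}

#' @export
print.geometry_measure <- function(x, ...) {
  cat(sprintf("screw-plateau distance %.2f mm, tilt %.1f deg\n",
              x$plateau_distance_mm, x$tilt_deg))
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation between two measurement series, with `r^2`
#' and the two-sided p value from the t transform on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, finite, with nonzero
#'   variance.
#' @return list with `r`, `r2`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .stopf("'x' and 'y' lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) .stopf("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
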