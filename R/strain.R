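#' Median-smooth a displacement field on the node grid
#'
#' Componentwise median filter over the cubic `(2r+1)^3` node
#' neighbourhood (radius counted in grid nodes), applied to the
#' displacement field before strain computation.  Failed nodes (status
#' not `ok`) are excluded from every neighbourhood sample and keep their
#' status; their displacement stays undefined.  Nodes whose window would
#' be truncated by the grid edge keep their original value: a truncated
#' median is biased on smooth fields, and this rule preserves the
#' exactness of affine displacement fields at every element, boundary
#' elements included.
#'
#' @param field a `dvc_field` from [run_dvc()].
#' @param radius_vox neighbourhood radius in nodes (integer >= 0).
#' @return the smoothed `dvc_field`.
#' @export
smooth_displacements <- function(field, radius_vox = 1) {
  .check_scalar(radius_vox, "radius_vox", lower = 0, integer = TRUE)
  if (radius_vox == 0) return(field)
  gd <- field$grid_dims
  r <- as.integer(radius_vox)
  interior <- function(n) {
    i <- rep(FALSE, n)
    if (n > 2 * r) i[(r + 1):(n - r)] <- TRUE
    i
  }
  full <- outer(outer(interior(gd[1]), interior(gd[2]), `&`),
                interior(gd[3]), `&`)
  u <- field$u
  for (c in 1:3) {
    a <- array(u[, c], gd)  # nodes run z fastest, matching array layout
    sm <- .cpp_median3d(as.numeric(a), gd, r, TRUE)
    u[full, c] <- sm[full]
  }
  field$u <- u
  field
}

# corner offsets of the trilinear hexahedron, z fastest; sign s_b = 2*corner-1
.hex_corners <- expand.grid(cz = 0:1, cy = 0:1, cx = 0:1)

#' Deformation gradient of one hexahedral element
#'
#' `F = I + du/dX` at the element centre, from trilinear (8-node
#' isoparametric hexahedron) shape-function derivatives over the element's
#' corner nodes; with node spacing `h` the centre derivative reduces to
#' `du_a/dX_b = sum_corners s_b u_a / (4 h)`.  Displacements and node
#' spacing are both in voxels, so `F` is dimensionless.  `F` rows/columns
#' are ordered `(x, y, z)`.
#'
#' @param field a `dvc_field`.
#' @param element integer 3-vector: 1-based node-grid index `(i, j, k)`
#'   (z, y, x axes) of the element's lower corner node.
#' @return 3x3 deformation gradient, or an error if a corner node failed.
#' @export
deformation_gradient <- function(field, element) {
  gd <- field$grid_dims
  if (any(element < 1) || any(element + 1 > gd))
    .stopf("element out of the node grid")
  h <- field$cfg$node_spacing_vox
  Fm <- diag(3)
  uc <- matrix(0, 8, 3)
  for (k in 1:8) {
    co <- .hex_corners[k, ]
    i <- (element[1] + co$cz) + gd[1] * (element[2] - 1 + co$cy) +
      gd[1] * gd[2] * (element[3] - 1 + co$cx)
    uc[k, ] <- field$u[i, ]
  }
  if (any(!is.finite(uc))) .stopf("element has a failed corner node")
  for (a in 1:3)  # displacement component, (x, y, z) order
    for (b in 1:3) {  # derivative axis, (x, y, z) order
      s <- 2 * .hex_corners[[4 - b]] - 1  # cx for b=1, cy for b=2, cz for b=3
      Fm[a, b] <- Fm[a, b] + sum(s * uc[, 4 - a]) / (4 * h)
    }
  Fm
}

#' Green-Lagrange strain tensor from a deformation gradient
#'
#' `E = (F'F - I) / 2`, zero for any rigid motion.  Returned as the six
#' stored components `(exx, eyy, ezz, eyx, ezx, ezy)` with the symmetric
#' shears (`eyx = exy`, etc.).
#'
#' @param F 3x3 deformation gradient, `(x, y, z)` ordering.
#' @return named numeric vector of the six strain components.
#' @export
green_lagrange <- function(F) {
  E <- (t(F) %*% F - diag(3)) / 2
  c(exx = E[1, 1], eyy = E[2, 2], ezz = E[3, 3],
    eyx = E[2, 1], ezx = E[3, 1], ezy = E[3, 2])
}

#' Volumetric strain
#'
#' Local relative volume change `det(F) - 1`; 0 for rigid motion,
#' `1.01^3 - 1` for a uniform 1 percent dilation.
#'
#' @param F 3x3 deformation gradient.
#' @return scalar volumetric strain.
#' @export
volumetric_strain <- function(F) {
  det(F) - 1
}

#' Maximum shear strain
#'
#' The scalar shear measure
#' `gamma = (1/3) sqrt(2 (exx-eyy)^2 + 2 (exx-ezz)^2 + 2 (eyy-ezz)^2 +
#' 12 eyx^2 + 12 ezx^2 + 12 ezy^2)`: non-negative, and zero exactly for
#' isotropic strain states.
#'
#' @param eps named vector (or list) of the six Green-Lagrange components
#'   as returned by [green_lagrange()].
#' @return scalar `gamma >= 0`.
#' @export
max_shear <- function(eps) {
  e <- as.list(eps)
  sqrt(2 * (e$exx - e$eyy)^2 + 2 * (e$exx - e$ezz)^2 +
         2 * (e$eyy - e$ezz)^2 +
         12 * e$eyx^2 + 12 * e$ezx^2 + 12 * e$ezy^2) / 3
}

#' Compute the strain field from a displacement field
#'
#' The full post-processing chain: median smoothing of the node
#' displacements (default radius 1 node), then per hexahedral element of
#' the node grid the deformation gradient at the element centre, its
#' Green-Lagrange components, volumetric strain `det(F) - 1`, and the
#' maximum shear strain.  Elements with any failed corner node are
#' flagged and carry `NaN`.
#'
#' @param field a `dvc_field` from [run_dvc()].
#' @param smooth_radius median-filter radius in nodes (0 disables).
#' @return an object of class `strain_field`: element-centre coordinates
#'   (voxels), the six strain components `E`, `vol_strain`, `max_shear`
#'   and per-element status.  Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @export
run_strain <- function(field, smooth_radius = 1) {
  if (!inherits(field, "dvc_field")) .stopf("'field' must be a dvc_field")
  if (sum(field$status == "ok") < 8)
    .stopf("fewer than 8 valid nodes: no element can be formed")
  field <- smooth_displacements(field, smooth_radius)
  gd <- field$grid_dims
  ed <- gd - 1L
  if (any(ed < 1L)) .stopf("node grid too small for elements")
  h <- field$cfg$node_spacing_vox
  U <- lapply(1:3, function(c) array(field$u[, c], gd))  # u_z, u_y, u_x
  iz <- seq_len(ed[1]); iy <- seq_len(ed[2]); ix <- seq_len(ed[3])
  ne <- prod(ed)
  # du[a][b]: component a (x,y,z), derivative axis b (x,y,z)
  du <- array(0, c(ne, 3, 3))
  comp_map <- c(3L, 2L, 1L)  # (x, y, z) -> u column/grid-array index
  for (k in 1:8) {
    co <- .hex_corners[k, ]
    for (a in 1:3) {
      ua <- U[[comp_map[a]]][iz + co$cz, iy + co$cy, ix + co$cx]
      for (b in 1:3) {
        s <- 2 * co[[4 - b]] - 1  # cx, cy, cz for b = 1, 2, 3
        du[, a, b] <- du[, a, b] + s * as.vector(ua) / (4 * h)
      }
    }
  }
  Fm <- du
  for (a in 1:3) Fm[, a, a] <- Fm[, a, a] + 1
  # E = (F'F - I)/2 per element
  Eab <- function(a, b) {
    (Fm[, 1, a] * Fm[, 1, b] + Fm[, 2, a] * Fm[, 2, b] +
       Fm[, 3, a] * Fm[, 3, b] - (a == b)) / 2
  }
  E <- cbind(exx = Eab(1, 1), eyy = Eab(2, 2), ezz = Eab(3, 3),
             eyx = Eab(2, 1), ezx = Eab(3, 1), ezy = Eab(3, 2))
  detF <- Fm[, 1, 1] * (Fm[, 2, 2] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 2]) -
    Fm[, 1, 2] * (Fm[, 2, 1] * Fm[, 3, 3] - Fm[, 2, 3] * Fm[, 3, 1]) +
    Fm[, 1, 3] * (Fm[, 2, 1] * Fm[, 3, 2] - Fm[, 2, 2] * Fm[, 3, 1])
  gamma <- sqrt(2 * (E[, "exx"] - E[, "eyy"])^2 +
                  2 * (E[, "exx"] - E[, "ezz"])^2 +
                  2 * (E[, "eyy"] - E[, "ezz"])^2 +
                  12 * (E[, "eyx"]^2 + E[, "ezx"]^2 + E[, "ezy"]^2)) / 3
  failed <- !is.finite(E[, 1]) | !is.finite(detF)
  E[failed, ] <- NaN
  detF[failed] <- NaN
  gamma[failed] <- NaN
  ctr <- as.matrix(expand.grid(
    z = (field$axes$z[iz] + field$axes$z[iz + 1]) / 2,
    y = (field$axes$y[iy] + field$axes$y[iy + 1]) / 2,
    x = (field$axes$x[ix] + field$axes$x[ix + 1]) / 2,
    KEEP.OUT.ATTRS = FALSE))
  structure(list(centers = ctr, grid_dims = ed,
                 axes = list(z = (field$axes$z[iz] + field$axes$z[iz + 1]) / 2,
                             y = (field$axes$y[iy] + field$axes$y[iy + 1]) / 2,
                             x = (field$axes$x[ix] + field$axes$x[ix + 1]) / 2),
                 E = E, vol_strain = detF - 1, max_shear = gamma,
                 status = factor(ifelse(failed, "failed", "ok"),
                                 levels = c("ok", "failed")),
                 node_spacing_vox = h,
                 voxel_size_um = field$voxel_size_um),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d elements (%s), %d valid\n",
              nrow(x$E), paste(x$grid_dims, collapse = " x "),
              sum(x$status == "ok")))
  ok <- x$status == "ok"
  if (any(ok)) {
    cat(sprintf("  vol strain: median %.5f [%.5f, %.5f]\n",
                median(x$vol_strain[ok]), min(x$vol_strain[ok]),
                max(x$vol_strain[ok])))
    cat(sprintf("  max shear : median %.5f, max %.5f\n",
                median(x$max_shear[ok]), max(x$max_shear[ok])))
  }
  invisible(x)
}

#' @export
summary.strain_field <- function(object, ...) {
  ok <- object$status == "ok"
  qs <- function(v) c(min = min(v), q25 = unname(quantile(v, .25)),
                      median = median(v), q75 = unname(quantile(v, .75)),
                      max = max(v))
  comps <- cbind(object$E, vol_strain = object$vol_strain,
                 max_shear = object$max_shear)[ok, , drop = FALSE]
  out <- list(n_elements = length(object$status), n_valid = sum(ok),
              stats = if (any(ok)) t(apply(comps, 2, qs)) else NULL)
  class(out) <- "summary.strain_field"
  out
}

#' @export
print.summary.strain_field <- function(x, ...) {
  cat(sprintf("strain field: %d elements, %d valid\n",
              x$n_elements, x$n_valid))
  if (!is.null(x$stats)) print(round(x$stats, 6))
  invisible(x)
}

#' @export
as.data.frame.strain_field <- function(x, ...) {
  vs <- x$voxel_size_um
  data.frame(z_vox = x$centers[, 1], y_vox = x$centers[, 2],
             x_vox = x$centers[, 3],
             z_um = x$centers[, 1] * vs, y_um = x$centers[, 2] * vs,
             x_um = x$centers[, 3] * vs,
             exx = x$E[, "exx"], eyy = x$E[, "eyy"], ezz = x$E[, "ezz"],
             eyx = x$E[, "eyx"], ezx = x$E[, "ezx"], ezy = x$E[, "ezy"],
             vol_strain = x$vol_strain, max_shear = x$max_shear,
             status = as.character(x$status))
}

#' @param x a `strain_field`.
#' @param component column of the strain table to map (default
#'   `"max_shear"`).
#' @param slice element-grid z index (default: middle).
#' @param ... passed to [graphics::image()].
#' @rdname run_strain
#' @export
plot.strain_field <- function(x, component = "max_shear",
                              slice = ceiling(x$grid_dims[1] / 2), ...) {
  vals <- switch(component, max_shear = x$max_shear,
                 vol_strain = x$vol_strain, x$E[, component])
  a <- array(vals, x$grid_dims)
  vs <- x$voxel_size_um
  image(x = x$axes$x * vs, y = x$axes$y * vs, z = t(a[slice, , ]),
        col = hcl.colors(64, "viridis"), xlab = "x (um)", ylab = "y (um)",
        main = sprintf("%s at z = %g um", component,
                       x$axes$z[slice] * vs), ...)
  invisible(x)
}
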