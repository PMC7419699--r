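#' DVC engine configuration
#'
#' Settings of the local (subset-based) digital volume correlation engine.
#' Defaults are the analysis settings of the targeted experiments: node
#' spacing 4 voxels and cubic subsets of 17 voxels per side, which on
#' 25 um scans yields a 100 um DVC map resolution.
#'
#' @param node_spacing_vox grid spacing between measurement nodes (voxels).
#' @param subset_side_vox side of the cubic correlation subset; odd, >= 3.
#' @param search_radius_vox half-width of the exhaustive integer search
#'   window (voxels).
#' @param min_valid_fraction minimum fraction of subset voxels that must be
#'   finite (unmasked) in both windows for a correlation score to count.
#' @param subpixel logical: refine the integer optimum by separable
#'   parabolic interpolation of the correlation score.
#' @param cc_min minimum acceptable correlation score; nodes below it are
#'   flagged `low_cc` and excluded from summaries.
#' @return a `dvc_config` list.
#' @export
dvc_config <- function(node_spacing_vox = 4, subset_side_vox = 17,
                       search_radius_vox = 3, min_valid_fraction = 0.5,
                       subpixel = TRUE, cc_min = 0.5) {
  .check_scalar(node_spacing_vox, "node_spacing_vox", lower = 1,
                integer = TRUE)
  .check_scalar(subset_side_vox, "subset_side_vox", lower = 3,
                integer = TRUE)
  if (subset_side_vox %% 2 == 0)
    .stopf("'subset_side_vox' must be odd, got %d", subset_side_vox)
  .check_scalar(search_radius_vox, "search_radius_vox", lower = 1,
                integer = TRUE)
  .check_scalar(min_valid_fraction, "min_valid_fraction")
  if (min_valid_fraction <= 0 || min_valid_fraction > 1)
    .stopf("'min_valid_fraction' must be in (0, 1]")
  if (!is.logical(subpixel) || length(subpixel) != 1L)
    .stopf("'subpixel' must be TRUE or FALSE")
  .check_scalar(cc_min, "cc_min", lower = -1, upper = 1)
  structure(list(node_spacing_vox = as.integer(node_spacing_vox),
                 subset_side_vox = as.integer(subset_side_vox),
                 search_radius_vox = as.integer(search_radius_vox),
                 min_valid_fraction = min_valid_fraction,
                 subpixel = subpixel, cc_min = cc_min),
            class = "dvc_config")
}

#' Build the regular DVC node grid
#'
#' Nodes sit at 0-based voxel coordinates that are multiples of the node
#' spacing; nodes whose subset plus search window would leave the volume
#' are excluded, so every retained node can be correlated at every offset.
#'
#' @param vol a [bone_volume()] (or its `dim()`).
#' @param cfg a [dvc_config()].
#' @return list with per-axis node coordinate vectors `z`, `y`, `x`
#'   (0-based voxels), the `nodes` matrix (n x 3, z varying fastest) and
#'   `grid_dims` (node counts per axis).
#' @export
build_node_grid <- function(vol, cfg = dvc_config()) {
  d <- if (is.null(dim(vol))) as.integer(vol) else dim(vol)
  if (length(d) != 3L) .stopf("need a 3D volume or its dim()")
  half <- (cfg$subset_side_vox - 1L) %/% 2L
  margin <- half + cfg$search_radius_vox
  ax <- lapply(d, function(n) {
    co <- seq(0L, n - 1L, by = cfg$node_spacing_vox)
    co[co >= margin & co <= n - 1L - margin]
  })
  if (any(!lengths(ax)))
    .stopf(paste0("volume too small for subset %d + search %d: ",
                  "no admissible node on some axis"),
           cfg$subset_side_vox, cfg$search_radius_vox)
  nodes <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  list(z = ax[[1]], y = ax[[2]], x = ax[[3]], nodes = nodes,
       grid_dims = lengths(ax))
}

#' Zero-normalised cross-correlation of one subset pair
#'
#' Correlates the reference subset centred at `center` with the deformed
#' subset centred at `center + offset`.  Only voxels finite in both
#' windows enter the sums; returns `NaN` when fewer than
#' `min_valid_fraction` of the subset voxels are valid or either window
#' has zero intensity variance.  ZNCC is invariant to affine intensity
#' changes `a * I + b` (a > 0) between the two scans.
#'
#' @param ref,def reference and deformed [bone_volume()]s.
#' @param center node centre, 0-based `(z, y, x)` voxels.
#' @param offset integer trial offset `(z, y, x)` voxels.
#' @param cfg a [dvc_config()].
#' @return correlation score in `[-1, 1]`, or `NaN`.
#' @export
correlate_subset <- function(ref, def, center, offset = c(0L, 0L, 0L),
                             cfg = dvc_config()) {
  half <- (cfg$subset_side_vox - 1L) %/% 2L
  d <- dim(ref)
  if (!identical(dim(def), d)) .stopf("ref and def dims differ")
  if (any(center - half < 0) || any(center + half > d - 1) ||
      any(center + offset - half < 0) || any(center + offset + half > d - 1))
    .stopf("subset window leaves the volume")
  .cpp_zncc(as.numeric(ref), as.numeric(def), d,
            as.integer(center), as.integer(offset), half,
            cfg$min_valid_fraction)
}

#' Exhaustive integer-offset search at one node
#'
#' Evaluates the correlation score at every offset of the cubic
#' `(2 * search_radius + 1)^3` window and returns the global argmax.
#' Ties are broken towards the smallest Euclidean offset norm, then
#' lexicographically in `(z, y, x)`, so the result is deterministic.
#'
#' @inheritParams correlate_subset
#' @return list with `offset` (integer 3-vector), `score`, `status`
#'   (`"ok"` or `"insufficient_valid"`), and the 3x3x3 score
#'   neighbourhood `neigh` around the optimum (27 values, `NA` outside
#'   the search window).
#' @export
search_integer <- function(ref, def, center, cfg = dvc_config()) {
  half <- (cfg$subset_side_vox - 1L) %/% 2L
  res <- .cpp_dvc_search(as.numeric(ref), as.numeric(def), dim(ref),
                         matrix(as.integer(center), 1, 3), half,
                         cfg$search_radius_vox, cfg$min_valid_fraction)
  list(offset = res$offset[1, ], score = res$cc[1],
       status = .status_levels[res$status[1] + 1L],
       neigh = res$neigh[1, ])
}

#' Subpixel refinement by parabolic peak interpolation
#'
#' Fits a parabola through the correlation scores at offsets -1, 0, +1
#' along each axis and returns the vertex position
#' `(s[-1] - s[+1]) / (2 (s[-1] - 2 s[0] + s[+1]))`, clamped to
#' `(-0.5, 0.5)`.  Axes whose neighbour scores are missing (optimum on
#' the search-window boundary) or whose parabola is not concave get a
#' zero correction.
#'
#' @param scores either a numeric 3-vector `(s[-1], s[0], s[+1])` for one
#'   axis, or the 27-value 3x3x3 neighbourhood from [search_integer()]
#'   (z fastest), in which case one correction per axis is returned.
#' @return the fractional correction: a scalar, or a `(z, y, x)` 3-vector.
#' @export
refine_subpixel <- function(scores) {
  para <- function(sm, s0, sp) {
    den <- sm - 2 * s0 + sp
    out <- ifelse(is.na(sm) | is.na(s0) | is.na(sp) | den >= 0, 0,
                  (sm - sp) / (2 * den))
    pmin(pmax(out, -0.5), 0.5)
  }
  if (length(scores) == 3L) return(para(scores[1], scores[2], scores[3]))
  if (length(scores) != 27L)
    .stopf("'scores' must have length 3 (one axis) or 27 (3x3x3)")
  # centre cross of the neighbourhood: column = (dz+1) + 3(dy+1) + 9(dx+1) + 1
  c(z = para(scores[13], scores[14], scores[15]),
    y = para(scores[11], scores[14], scores[17]),
    x = para(scores[5],  scores[14], scores[23]))
}

#' Run local digital volume correlation
#'
#' Tracks cubic gray-value subsets from the reference to the deformed
#' volume at every node of a regular grid: exhaustive integer search of
#' the zero-normalised cross-correlation, followed by separable parabolic
#' subpixel refinement.  `NaN` voxels (masked background/implant, warp
#' out-of-domain) never enter the correlation sums.  Node results are
#' independent, and the field is bit-reproducible for given inputs.
#'
#' @param ref,def reference and deformed [bone_volume()]s, congruent.
#' @param cfg a [dvc_config()].
#' @return an object of class `dvc_field`: node coordinates (0-based
#'   voxels), displacements `u` (voxels, `(z, y, x)` columns), correlation
#'   score and status per node, plus the grid layout and configuration.
#'   Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' spec <- phantom_spec(dims = c(48, 48, 48), screw_radius_um = 0, seed = 3)
#' ref <- make_trabecular_volume(spec)
#' def <- apply_warp(ref, warp_spec("rigid_translation",
#'                                  translation_vox = c(2, 1, 3)))
#' f <- run_dvc(ref, def, dvc_config(subset_side_vox = 9))
#' summary(f)
#' @export
run_dvc <- function(ref, def, cfg = dvc_config()) {
  if (!identical(dim(ref), dim(def)))
    .stopf("ref and def volumes must be congruent, got %s vs %s",
           paste(dim(ref), collapse = "x"), paste(dim(def), collapse = "x"))
  if (!isTRUE(all.equal(voxel_size(ref), voxel_size(def))))
    .stopf("ref and def voxel sizes differ")
  grid <- build_node_grid(ref, cfg)
  half <- (cfg$subset_side_vox - 1L) %/% 2L
  res <- .cpp_dvc_search(as.numeric(ref), as.numeric(def), dim(ref),
                         grid$nodes, half, cfg$search_radius_vox,
                         cfg$min_valid_fraction)
  status <- res$status  # 0 ok, 2 insufficient_valid
  cc <- res$cc
  low <- status == 0L & !is.na(cc) & cc < cfg$cc_min
  status[low] <- 1L
  u <- matrix(NA_real_, nrow(grid$nodes), 3,
              dimnames = list(NULL, c("u_z", "u_y", "u_x")))
  ok <- status == 0L
  if (any(ok)) {
    u[ok, ] <- res$offset[ok, , drop = FALSE]
    if (cfg$subpixel && cfg$search_radius_vox >= 1) {
      ng <- res$neigh[ok, , drop = FALSE]
      dz <- .para_axis(ng[, 13], ng[, 14], ng[, 15])
      dy <- .para_axis(ng[, 11], ng[, 14], ng[, 17])
      dx <- .para_axis(ng[, 5], ng[, 14], ng[, 23])
      # a score of 1 is an exact match: integer result, no refinement,
      # so noise-free integer shifts are recovered with zero error
      exact <- res$cc[ok] >= 1 - 1e-9
      u[ok, ] <- u[ok, , drop = FALSE] +
        cbind(dz, dy, dx) * as.numeric(!exact)
    }
  }
  structure(list(nodes = grid$nodes, axes = grid[c("z", "y", "x")],
                 grid_dims = grid$grid_dims, u = u, cc = cc,
                 status = factor(.status_levels[status + 1L],
                                 levels = .status_levels),
                 cfg = cfg, voxel_size_um = voxel_size(ref),
                 vol_dims = dim(ref)),
            class = "dvc_field")
}

.para_axis <- function(sm, s0, sp) {
  den <- sm - 2 * s0 + sp
  out <- ifelse(is.na(sm) | is.na(s0) | is.na(sp) | den >= 0, 0,
                (sm - sp) / (2 * den))
  pmin(pmax(out, -0.5), 0.5)
}

#' @export
print.dvc_field <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<dvc_field> %d nodes (%s grid), spacing %d vox, subset %d\n",
              n, paste(x$grid_dims, collapse = " x "),
              x$cfg$node_spacing_vox, x$cfg$subset_side_vox))
  tb <- table(x$status)
  cat("  status:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
      "\n")
  ok <- x$status == "ok"
  if (any(ok)) {
    m <- colMeans(x$u[ok, , drop = FALSE])
    cat(sprintf("  mean u over ok nodes (vox): z %.4f, y %.4f, x %.4f\n",
                m[1], m[2], m[3]))
    cat(sprintf("  mean cc over ok nodes: %.4f\n", mean(x$cc[ok])))
  }
  invisible(x)
}

#' @export
summary.dvc_field <- function(object, ...) {
  ok <- object$status == "ok"
  vs <- object$voxel_size_um
  comp <- if (any(ok)) {
    u <- object$u[ok, , drop = FALSE]
    data.frame(component = c("u_z", "u_y", "u_x"),
               mean_vox = colMeans(u), sd_vox = apply(u, 2, sd),
               mean_um = colMeans(u) * vs, sd_um = apply(u, 2, sd) * vs,
               row.names = NULL)
  } else data.frame()
  out <- list(n_nodes = nrow(object$nodes), status = table(object$status),
              displacement = comp,
              cc = if (any(ok)) summary(object$cc[ok]) else NULL,
              map_spacing_um = map_resolution(object))
  class(out) <- "summary.dvc_field"
  out
}

#' @export
print.summary.dvc_field <- function(x, ...) {
  cat(sprintf("DVC field: %d nodes, map spacing %.6g um\n", x$n_nodes,
              x$map_spacing_um))
  print(x$status)
  if (nrow(x$displacement)) {
    cat("displacement over ok nodes:\n")
    print(x$displacement, digits = 4)
  }
  invisible(x)
}

#' DVC map resolution
#'
#' Physical spacing of the displacement map: node spacing times voxel
#' size (e.g. 4-voxel spacing on 25 um scans gives 100 um maps).
#'
#' @param field a `dvc_field`.
#' @return map spacing in micrometres.
#' @export
map_resolution <- function(field) {
  field$cfg$node_spacing_vox * field$voxel_size_um
}

#' @export
as.data.frame.dvc_field <- function(x, ...) {
  vs <- x$voxel_size_um
  data.frame(z_vox = x$nodes[, 1], y_vox = x$nodes[, 2],
             x_vox = x$nodes[, 3],
             z_um = x$nodes[, 1] * vs, y_um = x$nodes[, 2] * vs,
             x_um = x$nodes[, 3] * vs,
             u_z = x$u[, 1], u_y = x$u[, 2], u_x = x$u[, 3],
             u_z_um = x$u[, 1] * vs, u_y_um = x$u[, 2] * vs,
             u_x_um = x$u[, 3] * vs,
             cc = x$cc, status = as.character(x$status))
}

#' @param x a `dvc_field`.
#' @param component one of `"u_z"`, `"u_y"`, `"u_x"`, `"cc"`.
#' @param slice node-grid z index of the map slice to show (default:
#'   middle).
#' @param ... passed to [graphics::image()].
#' @rdname run_dvc
#' @export
plot.dvc_field <- function(x, component = "u_z",
                           slice = ceiling(x$grid_dims[1] / 2), ...) {
  vals <- if (component == "cc") x$cc else x$u[, match(component,
                                                       colnames(x$u))]
  a <- array(vals, x$grid_dims)
  vs <- x$voxel_size_um
  image(x = x$axes$x * vs, y = x$axes$y * vs,
        z = t(a[slice, , ]), col = hcl.colors(64, "viridis"),
        xlab = "x (um)", ylab = "y (um)",
        main = sprintf("%s at z = %g um", component,
                       x$axes$z[slice] * vs), ...)
  invisible(x)
}
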