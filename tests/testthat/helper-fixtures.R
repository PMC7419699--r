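# shared fixtures and independent oracles, all generated in code

# smooth band-limited test texture: a sum of random-phase sinusoids, built
# without the package's own generator so that DVC tests do not depend on it
smooth_texture <- function(dims, seed = 1, n_waves = 40, kmax = 0.35,
                           voxel_size_um = 25) {
  set.seed(seed)
  z <- 0:(dims[1] - 1); y <- 0:(dims[2] - 1); x <- 0:(dims[3] - 1)
  a <- array(0, dims)
  for (i in seq_len(n_waves)) {
    k <- runif(3, -kmax, kmax)
    ph <- runif(1, 0, 2 * pi)
    a <- a + cos(outer(outer(k[1] * z, k[2] * y, `+`), k[3] * x, `+`) + ph)
  }
  bone_volume(100 + 10 * a, voxel_size_um = voxel_size_um)
}

# brute-force ZNCC over a subset window pair, plain R
brute_zncc <- function(ref, def, center, offset, half, min_frac = 0.5) {
  zi <- center[1] + (-half:half); yi <- center[2] + (-half:half)
  xi <- center[3] + (-half:half)
  a <- ref[zi + 1, yi + 1, xi + 1]
  b <- def[zi + 1 + offset[1], yi + 1 + offset[2], xi + 1 + offset[3]]
  v <- is.finite(a) & is.finite(b)
  if (sum(v) < min_frac * length(a) || sum(v) < 2) return(NaN)
  a <- a[v]; b <- b[v]
  if (sd(a) == 0 || sd(b) == 0) return(NaN)
  sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1) / (sd(a) * sd(b))
}

# brute-force median filter, spherical or cubic neighbourhood
brute_median3d <- function(a, radius, cubic = FALSE) {
  d <- dim(a)
  out <- array(NaN, d)
  offs <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                      dx = -radius:radius)
  if (!cubic)
    offs <- offs[offs$dz^2 + offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (is.nan(a[z, y, x])) next
    zz <- z + offs$dz; yy <- y + offs$dy; xx <- x + offs$dx
    keep <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] &
      xx >= 1 & xx <= d[3]
    vals <- a[cbind(zz[keep], yy[keep], xx[keep])]
    vals <- vals[!is.nan(vals)]
    if (length(vals)) out[z, y, x] <- median(vals)
  }
  out
}

# dvc_field with analytically imposed displacements u(X) (voxel coords,
# 0-based), for exercising the strain chain without running DVC
analytic_field <- function(dims = c(40, 40, 40), spacing = 4,
                           voxel_size_um = 25, ufun = function(p) 0 * p) {
  cfg <- dvc_config(node_spacing_vox = spacing, subset_side_vox = 9,
                    search_radius_vox = 1)
  grid <- build_node_grid(dims, cfg)
  u <- ufun(grid$nodes)
  colnames(u) <- c("u_z", "u_y", "u_x")
  structure(list(nodes = grid$nodes, axes = grid[c("z", "y", "x")],
                 grid_dims = grid$grid_dims, u = u,
                 cc = rep(1, nrow(u)),
                 status = factor(rep("ok", nrow(u)),
                                 levels = c("ok", "low_cc",
                                            "insufficient_valid",
                                            "out_of_bounds")),
                 cfg = cfg, voxel_size_um = voxel_size_um,
                 vol_dims = dims),
            class = "dvc_field")
}
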