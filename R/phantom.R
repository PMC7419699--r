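#' Specification of a synthetic trabecular-bone phantom
#'
#' Parameters of the synthetic micro-CT phantom: a trabecular bone texture
#' (Gaussian random field thresholded to a target solid fraction) with a
#' bright threaded screw along the z axis.  Defaults emulate the in situ
#' pullout experiments the package targets: 25 um voxels, peri-implant
#' BV/TV of 0.32, a 2.6 mm diameter screw with ~200 um deep threads.
#'
#' @param dims voxel counts per axis `(nz, ny, nx)`, each >= 32.
#' @param voxel_size_um voxel edge (um).
#' @param target_bvtv solid fraction of the bone texture, in (0, 1];
#'   1 is the degenerate fully-solid phantom.
#' @param screw_radius_um screw outer (thread crest) radius (um); 0 omits
#'   the screw.
#' @param thread_pitch_um,thread_depth_um thread geometry (um);
#'   `thread_depth_um = 0` gives a plain cylinder.
#' @param bone_texture_scale_um correlation length of the trabecular
#'   texture (um).  A free parameter of the generator, not an anatomical
#'   claim; the default gives features of a few voxels at 25 um, in the
#'   range of rodent trabecular spacing.
#' @param intensities named numeric vector `c(background=, bone=, screw=)`
#'   of mean gray levels, strictly increasing.
#' @param seed integer random seed; every generator output is a pure
#'   function of the spec including this seed.
#' @return a `phantom_spec` list.
#' @seealso [make_trabecular_volume()], [insert_screw()], [apply_warp()]
#' @export
phantom_spec <- function(dims = c(128, 128, 128),
                         voxel_size_um = 25,
                         target_bvtv = 0.32,
                         screw_radius_um = 1300,
                         thread_pitch_um = 400,
                         thread_depth_um = 200,
                         bone_texture_scale_um = 100,
                         intensities = c(background = 20, bone = 120,
                                         screw = 220),
                         seed = 1L) {
  if (length(dims) != 3L || any(dims < 32) || any(dims != round(dims)))
    .stopf("'dims' must be 3 integers, all >= 32")
  .check_scalar(voxel_size_um, "voxel_size_um", lower = 1e-6)
  .check_scalar(target_bvtv, "target_bvtv")
  if (target_bvtv <= 0 || target_bvtv > 1)
    .stopf("'target_bvtv' must be in (0, 1]")
  .check_scalar(screw_radius_um, "screw_radius_um", lower = 0)
  .check_scalar(thread_pitch_um, "thread_pitch_um", lower = 1e-6)
  .check_scalar(thread_depth_um, "thread_depth_um", lower = 0)
  .check_scalar(bone_texture_scale_um, "bone_texture_scale_um", lower = 1e-6)
  if (length(intensities) != 3L)
    .stopf("'intensities' must have 3 values (background, bone, screw)")
  if (is.null(names(intensities)))
    names(intensities) <- c("background", "bone", "screw")
  if (any(diff(intensities) <= 0))
    .stopf("'intensities' must be strictly increasing: background < bone < screw")
  .check_scalar(seed, "seed", integer = TRUE)
  structure(list(dims = as.integer(dims),
                 voxel_size_um = voxel_size_um,
                 target_bvtv = target_bvtv,
                 screw_radius_um = screw_radius_um,
                 thread_pitch_um = thread_pitch_um,
                 thread_depth_um = thread_depth_um,
                 bone_texture_scale_um = bone_texture_scale_um,
                 intensities = intensities,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# FFT-based isotropic Gaussian smoothing (periodic boundary), sigma in voxels
.gauss_smooth_fft <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  h <- lapply(d, function(n) {
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  })
  H <- outer(outer(h[[1]], h[[2]]), h[[3]])
  dim(H) <- d
  Re(fft(fft(a) * H, inverse = TRUE)) / prod(d)
}

#' Generate a trabecular bone texture volume
#'
#' Draws a white-noise field, smooths it to the requested correlation length
#' (spectral Gaussian filter), and thresholds it at the quantile that makes
#' the solid fraction equal `target_bvtv`.  Solid voxels take the bone
#' intensity, pores the background intensity; a mild sub-voxel blur
#' (sigma 0.6 voxel) then emulates the scanner point-spread so that
#' interfaces carry gray-level gradients, which is what subvoxel DVC locks
#' onto.  Deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return a [bone_volume()].
#' @examples
#' v <- make_trabecular_volume(phantom_spec(dims = c(32, 32, 32), seed = 7))
#' mean(v > mean(range(v)))  # close to target_bvtv
#' @export
make_trabecular_volume <- function(spec) {
  if (!inherits(spec, "phantom_spec")) .stopf("'spec' must be a phantom_spec")
  d <- spec$dims
  ints <- spec$intensities
  sigma <- spec$bone_texture_scale_um / spec$voxel_size_um / 2
  field <- .with_seed(spec$seed, {
    w <- array(rnorm(prod(d)), d)
    .gauss_smooth_fft(w, sigma)
  })
  solid <- if (spec$target_bvtv >= 1) {
    array(TRUE, d)
  } else {
    field > quantile(field, 1 - spec$target_bvtv, names = FALSE)
  }
  vol <- array(ints[["background"]], d)
  vol[solid] <- ints[["bone"]]
  vol <- .gauss_smooth_fft(vol, 0.6)
  bone_volume(vol, voxel_size_um = spec$voxel_size_um)
}

# thread-crest radius profile r(z) in voxels; z_vox 0-based
.screw_radius_profile <- function(spec, z_vox) {
  vs <- spec$voxel_size_um
  r_outer <- spec$screw_radius_um / vs
  depth <- spec$thread_depth_um / vs
  phase <- 2 * pi * (z_vox * vs) / spec$thread_pitch_um
  r_outer - depth * (0.5 + 0.5 * cos(phase))
}

#' Insert a threaded screw along the z axis
#'
#' Overwrites a threaded cylinder, centred in the xy plane and spanning the
#' full z extent, at the screw intensity.  The thread profile is sinusoidal
#' in z: the local radius oscillates between the outer (crest) radius and
#' outer radius minus `thread_depth_um`, with period `thread_pitch_um`.
#' The screw voxel mask is recorded on the returned volume
#' (`attr(, "screw_mask")`) for downstream masking and morphometry.
#'
#' @param vol a [bone_volume()].
#' @param spec the [phantom_spec()] holding the screw geometry.
#' @return the volume with the screw burnt in and its mask attached.
#' @export
insert_screw <- function(vol, spec) {
  if (!inherits(spec, "phantom_spec")) .stopf("'spec' must be a phantom_spec")
  if (spec$screw_radius_um == 0) return(vol)
  d <- dim(vol)
  vs <- voxel_size(vol)
  r_outer <- spec$screw_radius_um / vs
  if (2 * r_outer > min(d[2], d[3]))
    .stopf("screw diameter (%.1f voxels) exceeds the volume cross-section",
           2 * r_outer)
  cy <- (d[2] - 1) / 2
  cx <- (d[3] - 1) / 2
  r2 <- outer((seq_len(d[2]) - 1 - cy)^2, (seq_len(d[3]) - 1 - cx)^2, `+`)
  rz <- pmax(.screw_radius_profile(spec, 0:(d[1] - 1)), 0)
  mask <- array(FALSE, d)
  for (z in seq_len(d[1]))
    mask[z, , ] <- r2 <= rz[z]^2
  out <- .as_array(vol)
  out[mask] <- spec$intensities[["screw"]]
  .rewrap(out, vol, screw_mask = mask)
}

#' Specification of a ground-truth warp field
#'
#' Describes the imposed deformation used to produce a synthetic "deformed"
#' scan with known ground truth.  Exactly the parameters of the chosen kind
#' are required.  Displacements are defined in the reference frame: the
#' warped volume is resampled as `def(x) = ref(x - u(x))`, matching the
#' reference-to-deformed tracking direction of the DVC engine, so DVC run
#' on (ref, def) should recover `+u`.
#'
#' @param kind one of `"rigid_translation"`, `"rigid_rotation"`,
#'   `"affine"`, `"pullout_envelope"`.
#' @param translation_vox 3-vector `(z, y, x)` displacement in voxels
#'   (rigid_translation).
#' @param rotation_axis,rotation_deg unit axis `(z, y, x)` and angle in
#'   degrees (rigid_rotation); rotation about the volume centre.
#' @param affine_matrix 3x3 deformation gradient with positive determinant,
#'   applied about the volume centre (affine); ground-truth displacement is
#'   `u(X) = (F - I)(X - centre)`.
#' @param envelope list for the pullout-envelope field:
#'   `magnitude_vox` (axial displacement, voxels),
#'   `surface_radius_um` (screw surface radius the envelope hangs on),
#'   `plateau_um` (shell thickness carried at full magnitude, default 400),
#'   `decay_um` (cosine-taper distance to zero, default 400).  The axial
#'   displacement is `magnitude_vox` for radius r <= surface + plateau and
#'   tapers as `m/2 (1 + cos(pi s / decay))` over the next `decay_um`; its
#'   radial gradient is steepest at `surface + plateau + decay/2`, which is
#'   the analytic radius of the induced shear shell.
#' @return a `warp_spec` list.
#' @export
warp_spec <- function(kind = c("rigid_translation", "rigid_rotation",
                               "affine", "pullout_envelope"),
                      translation_vox = NULL,
                      rotation_axis = NULL, rotation_deg = NULL,
                      affine_matrix = NULL,
                      envelope = NULL) {
  kind <- match.arg(kind)
  w <- list(kind = kind)
  switch(kind,
    rigid_translation = {
      if (is.null(translation_vox) || length(translation_vox) != 3L)
        .stopf("rigid_translation needs 'translation_vox' (z, y, x)")
      w$translation_vox <- as.numeric(translation_vox)
    },
    rigid_rotation = {
      if (is.null(rotation_axis) || is.null(rotation_deg))
        .stopf("rigid_rotation needs 'rotation_axis' and 'rotation_deg'")
      n <- sqrt(sum(rotation_axis^2))
      if (n == 0) .stopf("'rotation_axis' must be nonzero")
      w$rotation_axis <- rotation_axis / n
      w$rotation_deg <- rotation_deg
    },
    affine = {
      if (is.null(affine_matrix) || !identical(dim(affine_matrix), c(3L, 3L)))
        .stopf("affine needs a 3x3 'affine_matrix'")
      if (det(affine_matrix) <= 0)
        .stopf("'affine_matrix' must have positive determinant")
      w$affine_matrix <- affine_matrix
    },
    pullout_envelope = {
      if (is.null(envelope) || is.null(envelope$magnitude_vox))
        .stopf("pullout_envelope needs 'envelope$magnitude_vox'")
      env <- list(magnitude_vox = envelope$magnitude_vox,
                  surface_radius_um = envelope$surface_radius_um %||% 1300,
                  plateau_um = envelope$plateau_um %||% 400,
                  decay_um = envelope$decay_um %||% 400)
      w$envelope <- env
    })
  structure(w, class = "warp_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotation matrix (Rodrigues), acting on (z, y, x) coordinate vectors
.rotation_matrix <- function(axis, deg) {
  th <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ground-truth displacement (z component) of the pullout envelope at radius
# r (voxels from the screw axis); other components are zero
.envelope_uz <- function(env, r_vox, voxel_size_um) {
  inner <- (env$surface_radius_um + env$plateau_um) / voxel_size_um
  decay <- env$decay_um / voxel_size_um
  m <- env$magnitude_vox
  uz <- numeric(length(r_vox))
  uz[r_vox <= inner] <- m
  tap <- r_vox > inner & r_vox < inner + decay
  uz[tap] <- m / 2 * (1 + cos(pi * (r_vox[tap] - inner) / decay))
  uz
}

#' Warp a volume under a ground-truth displacement field
#'
#' Resamples the volume under the imposed field by trilinear interpolation,
#' pulling intensities from `x - u(x)`; voxels mapped from outside the grid
#' become `NaN`, so the DVC masking path is exercised on warped phantoms.
#' Integer rigid translations are exact (no interpolation).  An attached
#' screw mask is transported with the same warp.
#'
#' @param vol a [bone_volume()].
#' @param warp a [warp_spec()].
#' @return the warped [bone_volume()].
#' @export
apply_warp <- function(vol, warp) {
  if (!inherits(warp, "warp_spec")) .stopf("'warp' must be a warp_spec")
  d <- dim(vol)
  ctr <- (d - 1) / 2
  idx <- cbind(z = as.vector(slice.index(.as_array(vol), 1)) - 1,
               y = as.vector(slice.index(.as_array(vol), 2)) - 1,
               x = as.vector(slice.index(.as_array(vol), 3)) - 1)
  src <- switch(warp$kind,
    rigid_translation = {
      t(t(idx) - warp$translation_vox)
    },
    rigid_rotation = {
      R <- .rotation_matrix(warp$rotation_axis, -warp$rotation_deg)
      t(R %*% (t(idx) - ctr) + ctr)
    },
    affine = {
      Finv <- solve(warp$affine_matrix)
      t(Finv %*% (t(idx) - ctr) + ctr)
    },
    pullout_envelope = {
      r <- sqrt((idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2)
      uz <- .envelope_uz(warp$envelope, r, voxel_size(vol))
      cbind(idx[, 1] - uz, idx[, 2], idx[, 3])
    })
  out <- array(.cpp_trilinear(as.numeric(vol), d, src), d)
  mask <- attr(vol, "screw_mask")
  if (!is.null(mask)) {
    mw <- .cpp_trilinear(as.numeric(mask), d, src)
    mask <- array(!is.na(mw) & mw >= 0.5, d)
  }
  .rewrap(out, vol, screw_mask = mask)
}

#' Ground-truth displacement of a warp at given points
#'
#' Evaluates the imposed displacement field `u(x)` (voxels, `(z, y, x)`
#' components) at 0-based voxel positions, for comparison with DVC output.
#'
#' @param warp a [warp_spec()].
#' @param pts n x 3 matrix of `(z, y, x)` positions (voxels, 0-based).
#' @param dims volume dims the warp was applied to (for the centre).
#' @param voxel_size_um voxel size (um), needed by the envelope field.
#' @return n x 3 matrix of displacements in voxels.
#' @export
warp_displacement <- function(warp, pts, dims, voxel_size_um = 25) {
  ctr <- (dims - 1) / 2
  switch(warp$kind,
    rigid_translation = matrix(warp$translation_vox, nrow(pts), 3,
                               byrow = TRUE),
    rigid_rotation = {
      R <- .rotation_matrix(warp$rotation_axis, warp$rotation_deg)
      t((R - diag(3)) %*% (t(pts) - ctr))
    },
    affine = t((warp$affine_matrix - diag(3)) %*% (t(pts) - ctr)),
    pullout_envelope = {
      r <- sqrt((pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2)
      cbind(.envelope_uz(warp$envelope, r, voxel_size_um), 0, 0)
    })
}

#' Add Gaussian imaging noise
#'
#' Adds zero-mean Gaussian noise to every finite voxel; `NaN` (masked)
#' voxels are untouched.  Deterministic given the seed and independent of
#' the caller's RNG state.
#'
#' @param vol a [bone_volume()].
#' @param sigma noise standard deviation (intensity units, >= 0).
#' @param seed integer seed.
#' @return the noisy [bone_volume()].
#' @export
add_noise <- function(vol, sigma, seed) {
  .check_scalar(sigma, "sigma", lower = 0)
  .check_scalar(seed, "seed", integer = TRUE)
  if (sigma == 0) return(vol)
  out <- .as_array(vol)
  fin <- !is.nan(out)
  out[fin] <- out[fin] + .with_seed(seed, rnorm(sum(fin), 0, sigma))
  .rewrap(out, vol)
}
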