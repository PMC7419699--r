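test_that("trabecular generator hits the target solid fraction and is deterministic", {
  spec <- phantom_spec(dims = c(96, 96, 96), target_bvtv = 0.32, seed = 42)
  v1 <- make_trabecular_volume(spec)
  v2 <- make_trabecular_volume(spec)
  expect_identical(unclass(v1), unclass(v2))
  # counting oracle: threshold at the midpoint of the two phase levels
  mid <- mean(spec$intensities[c("background", "bone")])
  expect_lt(abs(mean(v1 >= mid) - 0.32), 0.02)
})

test_that("degenerate fully-solid phantom is uniform at bone intensity", {
  spec <- phantom_spec(dims = c(32, 32, 32), target_bvtv = 1, seed = 1)
  v <- make_trabecular_volume(spec)
  expect_equal(range(v), rep(spec$intensities[["bone"]], 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("phantom spec validation rejects bad parameters", {
  expect_error(phantom_spec(dims = c(16, 96, 96)), "32")
  expect_error(phantom_spec(target_bvtv = 0), "target_bvtv")
  expect_error(phantom_spec(intensities = c(100, 50, 220)), "increasing")
})

test_that("screw insertion geometry: radius zero, plain cylinder area, intensity", {
  spec0 <- phantom_spec(dims = c(48, 48, 48), screw_radius_um = 0, seed = 2)
  v <- make_trabecular_volume(spec0)
  expect_identical(insert_screw(v, spec0), v)

  spec <- phantom_spec(dims = c(48, 64, 64), screw_radius_um = 400,
                       thread_depth_um = 0, seed = 2)
  vs <- insert_screw(make_trabecular_volume(spec), spec)
  mask <- attr(vs, "screw_mask")
  r_vox <- 400 / 25
  per_slice <- apply(mask, 1, sum)
  expect_true(all(abs(per_slice - pi * r_vox^2) / (pi * r_vox^2) < 0.03))
  expect_true(all(vs[mask] >= spec$intensities[["bone"]]))

  big <- phantom_spec(dims = c(48, 64, 64), screw_radius_um = 2000)
  expect_error(insert_screw(make_trabecular_volume(big), big), "diameter")
})

test_that("warp: identity, integer shift equals index shifting, affine volume change", {
  v <- smooth_texture(c(32, 32, 32), seed = 5)
  w0 <- apply_warp(v, warp_spec("rigid_translation",
                                translation_vox = c(0, 0, 0)))
  expect_equal(unclass(w0), unclass(v), ignore_attr = TRUE)

  t <- c(2, 1, 3)
  wt <- apply_warp(v, warp_spec("rigid_translation", translation_vox = t))
  d <- dim(v)
  shifted <- array(NaN, d)
  shifted[(1 + t[1]):d[1], (1 + t[2]):d[2], (1 + t[3]):d[3]] <-
    v[1:(d[1] - t[1]), 1:(d[2] - t[2]), 1:(d[3] - t[3])]
  expect_identical(unclass(wt)[!is.nan(shifted)],
                   shifted[!is.nan(shifted)])
  expect_identical(is.nan(unclass(wt)), is.nan(shifted))

  # a smooth-edged ball (so the half-maximum surface is resolved at
  # subvoxel scale, like a blurred tomogram): the voxel count above half
  # maximum grows by det(F) under an affine warp
  db <- c(48, 48, 48)
  ctr <- (db - 1) / 2
  dist <- sqrt(outer(outer((0:(db[1] - 1) - ctr[1])^2,
                           (0:(db[2] - 1) - ctr[2])^2, `+`),
                     (0:(db[3] - 1) - ctr[3])^2, `+`))
  smooth_ball <- 1 / (1 + exp((dist - 10) / 1.5))
  vb <- bone_volume(smooth_ball, 25)
  Fm <- diag(3) * 1.02
  wa <- apply_warp(vb, warp_spec("affine", affine_matrix = Fm))
  grow <- sum(unclass(wa) >= 0.5, na.rm = TRUE) / sum(smooth_ball >= 0.5)
  expect_lt(abs(grow - det(Fm)) / det(Fm), 0.03)
})

test_that("warp spec validates its parameters", {
  expect_error(warp_spec("rigid_translation"), "translation_vox")
  expect_error(warp_spec("affine",
                         affine_matrix = -diag(3)), "determinant")
  expect_error(warp_spec("pullout_envelope", envelope = list()),
               "magnitude_vox")
})

test_that("forward/backward translation round trip restores interior voxels", {
  v <- smooth_texture(c(32, 32, 32), seed = 7)
  t <- c(1.3, -0.7, 2.1)
  fwd <- apply_warp(v, warp_spec("rigid_translation", translation_vox = t))
  back <- apply_warp(fwd, warp_spec("rigid_translation",
                                    translation_vox = -t))
  core <- unclass(back)[8:25, 8:25, 8:25] - unclass(v)[8:25, 8:25, 8:25]
  # two trilinear resamplings of a band-limited texture: deviation stays
  # below 2 percent of the intensity range on interior voxels
  expect_lt(max(abs(core)), 0.02 * diff(range(v)))
})

test_that("noise is reproducible, respects sigma and masked voxels", {
  v <- smooth_texture(c(52, 52, 52), seed = 1)
  va <- unclass(v)
  va[1:5, , ] <- NaN
  v <- bone_volume(va, 25)
  expect_identical(add_noise(v, 0, 99), v)
  n1 <- add_noise(v, 3, 7)
  n2 <- add_noise(v, 3, 7)
  expect_identical(unclass(n1), unclass(n2))
  diffs <- (unclass(n1) - unclass(v))[!is.nan(va)]
  expect_gte(length(diffs), 1e5)
  expect_lt(abs(sd(diffs) - 3) / 3, 0.02)
  expect_identical(is.nan(unclass(n1)), is.nan(va))
  expect_error(add_noise(v, -1, 1), "sigma")
})
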