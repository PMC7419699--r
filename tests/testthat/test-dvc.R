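test_that("node grid matches brute enumeration and the spacing convention", {
  cfg <- dvc_config()
  g <- build_node_grid(c(64, 64, 64), cfg)
  # brute enumeration: every admissible coordinate on one axis
  half <- 8; search <- 3
  adm <- Filter(function(c0) c0 - half - search >= 0 &&
                  c0 + half + search <= 63, seq(0, 63, by = 4))
  expect_equal(g$z, adm)
  expect_equal(nrow(g$nodes), length(adm)^3)
  expect_true(all(g$nodes %% 4 == 0))

  g1 <- build_node_grid(c(40, 40, 40),
                        dvc_config(node_spacing_vox = 1,
                                   subset_side_vox = 9,
                                   search_radius_vox = 2))
  expect_equal(g1$z, 6:33)  # every admissible voxel is a node
  expect_error(build_node_grid(c(20, 20, 20), cfg), "too small")
})

test_that("subset correlation: self-match, intensity invariance, brute-force argmax", {
  v <- smooth_texture(c(32, 32, 32), seed = 8)
  cfg <- dvc_config(subset_side_vox = 17, search_radius_vox = 2)
  ctr <- c(15, 15, 15)
  expect_equal(correlate_subset(v, v, ctr, c(0, 0, 0), cfg), 1,
               tolerance = 1e-12)

  v2 <- bone_volume(2.5 * unclass(v) + 40, 25)
  expect_equal(correlate_subset(v, v2, ctr, c(0, 0, 0), cfg), 1,
               tolerance = 1e-12)

  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(1, 0, 0)))
  offs <- as.matrix(expand.grid(z = -2:2, y = -2:2, x = -2:2))
  ours <- apply(offs, 1, function(o) correlate_subset(v, def, ctr, o, cfg))
  brute <- apply(offs, 1, function(o)
    brute_zncc(unclass(v), unclass(def), ctr, o, 8))
  expect_equal(ours, brute, tolerance = 1e-10)
  expect_equal(offs[which.max(ours), ], c(z = 1, y = 0, x = 0))
})

test_that("integer search finds constructed shifts and breaks ties deterministically", {
  v <- smooth_texture(c(40, 40, 40), seed = 9)
  cfg <- dvc_config(subset_side_vox = 9, search_radius_vox = 3)
  s <- search_integer(v, v, c(20, 20, 20), cfg)
  expect_equal(s$offset, c(0L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(s$score, 1, tolerance = 1e-12)

  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(2, 1, 3)))
  s2 <- search_integer(v, def, c(20, 20, 20), cfg)
  expect_equal(s2$offset, c(2L, 1L, 3L), ignore_attr = TRUE)

  # period-2 stripes along z shifted by 1: offsets -1 and +1 both perfect;
  # the smaller-norm/lexicographic rule must pick (-1, 0, 0)
  d <- c(24, 24, 24)
  stripes <- bone_volume(array(rep(c(0, 100), length.out = d[1]), d), 25)
  sh <- apply_warp(stripes, warp_spec("rigid_translation",
                                      translation_vox = c(1, 0, 0)))
  st <- search_integer(stripes, sh, c(12, 12, 12),
                       dvc_config(subset_side_vox = 9,
                                  search_radius_vox = 2))
  expect_equal(st$offset, c(-1L, 0L, 0L), ignore_attr = TRUE)
})

test_that("parabolic refinement: symmetry, closed form, neighbourhood form", {
  expect_equal(refine_subpixel(c(0.9, 1.0, 0.9)), 0)
  expect_equal(refine_subpixel(c(0.80, 1.00, 0.90)),
               (0.80 - 0.90) / (2 * (0.80 - 2 + 0.90)), tolerance = 1e-12)
  expect_equal(refine_subpixel(c(0.80, 1.00, 0.90)), 1 / 6,
               tolerance = 1e-4)
  ng <- rep(NA_real_, 27)
  ng[14] <- 1; ng[13] <- 0.8; ng[15] <- 0.9   # z axis
  ng[11] <- 0.9; ng[17] <- 0.9                # y axis symmetric
  # x neighbours missing -> zero correction on that axis
  expect_equal(refine_subpixel(ng),
               c(z = 1 / 6, y = 0, x = 0), tolerance = 1e-12)
})

test_that("run_dvc is exact on identity and integer rigid shifts", {
  v <- smooth_texture(c(48, 48, 48), seed = 10)
  cfg <- dvc_config(subset_side_vox = 9)
  f0 <- run_dvc(v, v, cfg)
  expect_true(all(f0$status == "ok"))
  expect_true(all(f0$u == 0))
  expect_true(all(abs(f0$cc - 1) < 1e-12))

  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(2, 1, 3)))
  f <- run_dvc(v, def, cfg)
  ok <- f$status == "ok"
  expect_gt(sum(ok), 100)
  expect_equal(max(abs(t(f$u[ok, ]) - c(2, 1, 3))), 0)
})

test_that("run_dvc equals a brute-force correlator at every node and offset", {
  v <- smooth_texture(c(32, 32, 32), seed = 11)
  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(1.4, -0.6, 0.9)))
  def <- add_noise(def, 1, 3)
  cfg <- dvc_config(node_spacing_vox = 4, subset_side_vox = 9,
                    search_radius_vox = 2, subpixel = FALSE)
  f <- run_dvc(v, def, cfg)
  offs <- as.matrix(expand.grid(dz = -2:2, dy = -2:2, dx = -2:2))
  norm2 <- rowSums(offs^2)
  ord <- order(norm2, offs[, 1], offs[, 2], offs[, 3])
  offs <- offs[ord, ]
  for (i in seq_len(nrow(f$nodes))) {
    sc <- apply(offs, 1, function(o)
      brute_zncc(unclass(v), unclass(def), f$nodes[i, ], o, 4))
    best <- offs[which.max(sc), ]
    expect_equal(unname(f$u[i, ]), unname(best))
    expect_equal(unname(f$cc[i]), max(sc, na.rm = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("subpixel refinement recovers a half-voxel shift at most nodes", {
  v <- smooth_texture(c(48, 48, 48), seed = 12)
  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(0.5, 0, 0)))
  f <- run_dvc(v, def, dvc_config(subset_side_vox = 9))
  ok <- f$status == "ok"
  err <- abs(f$u[ok, 1] - 0.5)
  expect_gte(mean(err < 0.1), 0.9)
})

test_that("swapping reference and deformed negates the field", {
  spec <- phantom_spec(dims = c(48, 48, 48), screw_radius_um = 0,
                       seed = 13)
  v <- make_trabecular_volume(spec)
  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(0.4, -0.3, 0.2)))
  cfg <- dvc_config()  # subset 17: peak sharp enough for subvoxel symmetry
  fwd <- run_dvc(v, def, cfg)
  bwd <- run_dvc(def, v, cfg)
  ok <- fwd$status == "ok" & bwd$status == "ok"
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(fwd$u[ok, ] + bwd$u[ok, ])), 0.1)
})

test_that("a masked region leaves unrelated nodes untouched", {
  v <- smooth_texture(c(48, 48, 48), seed = 14)
  def <- apply_warp(v, warp_spec("rigid_translation",
                                 translation_vox = c(0.5, 0.5, 0)))
  cfg <- dvc_config(subset_side_vox = 9)
  f_clean <- run_dvc(v, def, cfg)
  vm <- unclass(v); dm <- unclass(def)
  vm[20:28, 20:28, 20:28] <- NaN
  dm[20:28, 20:28, 20:28] <- NaN
  f_mask <- run_dvc(bone_volume(vm, 25), bone_volume(dm, 25), cfg)
  # influence region of a node: center +/- (subset half + search radius);
  # masked block occupies 0-based coordinates 19..27
  reach <- 4 + 3
  far <- apply(f_clean$nodes, 1, function(n)
    any(n + reach < 19 | n - reach > 27))
  expect_gt(sum(far), 50)
  expect_identical(f_mask$u[far, ], f_clean$u[far, ])
})

test_that("dvc configuration rejects invalid settings", {
  expect_error(dvc_config(subset_side_vox = 16), "odd")
  expect_error(dvc_config(node_spacing_vox = 0), "node_spacing_vox")
  expect_error(dvc_config(min_valid_fraction = 0), "min_valid_fraction")
  expect_error(run_dvc(smooth_texture(c(32, 32, 32)),
                       smooth_texture(c(32, 32, 34))), "congruent")
})

test_that("map resolution bookkeeping: spacing 4 at 25 um gives 100 um maps", {
  v <- smooth_texture(c(40, 40, 40), seed = 15, voxel_size_um = 25)
  f <- run_dvc(v, v, dvc_config(node_spacing_vox = 4, subset_side_vox = 9))
  expect_equal(map_resolution(f), 100)
})
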