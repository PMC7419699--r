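test_that("error report: zero on identical scans, closed-form moments, CSV recomputation", {
  v <- smooth_texture(c(40, 40, 40), seed = 18)
  f0 <- run_dvc(v, v, dvc_config(subset_side_vox = 9))
  er0 <- dvc_error_report(f0)
  expect_equal(er0$displacement$accuracy_um, rep(0, 3))
  expect_equal(er0$displacement$precision_um, rep(0, 3))

  # constructed field: u_z alternating +a / -a over an even node count
  # -> accuracy 0, precision a (population standard deviation)
  a <- 0.3
  fc <- analytic_field(dims = c(40, 40, 36))
  expect_true(nrow(fc$u) %% 2 == 0)
  fc$u[, 1] <- a * rep_len(c(1, -1), nrow(fc$u))
  erc <- dvc_error_report(fc, voxel_size_um = 25)
  expect_equal(erc$displacement$accuracy_um[1], 0)
  expect_equal(erc$displacement$precision_um[1], a * 25)

  # report values match a brute recomputation from the exported table
  def <- add_noise(v, 2, 4)
  f <- run_dvc(v, def, dvc_config(subset_side_vox = 9))
  s <- run_strain(f)
  er <- dvc_error_report(f, s)
  out <- file.path(tempdir(), "err_field")
  write_field(f, out)
  tab <- read.csv(file.path(out, "table.csv"))
  okt <- tab$status == "ok"
  expect_equal(er$displacement$accuracy_um[1], mean(tab$u_z_um[okt]),
               tolerance = 1e-6)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(er$displacement$precision_um[2], psd(tab$u_y_um[okt]),
               tolerance = 1e-6)
  stab <- as.data.frame(s)
  oks <- stab$status == "ok"
  pooled <- abs(unlist(stab[oks, c("exx", "eyy", "ezz",
                                   "eyx", "ezx", "ezy")])) * 1e6
  expect_equal(unname(er$strain[["accuracy_ue"]]), mean(pooled))
  expect_equal(unname(er$strain[["precision_ue"]]), psd(pooled))
})

test_that("cylindrical BV/TV: solid, half-solid, and refused partial ROIs", {
  d <- c(120, 100, 100)
  solid <- array(TRUE, d)
  m1 <- bvtv_cylinder(solid, screw_max_radius_um = 250,
                      radial_extent_um = 500, axial_span_um = 2000,
                      voxel_size_um = 25)
  expect_equal(m1$bvtv, 1)

  # solid exactly on one side of the axis: ring symmetry gives 1/2
  ctr <- (d - 1) / 2
  half <- array(FALSE, d)
  ys <- slice.index(half, 2) - 1
  half[ys > ctr[2]] <- TRUE
  m2 <- bvtv_cylinder(half, 250, 500, 2000, voxel_size_um = 25)
  expect_equal(m2$bvtv, 0.5)
  expect_equal(m2$n_total, m2$n_solid * 2)

  expect_error(bvtv_cylinder(solid, 1300, 500, 2000, voxel_size_um = 25),
               "ROI")
  expect_error(bvtv_cylinder(solid, 250, 500, 4000, voxel_size_um = 25),
               "ROI")
})

test_that("BV/TV is invariant to intensity rescaling before binarisation", {
  spec <- phantom_spec(dims = c(96, 96, 96), screw_radius_um = 0,
                       seed = 19)
  v <- make_trabecular_volume(spec)
  bin1 <- unclass(v) >= isodata_threshold(v)
  v2 <- bone_volume(3 * unclass(v) + 10, 25)
  bin2 <- unclass(v2) >= isodata_threshold(v2)
  m1 <- bvtv_cylinder(bin1, 200, 400, 1500, voxel_size_um = 25)
  m2 <- bvtv_cylinder(bin2, 200, 400, 1500, voxel_size_um = 25)
  expect_equal(m1$bvtv, m2$bvtv, tolerance = 1e-3)
})

test_that("screw-plateau geometry: angles and distances by closed form", {
  horiz <- list(point = c(0, 0), dir = c(1, 0))
  expect_equal(screw_plateau_geometry(horiz, horiz, c(3, 0))$tilt_deg, 0)

  diag45 <- list(point = c(0, 0), dir = c(1, 1))
  g <- screw_plateau_geometry(diag45, horiz, c(0, 7.2))
  expect_equal(g$tilt_deg, 45)
  expect_equal(g$plateau_distance_mm, 7.2)

  expect_error(screw_plateau_geometry(list(point = c(0, 0), dir = c(0, 0)),
                                      horiz, c(0, 1)), "zero-length")
})

test_that("pearson correlation: exact lines, hand-computed r, invariances", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  px <- c(1, 2, 3, 4); py <- c(2, 3, 5, 9)
  # closed form: Sxy / sqrt(Sxx Syy) = 11.5 / sqrt(5 * 28.75)
  want <- 11.5 / sqrt(5 * 28.75)
  got <- pearson_r(px, py)
  expect_equal(got$r, want, tolerance = 1e-12)
  expect_equal(got$r2, want^2, tolerance = 1e-12)
  expect_lt(got$p, 0.05)

  # symmetry and sign-preserving affine invariance
  expect_equal(pearson_r(px, py)$r, pearson_r(py, px)$r)
  expect_equal(pearson_r(3 * px + 7, py)$r, got$r, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3")
})
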