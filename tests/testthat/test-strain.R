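test_that("displacement smoothing equals a brute-force 3x3x3 median", {
  f <- analytic_field(dims = c(40, 40, 40), spacing = 4,
                      ufun = function(p) cbind(sin(p[, 1] / 5),
                                               cos(p[, 2] / 7),
                                               p[, 3] * 0))
  set.seed(16)
  f$u <- f$u + matrix(rnorm(length(f$u), 0, 0.2), ncol = 3)
  sm <- smooth_displacements(f, 1)
  gd <- f$grid_dims
  edge <- function(n) c(1, n)
  for (c in 1:3) {
    want <- brute_median3d(array(f$u[, c], gd), 1, cubic = TRUE)
    # edge nodes (truncated window) keep their original value
    orig <- array(f$u[, c], gd)
    want[edge(gd[1]), , ] <- orig[edge(gd[1]), , ]
    want[, edge(gd[2]), ] <- orig[, edge(gd[2]), ]
    want[, , edge(gd[3])] <- orig[, , edge(gd[3])]
    expect_equal(array(sm$u[, c], gd), want)
  }
  # constant field unchanged; single interior outlier replaced
  fc <- analytic_field(ufun = function(p) cbind(p[, 1] * 0 + 2,
                                                p[, 2] * 0, p[, 3] * 0))
  expect_equal(smooth_displacements(fc, 1)$u, fc$u)
  fo <- fc
  mid <- which(fo$nodes[, 1] == fo$axes$z[4] &
                 fo$nodes[, 2] == fo$axes$y[4] &
                 fo$nodes[, 3] == fo$axes$x[4])
  fo$u[mid, 1] <- 50
  expect_equal(unname(smooth_displacements(fo, 1)$u[mid, 1]), 2)
})

test_that("deformation gradient: identity, exact linear fields, quadratic convergence", {
  f0 <- analytic_field()
  expect_equal(deformation_gradient(f0, c(1, 1, 1)), diag(3))

  # u_x = 0.1 X (X the x coordinate): F11 = 1.1 exactly, no cross terms
  fl <- analytic_field(ufun = function(p)
    cbind(0 * p[, 1], 0 * p[, 2], 0.1 * p[, 3]))
  Fm <- deformation_gradient(fl, c(2, 3, 4))
  expect_equal(Fm, matrix(c(1.1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3))

  # smooth quadratic field vs central finite differences at node spacing h
  h <- 4
  fq <- analytic_field(dims = c(60, 60, 60), spacing = h,
                       ufun = function(p) cbind(1e-4 * p[, 1]^2,
                                                0 * p[, 2], 0 * p[, 3]))
  el <- c(3, 3, 3)
  Fq <- deformation_gradient(fq, el)
  zc <- fq$axes$z[el[1]] + h / 2  # element-centre z coordinate
  fd <- (1e-4 * (zc + h / 2)^2 - 1e-4 * (zc - h / 2)^2) / h
  expect_equal(Fq[3, 3], 1 + fd, tolerance = 1e-8)
})

test_that("Green-Lagrange strain: closed forms and rotation objectivity", {
  expect_equal(unname(green_lagrange(diag(3))), rep(0, 6))
  F1 <- diag(3); F1[1, 1] <- 1.1
  e <- green_lagrange(F1)
  expect_equal(unname(e[["exx"]]), 0.105)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  expect_lt(max(abs(green_lagrange(R))), 1e-12)
})

test_that("volumetric strain closed forms", {
  expect_equal(volumetric_strain(diag(3)), 0)
  expect_equal(volumetric_strain(1.01 * diag(3)), 0.030301,
               tolerance = 1e-12)
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  expect_lt(abs(volumetric_strain(R)), 1e-12)
})

test_that("maximum shear strain: zero, isotropy, and the printed closed form", {
  z6 <- c(exx = 0, eyy = 0, ezz = 0, eyx = 0, ezx = 0, ezy = 0)
  expect_equal(max_shear(z6), 0)
  iso <- c(exx = 0.03, eyy = 0.03, ezz = 0.03, eyx = 0, ezx = 0, ezy = 0)
  expect_equal(max_shear(iso), 0)
  one <- c(exx = 0.105, eyy = 0, ezz = 0, eyx = 0, ezx = 0, ezy = 0)
  expect_equal(max_shear(one), 0.07, tolerance = 1e-12)
  # gamma is non-negative on random symmetric strain states
  set.seed(17)
  for (i in 1:50) {
    e <- stats::setNames(as.list(rnorm(6, 0, 0.05)),
                         c("exx", "eyy", "ezz", "eyx", "ezx", "ezy"))
    expect_gte(max_shear(e), 0)
  }
})

test_that("strain chain: translation invariance and affine exactness per element", {
  # rigid translation: all strain outputs vanish
  ft <- analytic_field(ufun = function(p)
    cbind(1.7 + 0 * p[, 1], -0.4 + 0 * p[, 2], 0.9 + 0 * p[, 3]))
  st <- run_strain(ft)
  expect_lt(max(abs(st$E)), 1e-10)
  expect_lt(max(abs(st$vol_strain)), 1e-10)
  expect_lt(max(st$max_shear), 1e-10)

  # imposed affine F: every element reproduces it exactly
  Fim <- matrix(c(1.02, 0.01, 0, 0.005, 0.99, 0, 0, 0.002, 1.03), 3, 3,
                byrow = TRUE)  # (x, y, z) ordering
  fa <- analytic_field(ufun = function(p) {
    X <- p[, 3]; Y <- p[, 2]; Z <- p[, 1]
    ux <- (Fim[1, 1] - 1) * X + Fim[1, 2] * Y + Fim[1, 3] * Z
    uy <- Fim[2, 1] * X + (Fim[2, 2] - 1) * Y + Fim[2, 3] * Z
    uz <- Fim[3, 1] * X + Fim[3, 2] * Y + (Fim[3, 3] - 1) * Z
    cbind(uz, uy, ux)
  })
  Eim <- green_lagrange(Fim)
  sa <- run_strain(fa)
  for (nm in names(Eim))
    expect_equal(max(abs(sa$E[, nm] - Eim[[nm]])), 0, tolerance = 1e-12)
  expect_equal(unname(sa$vol_strain), rep(det(Fim) - 1, nrow(sa$E)),
               tolerance = 1e-12)

  # adding a constant to every node changes nothing
  fb <- fa
  fb$u <- fb$u + rep(c(0.3, -0.2, 0.1), each = nrow(fb$u))
  sb <- run_strain(fb)
  expect_equal(sb$E, sa$E, tolerance = 1e-12)
})

test_that("elements with failed corner nodes are flagged, grid shrinks by one", {
  f <- analytic_field(dims = c(40, 40, 40))
  f$status[5] <- "insufficient_valid"
  f$u[5, ] <- NA
  s <- run_strain(f, smooth_radius = 0)
  expect_equal(s$grid_dims, f$grid_dims - 1L)
  bad <- s$status == "failed"
  expect_gt(sum(bad), 0)
  expect_true(all(is.nan(s$E[bad, ])))
  expect_error(run_strain(analytic_field(dims = c(40, 40, 40),
                                         spacing = 30)), "valid nodes")
})
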