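p0 <- cell_parameters()

test_that("reference mesh reproduces the disc and nucleus geometry", {
  mesh <- build_reference_mesh(p0, 0.1)
  expect_gt(sum(mesh$area) / (pi), 0.99)
  expect_lt(sum(mesh$area) / (pi), 1.01)
  nuc_frac <- sum(mesh$area[mesh$region == "nucleus"]) / sum(mesh$area)
  expect_equal(nuc_frac, (0.256 * sqrt(pi))^2, tolerance = 0.02)
  # equilateral estimate: ~4 pi / (sqrt(3) e^2) elements
  n_est <- 4 * pi / (sqrt(3) * 0.1^2)
  expect_gt(nrow(mesh$triangles), n_est / 2)
  expect_lt(nrow(mesh$triangles), n_est * 2)
  expect_gte(mesh$min_angle, 15)
})

test_that("mesh text export round-trips", {
  mesh <- coarse_mesh()
  f <- withr::local_tempfile(fileext = ".txt")
  write_mesh(mesh, f)
  m2 <- read_mesh(f)
  expect_equal(m2$nodes, unname(mesh$nodes), tolerance = 1e-14)
  expect_equal(m2$triangles, unname(mesh$triangles))
  expect_equal(as.character(m2$region), as.character(mesh$region))
  expect_setequal(m2$rim, mesh$rim)
})

test_that("spline displacement has partition of unity and linear precision", {
  set.seed(1)
  X <- cbind(runif(40, -1, 1), runif(40, -1, 1))
  # constant control displacements reproduce the constant
  cnst <- control_net(matrix(rep(c(0.3, -0.2), each = 16), 16, 2))
  u <- nurbs_displacement(cnst, X)
  expect_equal(u, cbind(rep(0.3, 40), rep(-0.2, 40)), tolerance = 1e-14)
  # zero net
  expect_equal(nurbs_displacement(control_net(), X), matrix(0, 40, 2))
  # affine control values give the exact affine field
  A <- matrix(c(0.2, -0.1, 0.05, 0.15), 2, 2)
  aff <- affine_net(A, c(0.02, -0.07))
  u2 <- nurbs_displacement(aff, X)
  expect_equal(u2, t(A %*% t(X)) + rep(c(0.02, -0.07), each = 40),
               tolerance = 1e-12)
  expect_error(nurbs_displacement(aff, c(1.5, 0)), "parameter domain")
})

test_that("deformation kinematics are exact for homogeneous stretches", {
  mesh <- coarse_mesh()
  cfg0 <- deform(mesh, control_net(), p0)
  expect_true(cfg0$admissible)
  expect_equal(range(cfg0$lI), c(1, 1), tolerance = 1e-12)
  expect_equal(range(cfg0$thickness), rep(p0$b0_over_R0, 2), tolerance = 1e-12)

  cfg <- deform(mesh, affine_net(diag(c(0.3, -0.2))), p0)
  expect_equal(range(cfg$F[, 1]), c(1.3, 1.3), tolerance = 1e-12)
  expect_equal(range(cfg$F[, 4]), c(0.8, 0.8), tolerance = 1e-12)
  expect_equal(range(cfg$lI), c(1.3, 1.3), tolerance = 1e-12)
  expect_equal(range(cfg$lII), c(0.8, 0.8), tolerance = 1e-12)
  # incompressibility: b * lI * lII = b0 on every element
  expect_equal(cfg$thickness * cfg$lI * cfg$lII,
               rep(p0$b0_over_R0, length(cfg$lI)), tolerance = 1e-12)
})

test_that("fold-over is detected as inadmissible", {
  mesh <- coarse_mesh()
  cfg <- deform(mesh, affine_net(diag(c(-1.5, 0))), p0)
  expect_false(cfg$admissible)
  expect_error(solve_unbound(cfg, mesh, p0), "folded|invalid")
})

test_that("geometry observables recover circles, ellipses and squares", {
  circ <- geometry_observables(circle_poly(0.92, 512))
  expect_equal(circ$A, pi * 0.92^2, tolerance = 1e-3)
  expect_equal(circ$AS, 1, tolerance = 1e-6)
  expect_equal(circ$FF, 1, tolerance = 0.01)
  expect_true(circ$simple)

  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- geometry_observables(cbind(2 * cos(th), sin(th)))
  expect_equal(ell$AS, 2, tolerance = 1e-4)
  # major axis along x1: angle from the stripe (x2) axis is pi/2
  expect_equal(abs(ell$phi_cell), pi / 2, tolerance = 1e-6)

  sq <- geometry_observables(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$FF, 4 / pi, tolerance = 1e-12)
  expect_equal(sq$A, 1)
})

test_that("shape metrics are invariant to vertex ordering and translation", {
  poly <- circle_poly(1, 100) %*% diag(c(1.7, 0.6))
  g1 <- geometry_observables(poly)
  # rotated starting vertex and reversed orientation
  g2 <- geometry_observables(poly[c(37:100, 1:36), ])
  g3 <- geometry_observables(poly[rev(seq_len(100)), ])
  g4 <- geometry_observables(sweep(poly, 2, c(3.2, -1.4), "+"))
  for (g in list(g2, g3, g4)) {
    expect_equal(g$A, g1$A, tolerance = 1e-12)
    expect_equal(g$AS, g1$AS, tolerance = 1e-10)
    expect_equal(g$FF, g1$FF, tolerance = 1e-12)
  }
  expect_equal(g2$phi_cell, g1$phi_cell, tolerance = 1e-10)
  expect_equal(g4$centroid, g1$centroid + c(3.2, -1.4), tolerance = 1e-10)
})

test_that("rigid translation moves the centroid and nothing else", {
  mesh <- coarse_mesh()
  net <- random_net(7)
  cfg1 <- deform(mesh, net, p0)
  cfg2 <- deform(mesh, translate_net(net, c(0.8, -0.3)), p0)
  g1 <- geometry_observables(cfg1); g2 <- geometry_observables(cfg2)
  expect_equal(g2$centroid, g1$centroid + c(0.8, -0.3), tolerance = 1e-12)
  expect_equal(g2$A, g1$A, tolerance = 1e-12)
  expect_equal(g2$AS, g1$AS, tolerance = 1e-12)
  expect_equal(g2$FF, g1$FF, tolerance = 1e-12)
})

test_that("sub-wavelength features are strongly attenuated by the spline", {
  mesh <- coarse_mesh()
  X <- mesh$nodes
  # high-frequency displacement field, wavelength ~ R0/3 << patch resolution
  target <- cbind(0.1 * sin(6 * pi * X[, 1]), numeric(nrow(X)))
  B <- hlecell:::patch_basis(X)
  dfit <- qr.solve(crossprod(B), crossprod(B, target))
  u <- B %*% dfit
  attenuation <- max(abs(u[, 1])) / 0.1
  expect_lt(attenuation, 0.35)
})

test_that("stripe admissibility and barrier behave as specified", {
  mesh <- coarse_mesh()
  lam <- suspension_state(p0)$lambda
  cfg <- deform(mesh, suspension_net(lam), p0)
  unpat <- stripe_admissible(cfg, stripe_pattern(Inf))
  expect_true(unpat$admissible)
  expect_identical(unpat$barrier, 0)
  # suspension circle (radius 0.92ish) on a W_hat = 1 stripe: admissible
  on1 <- stripe_admissible(cfg, stripe_pattern(1))
  expect_true(on1$admissible)
  expect_equal(on1$barrier, 0)
  # a node beyond the stripe edge: inadmissible, positive barrier
  wide <- deform(mesh, affine_net(diag(c(0.8, 0))), p0)
  off <- stripe_admissible(wide, stripe_pattern(1))
  expect_false(off$admissible)
  expect_gt(off$barrier, 0)
})
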