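test_that("area normalisation is affine with the stated anchors", {
  expect_equal(normalized_area(3, 3, 7), 0)
  expect_equal(normalized_area(7, 3, 7), 1)
  expect_equal(normalized_area(5, 3, 7), 0.5)
  expect_equal(normalized_area(c(3, 4, 5, 7), 3, 7), c(0, 0.25, 0.5, 1))
  expect_error(normalized_area(1, 2, 2), "degenerate")
})

test_that("squared displacements and MSD follow the definitions", {
  X <- matrix(0, 5, 3); Y <- matrix(0, 5, 3)
  m0 <- msd(X, Y, t_hat = 0:4)
  expect_equal(m0$MSD, rep(0, 5))
  X[5, 1] <- 3; Y[5, 1] <- 4
  m1 <- msd(X, Y, t_hat = 0:4)
  expect_equal(m1$R2[5, 1], 25)
  expect_equal(m1$MSD[5], 25 / 3)
  expect_error(msd(X, Y[, 1:2]), "mismatch")
})

test_that("random-walk MSD slope matches the closed form", {
  set.seed(12)
  s <- 0.1; n <- 200; frames <- 400
  X <- apply(matrix(rnorm(frames * n, 0, s), frames), 2, cumsum)
  Y <- apply(matrix(rnorm(frames * n, 0, s), frames), 2, cumsum)
  X <- rbind(0, X); Y <- rbind(0, Y)
  m <- msd(X, Y, t_hat = 0:frames)
  expect_equal(m$slope, 2 * s^2, tolerance = 0.05)
})

test_that("dimensionality parameter distinguishes 2D from 1D motion", {
  set.seed(3)
  n <- 400; frames <- 200
  dx <- matrix(rnorm(frames * n, 0, 0.1), frames)
  dy <- matrix(rnorm(frames * n, 0, 0.1), frames)
  X <- rbind(0, apply(dx, 2, cumsum)); Y <- rbind(0, apply(dy, 2, cumsum))
  iso <- directional_msd(X, Y)
  expect_equal(mean(iso$Lambda_hat[-(1:20)]), 1, tolerance = 0.1)
  expect_true(is.na(iso$Lambda_hat[1]))
  # motion purely along the stripe axis
  axis <- directional_msd(0 * X, Y)
  expect_equal(max(abs(axis$Lambda_hat[-1])), 0)
  # direct evaluation: MSD 10, MSD_y 7.5 -> 0.5
  X2 <- rbind(0, matrix(sqrt(2.5), 1, 4)); Y2 <- rbind(0, matrix(sqrt(7.5), 1, 4))
  expect_equal(directional_msd(X2, Y2)$Lambda_hat[2], 0.5, tolerance = 1e-12)
})

test_that("confined transverse motion drives Lambda toward zero", {
  set.seed(8)
  n <- 300; frames <- 600; w <- 0.5
  dy <- matrix(rnorm(frames * n, 0, 0.1), frames)
  Y <- rbind(0, apply(dy, 2, cumsum))
  # reflected random walk in x within |x| <= w
  X <- matrix(0, frames + 1, n)
  for (t in 2:(frames + 1)) {
    xn <- X[t - 1, ] + rnorm(n, 0, 0.1)
    xn <- ifelse(xn > w, 2 * w - xn, ifelse(xn < -w, -2 * w - xn, xn))
    X[t, ] <- xn
  }
  confined <- directional_msd(X, Y)
  late <- seq(round(0.8 * frames), frames)
  expect_lt(mean(confined$Lambda_hat[late]), 0.3)
})

test_that("nematic order parameter handles the canonical configurations", {
  expect_equal(order_parameter(rep(0.3, 10)), 1, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2)), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 4)), sqrt(0.5), tolerance = 1e-12)
  expect_error(order_parameter(numeric(0)), "angles")
  # rotation invariance of the doubled-angle construction
  set.seed(5)
  phi <- runif(50, -pi / 2, pi / 2)
  for (shift in c(0.3, 1.2)) {
    shifted <- (phi + shift + pi / 2) %% pi - pi / 2
    expect_equal(order_parameter(shifted), order_parameter(phi),
                 tolerance = 1e-10)
  }
})

test_that("cytoskeletal order centres the direction field before averaging", {
  vol <- rep(1, 100)
  expect_equal(cyto_order(rep(0.4, 100), vol), 1, tolerance = 1e-12)
  # two equal-volume domains at +/- 45 degrees: doubled angles cancel
  expect_equal(cyto_order(rep(c(pi / 4, -pi / 4), 50), vol), 0,
               tolerance = 1e-12)
  # near-uniform distribution: order close to zero
  expect_lt(cyto_order(seq(-pi / 2 + 0.001, pi / 2 - 0.001,
                           length.out = 500), rep(1, 500)), 0.01)
  # ensemble input: mean over configurations
  two <- cyto_order(list(rep(0.2, 100), rep(c(pi / 4, -pi / 4), 50)), vol)
  expect_equal(two, 0.5, tolerance = 1e-12)
})

test_that("cytoskeletal order reads dominant fibre directions off a configuration", {
  p0 <- cell_parameters()
  mesh <- coarse_mesh()
  # uniaxial stretch along the stripe axis: every element's dominant bundle
  # aligns with x2 (phi_max = 0), so the order parameter is 1
  cfg <- deform(mesh, affine_net(diag(c(0, 0.5))), p0)
  st <- solve_unbound(cfg, mesh, p0, angular_grid(13))  # odd: a bin at phi = 0
  sf <- staining_fields(mesh, cfg, st)
  cyto <- mesh$region == "cytoplasm"
  expect_equal(sf$elements$phi_max[cyto], rep(0, sum(cyto)), tolerance = 1e-9)
  expect_equal(cyto_order(sf$elements$phi_max[cyto], mesh$area[cyto]), 1,
               tolerance = 1e-9)
})

test_that("timescale fits recover tau exactly, covariantly, and under noise", {
  t <- seq(0, 60, by = 0.25)
  x <- 2 - (2 - 0.5) * exp(-t / 7)
  f <- fit_timescale(t, x, x_R = 0.5, x_inf = 2)
  expect_equal(f$tau, 7, tolerance = 1e-6)
  # rescaling the time axis rescales tau
  f2 <- fit_timescale(3 * t, x, x_R = 0.5, x_inf = 2)
  expect_equal(f2$tau, 21, tolerance = 1e-6)
  expect_error(fit_timescale(t, rep(1, length(t))), "flat")
  # Monte-Carlo oracle: 5% noise, 200 points, tau recovered within 10%
  set.seed(21)
  tn <- seq(0, 60, length.out = 200)
  xn <- 2 - 1.5 * exp(-tn / 7) + rnorm(200, 0, 0.05 * 1.5)
  fn <- fit_timescale(tn, xn, x_R = 0.5, x_inf = 2)
  expect_equal(fn$tau, 7, tolerance = 0.1)
})

test_that("ensemble summaries aggregate a small simulated ensemble", {
  mod <- coarse_model(Inf)
  st <- simulation_settings(dt_hat = 0.01, T_sim_hat = 1, thin = 10,
                            scheme = "forward")
  ens <- run_ensemble(mod, 2, n_traj = 3, st, seed = 40)
  s <- ensemble_summary(ens)
  expect_equal(s$n, 3)
  expect_equal(length(s$t_hat), nrow(ens[[1]]))
  expect_equal(s$mean$A_hat[1], 0)
  expect_equal(s$MSD[1], 0)
  expect_true(all(s$Theta >= 0 & s$Theta <= 1))
  expect_true(all(is.finite(s$mean$AS)))
})
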