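p0 <- cell_parameters()

test_that("steady-state functional unit count is linear in stretch", {
  expect_equal(steady_state_units(1.354, p0), 1)
  expect_equal(steady_state_units(1, p0), 1 / 1.354, tolerance = 1e-12)
  expect_equal(steady_state_units(2.708, p0), 2, tolerance = 1e-12)
  expect_error(steady_state_units(-0.1, p0), "positive")
})

test_that("bound enthalpy combines reference potential and isometric work", {
  # no mechanical work term: mu_b = mu_b0
  expect_equal(bound_enthalpy(cell_parameters(sigma_max = 0)), 1)
  expect_equal(bound_enthalpy(cell_parameters(Omega_log10_um3 = -300)), 1)
  # hand evaluation with the default constants: mu_b0 - sigma*Omega*(1+eps)/kBT
  kBT <- 1.380649e-23 * 310
  expected <- 1 - 240e3 * 10^-7.1 * 1e-18 * 1.354 / kBT
  expect_equal(bound_enthalpy(p0), expected, tolerance = 1e-12)
})

test_that("angular concentration follows the equilibrium closed forms", {
  # no free protein: no bound fibres
  expect_equal(angular_concentration(0, 1, p0), 0)
  # equal potentials (exponent zero): eta = Nu*eta_max/(pi*nss*eta_max + Nu)
  peq <- cell_parameters(sigma_max = 0, dmu_over_kBT = 0)
  nss <- 1.2 / 1.354
  expect_equal(angular_concentration(0.4, 1.2, peq),
               0.4 * 0.75 / (pi * nss * 0.75 + 0.4), tolerance = 1e-12)
  # saturation bound for any stretch (attained only in the underflow limit)
  for (lam in c(0.3, 1, 3, 10, 40)) {
    eta <- angular_concentration(0.9, lam, p0)
    expect_lte(eta, p0$eta_max)
    expect_gte(eta, 0)
    if (lam <= 3) expect_lt(eta, p0$eta_max)
  }
  # monotone in Nu_hat
  lam <- 1.3
  etas <- angular_concentration(seq(0.1, 0.9, 0.2), lam, p0)
  expect_true(all(diff(etas) > 0))
})

test_that("conservation solve matches a brute-force scan and is tight", {
  mesh <- coarse_mesh()
  cfg <- deform(mesh, control_net(), p0)      # uniform lambda = 1
  st <- solve_unbound(cfg, mesh, p0, angular_grid(12))
  expect_lt(abs(st$residual), 1e-10)
  # brute-force oracle: scan the residual on a 1e-6 grid
  grid <- angular_grid(12)
  nss <- 1 / 1.354
  resid <- function(Nu) {
    eta <- angular_concentration(Nu, 1, p0)
    Nu + pi * eta * nss - 1
  }
  Nus <- seq(1e-6, 1, by = 1e-6)
  resids <- Nus + pi * angular_concentration(Nus, 1, p0) * nss - 1
  i <- which.min(abs(resids))
  expect_equal(resids[i], resid(Nus[i]), tolerance = 1e-12) # same oracle
  expect_lt(abs(st$Nu_hat - Nus[i]), 1e-6)
  # all protein unbound when fibre formation is impossible
  tiny <- cell_parameters(eta_max = 1e-12)
  st0 <- solve_unbound(deform(mesh, control_net(), tiny), mesh, tiny,
                       angular_grid(12))
  expect_equal(st0$Nu_hat, 1, tolerance = 1e-9)
})

test_that("unbound potential follows the ideal-solution log law", {
  expect_equal(unbound_potential(p0$pi_NL, p0), p0$mu_u)
  expect_equal(unbound_potential(0.6, p0) - unbound_potential(0.3, p0),
               log(2), tolerance = 1e-12)
  expect_equal(unbound_potential(0.5, p0), log(0.5), tolerance = 1e-12)
  expect_error(unbound_potential(0, p0), "positive")
})

test_that("bound and unbound potentials are equal at the solved state", {
  mesh <- coarse_mesh()
  for (seed in 1:5) {
    st <- solve_unbound(deform(mesh, random_net(seed), p0), mesh, p0,
                        angular_grid(12))
    chib <- bound_potential(st, p0)
    expect_lt(max(abs(chib - st$chi_u) / abs(st$chi_u)), 1e-8)
  }
})

test_that("passive energy density has the documented special cases", {
  expect_equal(passive_energy_density(1, 1, "cytoplasm", p0), 0)
  expect_equal(passive_energy_density(1, 1, "nucleus", p0), 0)
  # equibiaxial: deviatoric bracket vanishes, pure bulk
  lam <- 1.2
  expect_equal(passive_energy_density(lam, lam, "cytoplasm", p0),
               p0$kappa_C / 2 * (lam^2 - 1)^2, tolerance = 1e-12)
  # penalty is continuous at activation
  lI <- 1.0; lII <- p0$Jc / lI
  just_below <- passive_energy_density(lI, lII * (1 - 1e-9), "cytoplasm", p0)
  just_above <- passive_energy_density(lI, lII * (1 + 1e-9), "cytoplasm", p0)
  expect_equal(just_below, just_above, tolerance = 1e-6)
  expect_true(all(passive_energy_density(c(0.5, 0.9, 1.4), c(0.4, 1.1, 0.7),
                                         "nucleus", p0) >= 0))
})

test_that("passive stress matches the finite-difference oracle", {
  expect_equal(passive_stress(1, 1, c(1, 0), "cytoplasm", p0),
               matrix(0, 2, 2))
  # equibiaxial stretch: isotropic stress
  s <- passive_stress(1.3, 1.3, c(0.6, 0.8), "nucleus", p0)
  expect_equal(s[1, 1], s[2, 2], tolerance = 1e-12)
  expect_equal(s[1, 2], 0, tolerance = 1e-12)
  set.seed(4)
  for (k in 1:6) {
    lI <- runif(1, 0.8, 1.6); lII <- runif(1, 0.5, min(lI, 1.2))
    reg <- sample(c("cytoplasm", "nucleus"), 1)
    h <- 1e-6
    num_I <- lI * (passive_energy_density(lI + h, lII, reg, p0) -
                   passive_energy_density(lI - h, lII, reg, p0)) / (2 * h)
    num_II <- lII * (passive_energy_density(lI, lII + h, reg, p0) -
                     passive_energy_density(lI, lII - h, reg, p0)) / (2 * h)
    an <- hlecell:::passive_principal_stresses(lI, lII, reg, p0)
    expect_equal(an[1], num_I, tolerance = 1e-6)
    expect_equal(an[2], num_II, tolerance = 1e-6)
  }
})

test_that("active stress reduces to the analytic angular integrals", {
  mesh <- coarse_mesh()
  cfg <- deform(mesh, control_net(), p0)  # lambda = 1 everywhere
  st <- solve_unbound(cfg, mesh, p0, angular_grid(36))
  act <- active_stress(cfg, st, p0)
  c_iso <- st$eta_hat[1, 1]
  expect_equal(max(abs(st$eta_hat - c_iso)), 0, tolerance = 1e-12)
  expected <- pi / 2 * p0$H0 * p0$sigma_max * c_iso
  cyto <- mesh$region == "cytoplasm"
  expect_equal(act[cyto, 1], rep(expected, sum(cyto)), tolerance = 1e-10)
  expect_equal(act[cyto, 3], rep(expected, sum(cyto)), tolerance = 1e-10)
  expect_equal(act[cyto, 2], rep(0, sum(cyto)), tolerance = 1e-12)
  # nucleus elements carry no active stress
  expect_equal(act[!cyto, ], matrix(0, sum(!cyto), 3))

  # a single bundle along the stripe axis loads only the 22 component
  grid <- angular_grid(37)                    # odd count: a bin centred at 0
  i0 <- which.min(abs(grid$phi))
  eta <- matrix(0, sum(cyto), 37); eta[, i0] <- 0.5
  fake <- structure(list(eta_hat = eta,
                         nss_hat = matrix(1 / 1.354, sum(cyto), 37),
                         Nu_hat = 0.5, chi_u = 0, grid = grid,
                         cyto = which(cyto)), class = "cytoskeletal_state")
  act2 <- active_stress(cfg, fake, p0)
  expect_equal(act2[cyto, 1], rep(0, sum(cyto)), tolerance = 1e-12)
  expect_equal(act2[cyto, 2], rep(0, sum(cyto)), tolerance = 1e-12)
  expect_gt(min(act2[cyto, 3]), 0)
})

test_that("total free energy decomposes additively and shifts linearly in mu_u", {
  mesh <- coarse_mesh()
  net <- random_net(11)
  eb <- total_free_energy(net, mesh, p0, GS = -4, grid = angular_grid(12))
  expect_equal(eb$G, eb$cyto_term + eb$passive_cyto + eb$passive_nucleus,
               tolerance = 1e-12)
  expect_equal(eb$G_hat, eb$G / 4, tolerance = 1e-12)
  # constant shift of the unbound reference potential
  dmu <- 0.37
  p2 <- cell_parameters(mu_u = dmu)
  eb2 <- total_free_energy(net, mesh, p2, grid = angular_grid(12))
  dc <- hlecell:::derived_constants(p0)
  VC <- sum(mesh$area[mesh$region == "cytoplasm"]) * p0$b0_over_R0
  expect_equal(eb2$G - eb$G, dc$rho0_kBT_kPa * VC * dmu, tolerance = 1e-9)
  expect_equal(eb2$Nu_hat, eb$Nu_hat, tolerance = 1e-12)
})

test_that("the cytoskeletal Gibbs integral equals rho0 V_C chi_u at equilibrium", {
  mesh <- coarse_mesh()
  grid <- angular_grid(12)
  net <- random_net(3)
  cfg <- deform(mesh, net, p0)
  st <- solve_unbound(cfg, mesh, p0, grid)
  eb <- total_free_energy(net, mesh, p0, grid = grid, config = cfg, state = st)
  dc <- hlecell:::derived_constants(p0)
  cyto <- mesh$region == "cytoplasm"
  VC <- sum(mesh$area[cyto]) * p0$b0_over_R0
  chib <- bound_potential(st, p0)
  # per-element angular integral of eta * nss * chi_b, then volume integral
  bound_int <- as.numeric((st$eta_hat * st$nss_hat * chib) %*% grid$w)
  g_cyto <- dc$rho0_kBT_kPa *
    sum(mesh$area[cyto] * p0$b0_over_R0 * (st$Nu_hat * st$chi_u + bound_int))
  expect_equal(g_cyto, eb$cyto_term, tolerance = 1e-9)
})

test_that("suspension configuration evaluates exactly to G_S", {
  mod <- coarse_model(Inf)
  e <- microstate_energy(mod, suspension_net(mod$lambda_susp))
  expect_equal(e$G_hat, mod$GS_hat, tolerance = 1e-12)
})

test_that("energy is invariant under rigid rotation of the configuration", {
  mesh <- coarse_mesh()
  net <- random_net(9)
  g <- hlecell:::greville()
  gpts <- as.matrix(expand.grid(j = g, i = g))[, c("i", "j")]
  eb1 <- total_free_energy(net, mesh, p0, grid = angular_grid(12))
  for (th in c(0.4, 1.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    # compose the rigid rotation with the morphing field: x' = R (X + u)
    d2 <- t(R %*% t(gpts + net$d)) - gpts
    eb2 <- total_free_energy(control_net(d2), mesh, p0,
                             grid = angular_grid(12))
    expect_equal(eb2$G, eb1$G, tolerance = 1e-10)
  }
})

test_that("compiled and reference energy paths agree", {
  mod <- coarse_model(Inf)
  for (seed in c(2, 5, 8)) {
    net <- random_net(seed)
    eb <- total_free_energy(net, mod$mesh, p0, GS = mod$GS,
                            grid = angular_grid(12))
    ec <- microstate_energy(mod, net)
    expect_equal(ec$G_hat, eb$G_hat, tolerance = 1e-12)
    expect_equal(ec$Nu_hat, eb$Nu_hat, tolerance = 1e-10)
    expect_equal(ec$passive_cyto, eb$passive_cyto, tolerance = 1e-10)
    expect_equal(ec$passive_nucleus, eb$passive_nucleus, tolerance = 1e-10)
  }
})

test_that("traction field satisfies global equilibrium and the divergence oracle", {
  mesh <- coarse_mesh()
  cfg <- deform(mesh, control_net(), p0)
  nE <- nrow(mesh$triangles)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), mesh$rim)

  # spatially uniform stress: interior nodes carry no load
  Sig_u <- cbind(rep(2, nE), rep(0.5, nE), rep(-1, nE))
  Tu <- traction_field(mesh, cfg, Sig_u, p0)
  expect_lt(max(abs(Tu[interior, ])), 1e-12)
  expect_lt(max(abs(colSums(Tu))), 1e-12)

  # manufactured linear field: Sigma_11 = a + b x1 -> -b0 * div = (-b0 b, 0)
  b <- 2.0
  ctr <- (mesh$nodes[mesh$triangles[, 1], ] + mesh$nodes[mesh$triangles[, 2], ] +
          mesh$nodes[mesh$triangles[, 3], ]) / 3
  Sig_l <- cbind(1 + b * ctr[, 1], rep(0, nE), rep(1, nE))
  Tl <- traction_field(mesh, cfg, Sig_l, p0)
  expect_lt(max(abs(colSums(Tl))), 1e-10)
  # tributary areas of interior nodes
  A_node <- numeric(nrow(mesh$nodes))
  for (a in 1:3) {
    acc <- rowsum(mesh$area / 3, mesh$triangles[, a])
    idx <- as.integer(rownames(acc))
    A_node[idx] <- A_node[idx] + acc
  }
  tx <- Tl[interior, 1] / A_node[interior]
  expect_equal(mean(tx), -p0$b0_over_R0 * b, tolerance = 0.05)
  expect_lt(max(abs(Tl[interior, 2] / A_node[interior])), 0.02)
})

test_that("staining fields integrate the bound density and locate bundles", {
  mesh <- coarse_mesh()
  cfg <- deform(mesh, control_net(), p0)
  st <- solve_unbound(cfg, mesh, p0, angular_grid(36))
  sf <- staining_fields(mesh, cfg, st)
  cyto <- mesh$region == "cytoplasm"
  c_iso <- st$eta_hat[1, 1]
  expect_equal(sf$elements$Nb_hat[cyto], rep(pi * c_iso / 1.354, sum(cyto)),
               tolerance = 1e-10)
  expect_equal(sf$elements$Nb_hat[!cyto], rep(0, sum(!cyto)))
  # isotropic distribution: the |phi| tie-break selects the smallest bin
  expect_equal(abs(sf$elements$phi_max[cyto]),
               rep(min(abs(angular_grid(36)$phi)), sum(cyto)))

  # delta bundle at a known angle
  grid <- angular_grid(36)
  i0 <- 25
  eta <- matrix(0, sum(cyto), 36); eta[, i0] <- 0.4
  fake <- structure(list(eta_hat = eta, nss_hat = matrix(1, sum(cyto), 36),
                         Nu_hat = 0.5, chi_u = 0, grid = grid,
                         cyto = which(cyto)), class = "cytoskeletal_state")
  sf2 <- staining_fields(mesh, cfg, fake)
  expect_equal(sf2$elements$phi_max[cyto], rep(grid$phi[i0], sum(cyto)))
  zero <- structure(list(eta_hat = eta * 0, nss_hat = matrix(1, sum(cyto), 36),
                         Nu_hat = 1, chi_u = 0, grid = grid,
                         cyto = which(cyto)), class = "cytoskeletal_state")
  expect_equal(staining_fields(mesh, cfg, zero)$elements$Nb_hat,
               rep(0, nrow(mesh$triangles)))
})
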