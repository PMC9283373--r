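# Shared fixtures: coarse meshes and models are expensive to build, so they
# are memoised for the whole test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

coarse_mesh <- function() {
  fixture("mesh02", function() build_reference_mesh(cell_parameters(), 0.2))
}

coarse_model <- function(W = Inf) {
  key <- paste0("model_", W)
  fixture(key, function()
    hle_model(cell_parameters(), coarse_mesh(), stripe_pattern(W), n_phi = 12))
}

# a mildly perturbed admissible control net (deterministic in `seed`)
random_net <- function(seed, scale = 0.06) {
  set.seed(seed)
  lam <- fixture("lambda_susp", function() suspension_state()$lambda)
  control_net(suspension_net(lam)$d + matrix(rnorm(32, 0, scale), 16, 2))
}

# circle boundary polygon fixture
circle_poly <- function(r = 1, n = 256, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Coarse-scale stochastic study (calibration + 20-trajectory ensemble to
# T_hat = 200); expensive, so computed once per substrate pattern and shared
# by every test that needs it.
hle_study <- function(W) {
  key <- paste0("study_", W)
  fixture(key, function() {
    mod <- coarse_model(W)
    cal <- calibrate_zeta(mod, n_steps = 40000, burn = 10000, seed = 7)
    st <- simulation_settings(dt_hat = 0.01, T_sim_hat = 200, thin = 25,
                              scheme = "forward")
    ens <- run_ensemble(mod, cal$zeta_hat, n_traj = 20, st, seed = 1000)
    list(model = mod, cal = cal, summary = ensemble_summary(ens))
  })
}
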