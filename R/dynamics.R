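#' Simulation settings for the Langevin integrator
#'
#' @param dt_hat normalised time step (default 0.001; the coarse-mesh studies
#'   in the vignette use 0.01 after a step-halving convergence check).
#' @param T_sim_hat total simulated normalised time.
#' @param thin store every `thin`-th step.
#' @param h finite-difference step for the energy gradient.
#' @param scheme gradient scheme: `"central"` (default) or `"forward"` (half
#'   the energy evaluations; adequate when the noise dominates the O(h)
#'   truncation bias).
#' @param max_retry number of noise redraws allowed when a step folds the
#'   mesh before the trajectory aborts.
#' @param store_nets also keep the control nets of the stored frames.
#' @param gamma_R02_over_GS_minutes physical timescale `(gamma R0^2)/|G_S|` in
#'   minutes mapping `t = t_hat * timescale`; a pure relabelling of the time
#'   axis (default 10).
#' @return list of class `simulation_settings`.
#' @export
simulation_settings <- function(dt_hat = 0.001, T_sim_hat = 100, thin = 10,
                                h = 1e-6, scheme = c("central", "forward"),
                                max_retry = 100, store_nets = FALSE,
                                gamma_R02_over_GS_minutes = 10) {
  scheme <- match.arg(scheme)
  stopifnot(dt_hat > 0, T_sim_hat > 0, thin >= 1)
  structure(list(dt_hat = dt_hat, T_sim_hat = T_sim_hat, thin = as.integer(thin),
                 h = h, scheme = scheme, max_retry = as.integer(max_retry),
                 store_nets = store_nets,
                 gamma_R02_over_GS_minutes = gamma_R02_over_GS_minutes),
            class = "simulation_settings")
}

#' One Euler-Maruyama step of the homeostatic Langevin equation
#'
#' `r' = r + (-grad + sqrt(2/(zeta_hat * dt_hat)) * N(0,1)) * dt_hat`,
#' applied independently to every degree of freedom. Exposed mainly for the
#' toy-system validation suite; full-model trajectories run in the compiled
#' core.
#'
#' @param r state vector.
#' @param grad energy gradient at `r`.
#' @param zeta_hat inverse homeostatic temperature.
#' @param dt_hat time step.
#' @return updated state vector.
#' @export
langevin_step <- function(r, grad, zeta_hat, dt_hat) {
  r + (-grad + sqrt(2 / (zeta_hat * dt_hat)) * rnorm(length(r))) * dt_hat
}

#' Integrate an arbitrary energy with the Langevin scheme (R loop)
#'
#' Reference integrator for low-dimensional toy energies; use
#' [run_trajectory()] for the full cell model.
#'
#' @param energy scalar energy function (used only if `grad` is `NULL`).
#' @param grad gradient function; `NULL` for numerical central differences.
#' @param r0 initial state.
#' @param zeta_hat,dt_hat,n_steps integrator parameters.
#' @param thin keep every `thin`-th state.
#' @param seed RNG seed.
#' @return matrix of thinned states (rows).
#' @export
langevin_run <- function(energy, grad = NULL, r0, zeta_hat, dt_hat, n_steps,
                         thin = 1, seed = 1) {
  set.seed(seed)
  if (is.null(grad))
    grad <- function(x) energy_gradient(energy, x, scheme = "central", h = 1e-6)
  r <- as.numeric(r0)
  keep <- floor(n_steps / thin)
  out <- matrix(NA_real_, keep, length(r))
  k <- 0L
  for (it in seq_len(n_steps)) {
    r <- langevin_step(r, grad(r), zeta_hat, dt_hat)
    if (it %% thin == 0 && k < keep) {
      k <- k + 1L
      out[k, ] <- r
    }
  }
  out
}

#' Simulate one trajectory of the homeostatic Langevin equation
#'
#' Seeds the suspension-state circle at the origin (on the stripe axis for
#' patterned substrates) at `t_hat = 0` and integrates the normalised HLE to
#' `T_sim_hat` with the forward Euler-Maruyama scheme, storing thinned frames
#' of shape observables, centroid position and energy.
#'
#' @param model an [hle_model()].
#' @param zeta_hat inverse homeostatic temperature (e.g. from
#'   [calibrate_zeta()]).
#' @param settings a [simulation_settings()] object.
#' @param seed RNG seed; identical seeds give bit-identical trajectories.
#' @return An object of class `hle_trajectory`: data.frame with columns
#'   `t_hat`, `x_c`, `y_c`, `A`, `p`, `AS`, `phi_cell`, `FF`, `G_hat`,
#'   `Nu_hat`; attributes carry the run metadata (and control nets when
#'   requested).
#' @export
run_trajectory <- function(model, zeta_hat, settings = simulation_settings(),
                           seed = 1) {
  stopifnot(inherits(model, "hle_model"), zeta_hat > 0)
  n_steps <- as.integer(round(settings$T_sim_hat / settings$dt_hat))
  d0 <- as.numeric(suspension_net(model$lambda_susp)$d)
  set.seed(seed)
  raw <- cpp_langevin(model$cpp, d0, n_steps, settings$dt_hat, zeta_hat,
                      settings$thin, settings$h,
                      if (settings$scheme == "forward") 1L else 0L,
                      settings$max_retry, settings$store_nets)
  obs <- raw$obs
  ell <- moments_to_ellipse(obs[, 2], obs[, 6], obs[, 7], obs[, 8])
  frames <- data.frame(t_hat = obs[, 1], x_c = obs[, 4], y_c = obs[, 5],
                       A = obs[, 2], p = obs[, 3], AS = ell$AS,
                       phi_cell = ell$phi, FF = obs[, 3]^2 / (4 * pi * obs[, 2]),
                       G_hat = obs[, 9], Nu_hat = obs[, 10])
  structure(frames, class = c("hle_trajectory", "data.frame"),
            seed = seed, zeta_hat = zeta_hat, settings = settings,
            pattern = model$pattern, GS = model$GS,
            nets = if (settings$store_nets) raw$nets else NULL,
            d_final = raw$d_final, retries = raw$retries,
            substeps = raw$substeps, stalls = raw$stalls)
}

# Best-fit-ellipse aspect ratio and orientation from polygon area + central
# second moments (vectorised over frames).
moments_to_ellipse <- function(A, mxx, mxy, myy) {
  tr <- (mxx + myy) / A
  di <- sqrt(pmax(0, ((mxx - myy) / A)^2 + 4 * (mxy / A)^2))
  e1 <- (tr + di) / 2
  e2 <- pmax((tr - di) / 2, .Machine$double.eps)
  v1 <- ifelse(abs(mxy / A) > 1e-14, mxy / A, 1)
  v2 <- ifelse(abs(mxy / A) > 1e-14, e1 - mxx / A, 0)
  nv <- sqrt(v1^2 + v2^2)
  list(AS = sqrt(e1 / e2), phi = fold_axial(atan2(-v1 / nv, v2 / nv)))
}

#' Simulate an ensemble of Langevin trajectories
#'
#' @param model an [hle_model()].
#' @param zeta_hat inverse homeostatic temperature.
#' @param n_traj number of trajectories; trajectory `k` uses seed
#'   `seed + k - 1`.
#' @param settings a [simulation_settings()].
#' @param seed base seed.
#' @param cores plain per-trajectory parallel map via
#'   [parallel::mclapply()] when > 1.
#' @return An object of class `hle_ensemble`: list of `hle_trajectory`.
#' @export
run_ensemble <- function(model, zeta_hat, n_traj,
                         settings = simulation_settings(), seed = 1,
                         cores = 1) {
  seeds <- seed + seq_len(n_traj) - 1
  runner <- function(s) run_trajectory(model, zeta_hat, settings, seed = s)
  trajs <- if (cores > 1)
    parallel::mclapply(seeds, runner, mc.cores = cores)
  else lapply(seeds, runner)
  structure(trajs, class = "hle_ensemble", zeta_hat = zeta_hat,
            settings = settings, pattern = model$pattern, seed = seed)
}

#' @export
print.hle_trajectory <- function(x, ...) {
  cat(sprintf("HLE trajectory: %d frames to t_hat = %.4g (seed %d, zeta_hat %.3f)\n",
              nrow(x), max(x$t_hat), attr(x, "seed"), attr(x, "zeta_hat")))
  invisible(x)
}

#' @export
print.hle_ensemble <- function(x, ...) {
  cat(sprintf("HLE ensemble: %d trajectories, %d frames each\n",
              length(x), nrow(x[[1]])))
  invisible(x)
}
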