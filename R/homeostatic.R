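#' Metropolis sampling of the homeostatic ensemble
#'
#' Random-walk Metropolis over morphological microstates targeting the
#' stationary distribution `P_eq proportional to exp(-zeta_hat * G_hat)`. The
#' proposal perturbs one uniformly chosen control-point coordinate with a
#' Gaussian step whose size is adapted toward the target acceptance rate
#' during burn-in. Proposals that fold the mesh or protrude beyond the
#' adhesive stripe are rejected outright.
#'
#' `mcmc_sample()` is generic: for an [hle_model()] the chain runs in the
#' compiled core; for a plain energy function (toy systems) it runs in R.
#'
#' @param object an [hle_model()] or a scalar energy function of a numeric
#'   state vector.
#' @param zeta_hat inverse homeostatic temperature (dimensionless).
#' @param n_steps chain length (post-burn-in proposals).
#' @param seed RNG seed (chains are bit-reproducible).
#' @param burn burn-in proposals (step size adapts during this phase).
#' @param thin keep every `thin`-th state.
#' @param step0 initial proposal standard deviation.
#' @param step_max cap on the adapted proposal step (model chains only):
#'   moves stay below the spline feature wavelength, keeping the chain in
#'   the seeded morphological basin (see the methods vignette).
#' @param target_acc adaptation target acceptance rate.
#' @param d0 initial state; defaults to the suspension net for models.
#' @param ... unused.
#' @return list with `G_hat` (thinned energy chain), `samples` (thinned state
#'   matrix), `acceptance`, `step` (final proposal sd) and `mean_G_hat`.
#' @export
mcmc_sample <- function(object, zeta_hat, n_steps, seed = 1, ...) {
  UseMethod("mcmc_sample")
}

#' @rdname mcmc_sample
#' @export
mcmc_sample.hle_model <- function(object, zeta_hat, n_steps, seed = 1,
                                  burn = max(1000, n_steps %/% 5), thin = 10,
                                  step0 = 0.05, step_max = 0.1,
                                  target_acc = 0.3, d0 = NULL, ...) {
  stopifnot(zeta_hat > 0)
  if (is.null(d0)) d0 <- suspension_net(object$lambda_susp)
  d0 <- if (inherits(d0, "control_net")) as.numeric(d0$d) else as.numeric(d0)
  set.seed(seed)
  bu <- cpp_mcmc(object$cpp, d0, as.integer(burn), zeta_hat, step0,
                 as.integer(burn), 1L, target_acc)
  d1 <- bu$samples[nrow(bu$samples), ]
  # the proposal step is capped: microstate moves stay below the spline
  # feature wavelength, keeping the chain within the seeded morphological
  # basin (see the methods vignette)
  run <- cpp_mcmc(object$cpp, d1, as.integer(n_steps), zeta_hat,
                  min(bu$step, step_max), 0L, as.integer(thin), target_acc)
  if (bu$step < step_max) check_acceptance(run$acceptance)
  out <- list(G_hat = run$G_hat, samples = run$samples,
              acceptance = run$acceptance, step = run$step,
              mean_G_hat = mean(run$G_hat))
  class(out) <- "mcmc_ensemble"
  out
}

#' @rdname mcmc_sample
#' @export
mcmc_sample.function <- function(object, zeta_hat, n_steps, seed = 1,
                                 burn = max(200, n_steps %/% 5), thin = 1,
                                 step0 = 0.5, target_acc = 0.3, d0 = 0, ...) {
  stopifnot(zeta_hat > 0)
  set.seed(seed)
  d <- as.numeric(d0)
  e <- object(d)
  step <- step0
  n_tot <- burn + n_steps
  keep <- floor(n_steps / thin)
  G <- numeric(keep); S <- matrix(NA_real_, keep, length(d))
  acc <- 0L; acc_w <- 0L; win <- 0L; k <- 0L
  for (it in seq_len(n_tot)) {
    q <- sample.int(length(d), 1)
    prop <- d
    prop[q] <- prop[q] + step * rnorm(1)
    ep <- object(prop)
    dE <- ep - e
    if (is.finite(ep) && (dE <= 0 || runif(1) < exp(-zeta_hat * dE))) {
      d <- prop; e <- ep
      if (it > burn) acc <- acc + 1L
      acc_w <- acc_w + 1L
    }
    win <- win + 1L
    if (it <= burn && win >= 50) {
      step <- min(max(step * exp(0.8 * (acc_w / win - target_acc)), 1e-4), 50)
      acc_w <- 0L; win <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0 && k < keep) {
      k <- k + 1L
      G[k] <- e; S[k, ] <- d
    }
  }
  rate <- acc / n_steps
  check_acceptance(rate)
  out <- list(G_hat = G, samples = S, acceptance = rate, step = step,
              mean_G_hat = mean(G))
  class(out) <- "mcmc_ensemble"
  out
}

check_acceptance <- function(rate) {
  if (rate < 0.05 || rate > 0.8)
    warning(sprintf("MCMC acceptance rate %.2f outside [0.05, 0.8]; %s",
                    rate, "check the proposal step size"), call. = FALSE)
  invisible(rate)
}

#' @export
print.mcmc_ensemble <- function(x, ...) {
  cat(sprintf("MCMC ensemble: %d kept states, <G_hat> = %.4f, acceptance %.2f\n",
              length(x$G_hat), x$mean_G_hat, x$acceptance))
  invisible(x)
}

#' Calibrate the homeostatic temperature
#'
#' Finds `zeta_hat` such that the ensemble average normalised free energy
#' equals its suspension value, `<G_hat> = G_S/|G_S|` (the homeostatic
#' constraint). The average is estimated by Metropolis chains run with common
#' random numbers across `zeta_hat` iterates, which makes `<G_hat>(zeta_hat)`
#' a deterministic, monotonically decreasing function that a bracketed root
#' solve handles directly.
#'
#' @param object an [hle_model()], or a function `f(zeta_hat)` returning the
#'   ensemble mean energy (toy systems).
#' @param target target mean energy; defaults to `sign(G_S)` for models.
#' @param zeta0 initial guess.
#' @param n_steps,burn,thin,seed chain settings passed to [mcmc_sample()].
#' @param tol relative tolerance on `zeta_hat`.
#' @param ... unused.
#' @return An object of class `homeostatic_calibration`: list with
#'   `zeta_hat`, `GS`, `mean_G_hat` at the calibrated value, `acceptance`, and
#'   the bracket diagnostics.
#' @export
calibrate_zeta <- function(object, ...) UseMethod("calibrate_zeta")

#' @rdname calibrate_zeta
#' @export
calibrate_zeta.hle_model <- function(object, target = NULL, zeta0 = 20,
                                     n_steps = 40000, burn = 10000, thin = 10,
                                     seed = 1, f_tol = 0.05, max_iter = 14,
                                     ...) {
  if (is.null(target)) target <- object$GS_hat
  last <- new.env()
  f <- function(z) {
    s <- mcmc_sample(object, z, n_steps, seed = seed, burn = burn,
                     thin = thin)
    last$acc <- s$acceptance
    s$mean_G_hat - target
  }
  root <- bracketed_root(f, zeta0, f_tol, max_iter)
  structure(list(zeta_hat = root$x, GS = object$GS, GS_hat = object$GS_hat,
                 mean_G_hat = root$f + target, target = target,
                 acceptance = last$acc, bracket = root$bracket,
                 n_steps = n_steps, n_evals = root$n_evals),
            class = "homeostatic_calibration")
}

#' @rdname calibrate_zeta
#' @param f_tol stop when the mean-energy mismatch falls below this value
#'   (Monte Carlo estimates make the map noisy, so a residual tolerance is
#'   more meaningful than a tight bracket).
#' @param max_iter bisection iteration cap after bracketing.
#' @export
calibrate_zeta.function <- function(object, target, zeta0 = 1, f_tol = 0.005,
                                    max_iter = 40, ...) {
  root <- bracketed_root(function(z) object(z) - target, zeta0, f_tol,
                         max_iter)
  structure(list(zeta_hat = root$x, mean_G_hat = root$f + target,
                 target = target, bracket = root$bracket,
                 n_evals = root$n_evals),
            class = "homeostatic_calibration")
}

# Root of a monotonically decreasing, possibly Monte Carlo-noisy f: geometric
# bracket expansion followed by bisection in log space, stopping on |f| or
# the iteration cap and returning the iterate with the smallest residual.
bracketed_root <- function(f, x0, f_tol, max_iter) {
  evals <- 0L
  fe <- function(x) { evals <<- evals + 1L; f(x) }
  lo <- x0; flo <- fe(lo)
  best <- list(x = lo, f = flo)
  note <- function(x, fx) if (abs(fx) < abs(best$f)) best <<- list(x = x, f = fx)
  if (flo < 0) {
    hi <- lo; fhi <- flo
    while (flo < 0) {
      hi <- lo; fhi <- flo
      lo <- lo / 4
      if (lo < 1e-8)
        stop("calibration failed to bracket: f(", signif(lo * 4, 3), ") = ",
             signif(flo, 4), call. = FALSE)
      flo <- fe(lo); note(lo, flo)
    }
  } else {
    hi <- x0 * 4; fhi <- fe(hi); note(hi, fhi)
    while (fhi > 0) {
      lo <- hi; flo <- fhi
      hi <- hi * 4
      if (hi > 1e8)
        stop("calibration failed to bracket: f(", signif(hi / 4, 3), ") = ",
             signif(fhi, 4), call. = FALSE)
      fhi <- fe(hi); note(hi, fhi)
    }
  }
  for (it in seq_len(max_iter)) {
    if (abs(best$f) < f_tol) break
    mid <- sqrt(lo * hi)
    fm <- fe(mid); note(mid, fm)
    if (fm > 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
    if (hi / lo < 1.02) break
  }
  list(x = best$x, f = best$f, bracket = c(lo, hi), n_evals = evals)
}

#' @export
print.homeostatic_calibration <- function(x, ...) {
  cat(sprintf("Homeostatic calibration: zeta_hat = %.4f (1/zeta_hat = %.4f)\n",
              x$zeta_hat, 1 / x$zeta_hat))
  cat(sprintf("  <G_hat> = %.4f (target %.4f)\n", x$mean_G_hat, x$target))
  if (!is.null(x$acceptance))
    cat(sprintf("  final-chain acceptance %.2f\n", x$acceptance))
  invisible(x)
}
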