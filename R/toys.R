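#' Toy energy systems for validating the samplers and integrators
#'
#' Low-dimensional energies with closed-form ensemble properties, used to test
#' the Metropolis sampler, the homeostatic calibration and the Langevin
#' integrator against exact results.
#'
#' * `"quadratic"`: `G(r) = sum(k_q r_q^2)/2`. Stationary per-coordinate
#'   variance `1/(zeta k_q)`, mean excess energy `<G> - G_min = d/(2 zeta)`.
#' * `"double_well"`: `G(r) = a (r^2 - b^2)^2` (1-DOF), two symmetric wells
#'   (at plus and minus `b`) with equal occupancy.
#' * `"two_state"`: discrete two-level system with energy gap `dG`;
#'   equilibrium occupancy ratio `exp(-zeta dG)`.
#'
#' @param kind energy type.
#' @param k stiffness vector (quadratic; its length sets the dimension).
#' @param a,b double-well shape constants.
#' @param dG two-state energy gap.
#' @return list of class `toy_system` with `energy`, `grad` (where defined),
#'   `d` (dimension) and closed-form helpers `stationary_var(zeta)`,
#'   `mean_excess(zeta)`, `boltzmann_ratio(zeta)`.
#' @examples
#' toy <- make_toy_system("quadratic", k = c(1, 1))
#' toy$mean_excess(zeta = 4) # 0.25
#' @export
make_toy_system <- function(kind = c("quadratic", "double_well", "two_state"),
                            k = 1, a = 1, b = 1, dG = 1) {
  kind <- match.arg(kind)
  switch(kind,
    quadratic = {
      k <- as.numeric(k)
      stopifnot(all(k > 0))
      structure(list(
        kind = kind, k = k, d = length(k),
        energy = function(r) sum(k * r^2) / 2,
        grad = function(r) k * r,
        stationary_var = function(zeta) 1 / (zeta * k),
        mean_excess = function(zeta) length(k) / (2 * zeta),
        G_min = 0), class = "toy_system")
    },
    double_well = {
      stopifnot(a > 0, b > 0)
      structure(list(
        kind = kind, a = a, b = b, d = 1L,
        energy = function(r) a * (sum(r^2) - b^2)^2,
        grad = function(r) 4 * a * r * (sum(r^2) - b^2),
        G_min = 0), class = "toy_system")
    },
    two_state = {
      structure(list(
        kind = kind, dG = dG, d = 1L,
        energy = function(s) ifelse(s > 0.5, dG, 0),
        boltzmann_ratio = function(zeta) exp(-zeta * dG),
        G_min = 0), class = "toy_system")
    })
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("Toy energy system '%s' (d = %d)\n", x$kind, x$d))
  invisible(x)
}

#' Fast samplers for the quadratic toy system
#'
#' Compiled Metropolis and Euler-Maruyama loops for the d-dimensional
#' quadratic energy, seeded through R's RNG.
#'
#' @param toy a quadratic [make_toy_system()].
#' @param zeta_hat inverse temperature.
#' @param n_steps iterations.
#' @param dt_hat Langevin time step.
#' @param thin keep every `thin`-th state.
#' @param seed RNG seed.
#' @param r0 initial state (defaults to the origin).
#' @param step0 initial Metropolis proposal sd.
#' @param burn Metropolis burn-in (with step adaptation).
#' @return `toy_langevin()`: thinned sample matrix. `toy_mcmc()`: list with
#'   `G`, `samples`, `acceptance`.
#' @export
toy_langevin <- function(toy, zeta_hat, dt_hat, n_steps, thin = 1, seed = 1,
                         r0 = NULL) {
  stopifnot(inherits(toy, "toy_system"), toy$kind == "quadratic")
  if (is.null(r0)) r0 <- numeric(toy$d)
  set.seed(seed)
  cpp_quad_langevin(toy$k, as.numeric(r0), zeta_hat, dt_hat,
                    as.integer(n_steps), as.integer(thin))$samples
}

#' @rdname toy_langevin
#' @export
toy_mcmc <- function(toy, zeta_hat, n_steps, thin = 1, seed = 1, r0 = NULL,
                     step0 = 1, burn = 2000) {
  stopifnot(inherits(toy, "toy_system"), toy$kind == "quadratic")
  if (is.null(r0)) r0 <- numeric(toy$d)
  set.seed(seed)
  bu <- cpp_quad_mcmc(toy$k, as.numeric(r0), zeta_hat, as.integer(burn),
                      step0, as.integer(burn), 1L, 0.3)
  r1 <- bu$samples[nrow(bu$samples), ]
  cpp_quad_mcmc(toy$k, r1, zeta_hat, as.integer(n_steps), bu$step, 0L,
                as.integer(thin), 0.3)
}
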