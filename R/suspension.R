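#' Suspension reference state
#'
#' A cell in suspension must self-equilibrate: the compressive elastic stress
#' of the cytoplasm balances the tension of a spatially uniform, isotropic
#' stress-fibre distribution, while the (much stiffer) nucleus remains
#' undeformed. For a spatially uniform equibiaxial cytoplasm stretch `lambda`
#' this is a one-variable root solve of the total in-plane stress
#' `Sigma(lambda) = sigma_A(lambda) + sigma_p(lambda) = 0`, where the
#' equibiaxial symmetry makes both stresses isotropic and lets the angular
#' integrals be evaluated in closed form.
#'
#' The free energy of the solved state defines the reference `G_S` that
#' normalises every other energy in the framework.
#'
#' @param params [cell_parameters()].
#' @param interval search bracket for the stretch.
#' @return An object of class `suspension_state`: list with `lambda`
#'   (equibiaxial suspension stretch), `radius_ratio` (deformed cell radius
#'   over R0, equal to `lambda` for the homogeneous compression), `GS`
#'   (kPa R0^3), `GS_hat` (`GS/|GS|`), `Nu_hat`, `eta_hat`, `residual_stress`
#'   (kPa), and `area_ratio` (`A_R / (pi R0^2)`).
#' @examples
#' s <- suspension_state(cell_parameters())
#' s$radius_ratio
#' @export
suspension_state <- function(params = cell_parameters(),
                             interval = c(0.3, 1.5)) {
  f <- function(l) uniform_stress(l, params)
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf(
      "no traction-free suspension stretch in (%g, %g); parameter set invalid",
      interval[1], interval[2]), call. = FALSE)
  lam <- uniroot(f, interval, tol = 1e-13)$root
  ch <- uniform_chemistry(lam, params)
  dc <- derived_constants(params)
  GS <- dc$rho0_kBT_kPa * dc$VC_hat * (params$mu_u + log(ch$Nu / params$pi_NL)) +
    dc$VC_hat * passive_energy_density(lam, lam, "cytoplasm", params)
  structure(list(lambda = lam, radius_ratio = lam, GS = GS,
                 GS_hat = sign(GS), Nu_hat = ch$Nu, eta_hat = ch$eta,
                 residual_stress = f(lam),
                 area_ratio = lam^2),
            class = "suspension_state")
}

# Chemistry of a spatially uniform equibiaxial state: every fibre direction
# sees the same stretch, so conservation reduces to Nu + pi*eta*nss = 1.
uniform_chemistry <- function(lam, params) {
  dc <- derived_constants(params)
  nss <- lam / (1 + params$eps_ss)
  em <- params$eta_max
  E <- nss * dc$dmu_hat
  a <- pi * nss * em
  if (E >= 0) {
    D <- a * exp(-E)
    # Nu + a*Nu/(D+Nu) = 1  =>  Nu^2 + (D + a - 1) Nu - D = 0
    Nu <- (-(D + a - 1) + sqrt((D + a - 1)^2 + 4 * D)) / 2
    eta <- Nu * em / (D + Nu)
  } else {
    X <- exp(E)
    # eta = Nu*em*X/(a + Nu*X); conservation solved on the rescaled branch
    Nu <- uniroot(function(Nu) Nu + pi * nss * Nu * em * X / (a + Nu * X) - 1,
                  c(0, 1), tol = 1e-15)$root
    eta <- Nu * em * X / (a + Nu * X)
  }
  list(Nu = Nu, eta = eta, nss = nss)
}

# Total in-plane stress of the uniform equibiaxial state (kPa, isotropic).
uniform_stress <- function(lam, params) {
  ch <- uniform_chemistry(lam, params)
  act <- pi / 2 * params$H0 * params$sigma_max * ch$eta * lam
  pas <- passive_principal_stresses(lam, lam, "cytoplasm", params)[1]
  act + pas
}

#' @export
print.suspension_state <- function(x, ...) {
  cat(sprintf("Suspension state: radius %.4f R0, G_S = %.4f kPa R0^3, Nu_hat = %.4f\n",
              x$radius_ratio, x$GS, x$Nu_hat))
  cat(sprintf("  residual stress %.2e kPa, eta_hat = %.4f\n",
              x$residual_stress, x$eta_hat))
  invisible(x)
}
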