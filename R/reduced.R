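#' Reduced elliptical-cell free energy
#'
#' The deterministic two-variable model in which the cell is a spatially
#' uniform ellipse with axes aligned to x1/x2: the homogeneous deformation
#' `F = diag(l1, l2)` fixes a single fibre-stretch profile `lambda(phi)`, a
#' single global conservation solve gives the unbound fraction, and the Ogden
#' energies of cytoplasm and nucleus (which co-deforms affinely; its stiff
#' shear exponent is what ultimately caps the ellipse aspect ratio) are
#' evaluated once. The nucleus energy is measured relative to the equibiaxial
#' suspension stretch so that `ellipse_energy(l, l)` at the suspension
#' stretch reproduces `G_S` exactly (the suspension solve keeps the nucleus
#' undeformed; the shift is a constant, invisible to gradients).
#'
#' @param l1,l2 principal-axis stretches (vectors of equal length recycle).
#' @param params [cell_parameters()].
#' @param GS normalising suspension energy; computed from
#'   [suspension_state()] when `NULL`.
#' @param n_phi angular quadrature bins.
#' @return normalised energy `G_hat = G/|G_S|` (same shape as `l1`), with the
#'   penalty-active region flagged by attribute `"penalty"` when any input has
#'   `l1*l2 < Jc`.
#' @examples
#' s <- suspension_state()
#' ellipse_energy(s$lambda, s$lambda) # = sign(G_S) = -1
#' @export
ellipse_energy <- function(l1, l2, params = cell_parameters(), GS = NULL,
                           n_phi = 36) {
  stopifnot(all(l1 > 0), all(l2 > 0))
  if (is.null(GS)) GS <- suspension_state(params)$GS
  G <- cpp_ellipse_energy(as.numeric(l1), as.numeric(l2),
                          ellipse_par(params, n_phi))
  out <- G / abs(GS)
  if (any(l1 * l2 < params$Jc)) attr(out, "penalty") <- TRUE
  out
}

ellipse_par <- function(params, n_phi, lambda_susp = NULL) {
  dc <- derived_constants(params)
  grid <- angular_grid(n_phi)
  if (is.null(lambda_susp)) lambda_susp <- suspension_state(params)$lambda
  # reference shift: the suspension solve keeps the nucleus undeformed, the
  # reduced model deforms it affinely; measuring the nucleus energy relative
  # to the equibiaxial suspension stretch keeps G(l_s, l_s) = G_S exactly
  # (a constant shift, invisible to gradients and minima)
  psiN_ref <- dc$VN_hat *
    passive_energy_density(lambda_susp, lambda_susp, "nucleus", params)
  list(eps_ss = params$eps_ss, eta_max = params$eta_max, dmu_hat = dc$dmu_hat,
       rho0_kBT = dc$rho0_kBT_kPa, chi_const = params$mu_u - log(params$pi_NL),
       VC_hat = dc$VC_hat, VN_hat = dc$VN_hat, psiN_ref = psiN_ref,
       mu_C = params$mu_C, m_C = params$m_C, kappa_C = params$kappa_C,
       mu_N = params$mu_N, m_N = params$m_N, kappa_N = params$kappa_N,
       kappa_bar = params$kappa_bar, Jc = params$Jc,
       s2 = grid$s2, sc2 = grid$sc2, c2 = grid$c2, w_phi = grid$w)
}

# Reference R implementation of the reduced energy (oracle for the compiled
# path): same chemistry as uniform_chemistry but with an anisotropic stretch.
ellipse_energy_r <- function(l1, l2, params = cell_parameters(), GS = NULL,
                             n_phi = 36) {
  susp <- suspension_state(params)
  if (is.null(GS)) GS <- susp$GS
  dc <- derived_constants(params)
  grid <- angular_grid(n_phi)
  lam <- sqrt(l1^2 * grid$s2 + l2^2 * grid$c2)
  nss <- lam / (1 + params$eps_ss)
  em <- params$eta_max
  D <- pi * nss * em * exp(-nss * dc$dmu_hat)
  coef <- grid$w * nss * em
  f <- function(Nu) Nu + sum(coef * Nu / (D + Nu)) - 1
  Nu <- uniroot(f, c(1e-300, 1), tol = 1e-16)$root
  lI <- max(l1, l2); lII <- min(l1, l2)
  G <- dc$rho0_kBT_kPa * dc$VC_hat * (params$mu_u + log(Nu / params$pi_NL)) +
    dc$VC_hat * passive_energy_density(lI, lII, "cytoplasm", params) +
    dc$VN_hat * (passive_energy_density(lI, lII, "nucleus", params) -
                 passive_energy_density(susp$lambda, susp$lambda, "nucleus",
                                        params))
  G / abs(GS)
}

#' Deterministic gradient flow of the reduced model
#'
#' Integrates `dl_i/dt_hat = -dG_hat/dl_i` by forward Euler from a starting
#' state until the gradient norm falls below `tol`. Starting exactly on the
#' symmetric diagonal keeps the flow symmetric forever, so the suspension
#' start is given an infinitesimal asymmetric perturbation by default.
#'
#' @param params [cell_parameters()].
#' @param start length-2 initial stretches; default: suspension state with a
#'   relative `1e-6` perturbation of the first axis.
#' @param dt_hat Euler step.
#' @param tol gradient-norm stopping tolerance.
#' @param max_steps iteration cap; non-convergence returns the partial path
#'   flagged with `converged = FALSE`.
#' @param thin record every `thin`-th step.
#' @param n_phi angular quadrature bins.
#' @return An object of class `ellipse_flow`: data.frame with `t_hat`, `l1`,
#'   `l2`, `A_over_AR`, `AS`, `G_hat`; attributes `converged`, `suspension`.
#' @export
gradient_flow <- function(params = cell_parameters(), start = NULL,
                          dt_hat = 0.01, tol = 1e-6, max_steps = 2e5,
                          thin = 10, n_phi = 36) {
  susp <- suspension_state(params)
  if (is.null(start)) start <- c(susp$lambda * (1 + 1e-6), susp$lambda)
  par <- ellipse_par(params, n_phi)
  gabs <- abs(susp$GS)
  en <- function(l) cpp_ellipse_energy(l[1], l[2], par) / gabs
  gr <- function(l) {
    h <- 1e-7
    c(cpp_ellipse_energy(l[1] + h, l[2], par) -
        cpp_ellipse_energy(l[1] - h, l[2], par),
      cpp_ellipse_energy(l[1], l[2] + h, par) -
        cpp_ellipse_energy(l[1], l[2] - h, par)) / (2 * h * gabs)
  }
  l <- as.numeric(start)
  keep <- list(c(0, l, en(l)))
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    g <- gr(l)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    l <- l - g * dt_hat
    if (any(l <= 0)) stop("gradient flow left the admissible stretch domain")
    if (it %% thin == 0) keep[[length(keep) + 1]] <- c(it * dt_hat, l, en(l))
  }
  m <- do.call(rbind, keep)
  out <- data.frame(t_hat = m[, 1], l1 = m[, 2], l2 = m[, 3],
                    A_over_AR = m[, 2] * m[, 3] / susp$lambda^2,
                    AS = pmax(m[, 2], m[, 3]) / pmin(m[, 2], m[, 3]),
                    G_hat = m[, 4])
  structure(out, class = c("ellipse_flow", "data.frame"),
            converged = converged, suspension = susp$lambda)
}

#' @export
print.ellipse_flow <- function(x, ...) {
  cat(sprintf("Reduced-model gradient flow: %d frames to t_hat = %.4g (%s)\n",
              nrow(x), max(x$t_hat),
              if (isTRUE(attr(x, "converged"))) "converged"
              else "NOT converged"))
  cat(sprintf("  final (l1, l2) = (%.4f, %.4f), A/A_R = %.3f, AS = %.3f\n",
              x$l1[nrow(x)], x$l2[nrow(x)], x$A_over_AR[nrow(x)],
              x$AS[nrow(x)]))
  invisible(x)
}

#' Free-energy landscape of the reduced model
#'
#' Evaluates `G_hat` over a rectangular grid of principal stretches together
#' with the isoline families of normalised area
#' `A/A_R = l1*l2/lambda_susp^2` and aspect ratio `AS = l1/l2`.
#'
#' @param params [cell_parameters()].
#' @param l1,l2 grid coordinate vectors.
#' @param n_phi angular quadrature bins.
#' @return list of class `ellipse_landscape`: `l1`, `l2`, `G_hat` (matrix
#'   indexed `[l1, l2]`), `A_over_AR`, `AS` (matching matrices) and
#'   `lambda_susp`.
#' @export
landscape_map <- function(params = cell_parameters(),
                          l1 = seq(0.5, 2, length.out = 61), l2 = l1,
                          n_phi = 36) {
  susp <- suspension_state(params)
  par <- ellipse_par(params, n_phi)
  gg <- expand.grid(l1 = l1, l2 = l2)
  G <- cpp_ellipse_energy(gg$l1, gg$l2, par) / abs(susp$GS)
  structure(list(l1 = l1, l2 = l2,
                 G_hat = matrix(G, length(l1), length(l2)),
                 A_over_AR = outer(l1, l2) / susp$lambda^2,
                 AS = outer(l1, l2, "/"),
                 lambda_susp = susp$lambda),
            class = "ellipse_landscape")
}

#' @export
print.ellipse_landscape <- function(x, ...) {
  cat(sprintf("Reduced-model landscape on %d x %d grid, G_hat in [%.3f, %.3f]\n",
              length(x$l1), length(x$l2), min(x$G_hat), max(x$G_hat)))
  invisible(x)
}
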