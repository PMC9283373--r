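#' Angular quadrature grid for stress-fibre orientations
#'
#' Uniform bins on `[-pi/2, pi/2)` with midpoint weights. Stress-fibre angles
#' are measured from the x2 (stripe) axis; the direction vector of angle `phi`
#' is `m = (-sin(phi), cos(phi))`.
#'
#' @param n_phi number of bins (default 36, i.e. 5 degree resolution).
#' @return list with `phi` (bin centres), `w` (weights summing to pi), and the
#'   precomputed quadratic-form coefficients `s2`, `sc2`, `c2` such that
#'   `lambda(phi)^2 = C11*s2 + C12*sc2 + C22*c2`.
#' @export
angular_grid <- function(n_phi = 36) {
  phi <- -pi / 2 + (seq_len(n_phi) - 0.5) * pi / n_phi
  list(phi = phi, w = rep(pi / n_phi, n_phi),
       s2 = sin(phi)^2, sc2 = -2 * sin(phi) * cos(phi), c2 = cos(phi)^2)
}

#' Steady-state functional units per stress-fibre
#'
#' The number of functional units in series in a fibre at stretch `lambda`,
#' normalised by the reference count: `lambda / (1 + eps_ss)`.
#'
#' @param lambda fibre stretch(es), positive.
#' @param params [cell_parameters()].
#' @return normalised unit count, same shape as `lambda`.
#' @export
steady_state_units <- function(lambda, params = cell_parameters()) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("invalid kinematics: fibre stretch must be positive", call. = FALSE)
  lambda / (1 + params$eps_ss)
}

#' Enthalpy of bound stress-fibre packets
#'
#' `mu_b = mu_b0 - sigma_max * Omega * (1 + eps_ss)`, returned per packet in
#' units of kBT.
#'
#' @param params [cell_parameters()].
#' @export
bound_enthalpy <- function(params = cell_parameters()) {
  derived_constants(params)$mu_b
}

#' Equilibrium angular stress-fibre concentration
#'
#' The bound concentration at chemical equilibrium between bound and unbound
#' stress-fibre proteins. Evaluated in whichever exponential branch cannot
#' overflow: with `E = nss_hat * (mu_u - mu_b)/kBT`,
#' `eta = Nu * eta_max / (pi * nss * eta_max * exp(-E) + Nu)` for `E >= 0` and
#' the algebraically identical `Nu * eta_max * exp(E) / (pi * nss * eta_max +
#' Nu * exp(E))` otherwise.
#'
#' @param Nu_hat normalised unbound concentration in `[0, 1]`.
#' @param lambda fibre stretch(es).
#' @param params [cell_parameters()].
#' @return eta_hat, strictly below `eta_max`.
#' @export
angular_concentration <- function(Nu_hat, lambda, params = cell_parameters()) {
  stopifnot(Nu_hat >= 0, Nu_hat <= 1)
  dc <- derived_constants(params)
  nss <- steady_state_units(lambda, params)
  em <- params$eta_max
  k <- max(length(Nu_hat), length(nss))
  Nu <- rep_len(Nu_hat, k)
  nss <- rep_len(nss, k)
  E <- nss * dc$dmu_hat
  out <- numeric(k)
  pos <- E >= 0
  out[pos] <- Nu[pos] * em / (pi * nss[pos] * em * exp(-E[pos]) + Nu[pos])
  out[!pos] <- Nu[!pos] * em * exp(E[!pos]) /
    (pi * nss[!pos] * em + Nu[!pos] * exp(E[!pos]))
  out
}

#' Solve the unbound concentration from protein conservation
#'
#' Finds the scalar `Nu_hat` such that the total stress-fibre protein content
#' is conserved over the cytoplasm:
#' `Nu_hat + (1/V_C) * int int eta * nss dphi dV = 1`.
#' Solved by a safeguarded Newton iteration on the monotone residual; the
#' returned state satisfies the conservation law to better than 1e-12.
#'
#' @param config a [deform()] configuration.
#' @param mesh the [build_reference_mesh()] mesh the configuration came from.
#' @param params [cell_parameters()].
#' @param grid an [angular_grid()].
#' @return An object of class `cytoskeletal_state`: list with `Nu_hat`,
#'   `eta_hat` and `nss_hat` (cytoplasm-element x angular-bin matrices),
#'   `chi_u` (unbound chemical potential, kBT units), `residual`, `grid`, and
#'   `cyto` (row indices of the cytoplasm elements).
#' @export
solve_unbound <- function(config, mesh, params = cell_parameters(),
                          grid = angular_grid()) {
  if (!config$admissible)
    stop("invalid kinematics: configuration has folded elements", call. = FALSE)
  cyto <- which(mesh$region == "cytoplasm")
  C <- config$C[cyto, , drop = FALSE]
  lam2 <- outer(C[, 1], grid$s2) + outer(C[, 2], grid$sc2) +
    outer(C[, 3], grid$c2)
  lam <- sqrt(pmax(lam2, .Machine$double.eps))
  nss <- lam / (1 + params$eps_ss)
  dc <- derived_constants(params)
  em <- params$eta_max
  E <- nss * dc$dmu_hat
  # eta = Nu*em/(D + Nu) with D = pi*nss*em*exp(-E); D can underflow to 0
  # harmlessly (saturated binding) but never overflow for E >= 0. For E < 0
  # rescale so the representation stays bounded.
  D <- pi * nss * em * exp(-E)
  w <- mesh$area[cyto] / sum(mesh$area[cyto])       # volume weights (b0 cancels)
  wq <- outer(w, grid$w)                             # combined quadrature weight
  coef <- wq * nss * em                              # eta*nss summand = coef*Nu/(D+Nu)
  resid <- function(Nu) Nu + sum(coef * Nu / (D + Nu)) - 1
  # safeguarded Newton in log(Nu): conditioning survives Nu near underflow
  lo <- -710; hi <- 0; u <- -1
  for (it in 1:200) {
    Nu <- exp(u)
    term <- coef * Nu / (D + Nu)
    f <- Nu + sum(term) - 1
    if (abs(f) < 1e-13) break
    fp <- Nu + sum(term * D / (D + Nu))
    if (f > 0) hi <- u else lo <- u
    u2 <- u - f / fp
    u <- if (u2 <= lo || u2 >= hi) (lo + hi) / 2 else u2
  }
  Nu <- exp(u)
  if (abs(resid(Nu)) > 1e-10)
    stop(sprintf(
      "conservation solve failed: residual %.3e (bracket residuals %.3e, %.3e)",
      resid(Nu), resid(0), resid(1)), call. = FALSE)
  eta <- Nu * em / (D + Nu)
  structure(list(Nu_hat = Nu, eta_hat = eta, nss_hat = nss,
                 chi_u = unbound_potential(Nu, params),
                 residual = resid(Nu), grid = grid, cyto = cyto),
            class = "cytoskeletal_state")
}

#' @export
print.cytoskeletal_state <- function(x, ...) {
  cat(sprintf("Cytoskeletal state: Nu_hat = %.5f, max eta_hat = %.4f, residual %.1e\n",
              x$Nu_hat, max(x$eta_hat), x$residual))
  invisible(x)
}

#' Chemical potential of unbound stress-fibre proteins
#'
#' `chi_u = mu_u + kBT ln(Nu_hat / (pi N_L))`, per packet in kBT units.
#'
#' @param Nu_hat unbound concentration, strictly positive.
#' @param params [cell_parameters()].
#' @export
unbound_potential <- function(Nu_hat, params = cell_parameters()) {
  if (any(Nu_hat <= 0))
    stop("chi_u diverges: Nu_hat must be strictly positive", call. = FALSE)
  params$mu_u + log(Nu_hat / params$pi_NL)
}

#' Chemical potential of bound stress-fibre proteins
#'
#' Per packet, in kBT units, evaluated fibre-by-fibre from the solved state;
#' equals [unbound_potential()] everywhere at chemical equilibrium.
#'
#' @param state a [solve_unbound()] state.
#' @param params [cell_parameters()].
#' @return matrix matching `state$eta_hat`.
#' @export
bound_potential <- function(state, params = cell_parameters()) {
  dc <- derived_constants(params)
  em <- params$eta_max
  with(state, dc$mu_b +
    log(pi * eta_hat * nss_hat / (Nu_hat * (1 - eta_hat / em))) / nss_hat +
    log(Nu_hat / params$pi_NL))
}

#' Passive strain-energy density
#'
#' 2D Ogden-type deviatoric energy plus an in-plane bulk quadratic and the
#' compression penalty `kappa_bar * H(Jc - J) * (J - Jc)^2`, where
#' `J = lI * lII`.
#'
#' @param lI,lII principal stretches (vectors allowed).
#' @param region `"cytoplasm"` or `"nucleus"`.
#' @param params [cell_parameters()].
#' @return energy density (kPa), same shape as `lI`.
#' @export
passive_energy_density <- function(lI, lII, region = c("cytoplasm", "nucleus"),
                                   params = cell_parameters()) {
  region <- match.arg(region)
  stopifnot(all(lI > 0), all(lII > 0))
  mu <- if (region == "cytoplasm") params$mu_C else params$mu_N
  m <- if (region == "cytoplasm") params$m_C else params$m_N
  kap <- if (region == "cytoplasm") params$kappa_C else params$kappa_N
  r <- (lI / lII)^(m / 2)
  J <- lI * lII
  2 * mu / m^2 * (r + 1 / r - 2) + kap / 2 * (J - 1)^2 + penalty_density(J, params)
}

penalty_density <- function(J, params) {
  params$kappa_bar * ifelse(J < params$Jc, (J - params$Jc)^2, 0)
}

#' Passive Cauchy stress
#'
#' Principal passive Cauchy stresses `sigma_k = lambda_k dPsi/dlambda_k`
#' rotated into the x1-x2 frame by the supplied principal directions.
#'
#' @param lI,lII principal stretches (scalars).
#' @param principal_dirs unit vector of the major principal direction (the
#'   minor direction is its perpendicular).
#' @param region `"cytoplasm"` or `"nucleus"`.
#' @param params [cell_parameters()].
#' @return 2 x 2 symmetric Cauchy stress (kPa).
#' @export
passive_stress <- function(lI, lII, principal_dirs = c(1, 0),
                           region = c("cytoplasm", "nucleus"),
                           params = cell_parameters()) {
  region <- match.arg(region)
  pr <- passive_principal_stresses(lI, lII, region, params)
  v1 <- principal_dirs / sqrt(sum(principal_dirs^2))
  v2 <- c(-v1[2], v1[1])
  pr[1] * tcrossprod(v1) + pr[2] * tcrossprod(v2)
}

passive_principal_stresses <- function(lI, lII, region, params) {
  mu <- if (region == "cytoplasm") params$mu_C else params$mu_N
  m <- if (region == "cytoplasm") params$m_C else params$m_N
  kap <- if (region == "cytoplasm") params$kappa_C else params$kappa_N
  r <- (lI / lII)^(m / 2)
  J <- lI * lII
  vol <- kap * (J - 1) * J +
    2 * params$kappa_bar * ifelse(J < params$Jc, (J - params$Jc) * J, 0)
  c(mu / m * (r - 1 / r) + vol, mu / m * (1 / r - r) + vol)
}

#' Active stress of the stress-fibre distribution
#'
#' Angular quadrature of the fibre tension over orientations: per element,
#' `sigma_A = H0 * sigma_max * sum_phi w * eta * lambda(phi) * n n^T`, where
#' `n` is the push-forward `F m / |F m|` of the reference fibre direction.
#'
#' @param config a [deform()] configuration.
#' @param state the matching [solve_unbound()] state.
#' @param params [cell_parameters()].
#' @return E x 3 matrix of (S11, S12, S22) per element (kPa); zero rows for
#'   nucleus elements.
#' @export
active_stress <- function(config, state, params = cell_parameters()) {
  grid <- state$grid
  nE <- length(config$lI)
  out <- matrix(0, nE, 3)
  Fm <- config$F[state$cyto, , drop = FALSE]
  ms <- -sin(grid$phi); mc <- cos(grid$phi)
  # push-forward components for all (element, angle)
  p1 <- outer(Fm[, 1], ms) + outer(Fm[, 2], mc)   # (F m)_1
  p2 <- outer(Fm[, 3], ms) + outer(Fm[, 4], mc)   # (F m)_2
  lam <- sqrt(pmax(p1^2 + p2^2, .Machine$double.eps))
  pref <- params$H0 * params$sigma_max
  wfac <- state$eta_hat / lam                     # eta * lambda * (1/lam^2)
  W <- matrix(grid$w, nrow(wfac), ncol(wfac), byrow = TRUE)
  out[state$cyto, 1] <- pref * rowSums(W * wfac * p1 * p1)
  out[state$cyto, 2] <- pref * rowSums(W * wfac * p1 * p2)
  out[state$cyto, 3] <- pref * rowSums(W * wfac * p2 * p2)
  out
}

#' Total Gibbs free energy of a morphological microstate
#'
#' Assembles the cell free energy
#' `G = rho0 V_C chi_u + int Psi_C dV + int Psi_N dV` (the substrate is rigid
#' and the adhesion term is configuration-independent, so both are dropped)
#' and reports its decomposition. Volume integrals use reference-configuration
#' quadrature; in-plane incompressibility of the model makes reference and
#' current volumes identical.
#'
#' @param net a [control_net()] (or an already-deformed configuration via
#'   `config`).
#' @param mesh a [build_reference_mesh()] mesh.
#' @param params [cell_parameters()].
#' @param GS suspension free energy used to normalise (kPa R0^3); when `NULL`,
#'   `G_hat` is `NA`.
#' @param grid an [angular_grid()].
#' @param config optional precomputed [deform()] configuration.
#' @param state optional precomputed [solve_unbound()] state.
#' @return An `energy_breakdown`: list with `G`, `G_hat`, `cyto_term`,
#'   `passive_cyto`, `passive_nucleus`, `penalty_term`, `Nu_hat`, and the
#'   `state` used.
#' @export
total_free_energy <- function(net, mesh, params = cell_parameters(),
                              GS = NULL, grid = angular_grid(),
                              config = NULL, state = NULL) {
  if (is.null(config)) config <- deform(mesh, net, params)
  if (!config$admissible)
    stop("inadmissible microstate: folded element (det F <= 0)", call. = FALSE)
  if (is.null(state)) state <- solve_unbound(config, mesh, params, grid)
  dc <- derived_constants(params)
  b0 <- params$b0_over_R0
  cyto <- mesh$region == "cytoplasm"
  VC <- sum(mesh$area[cyto]) * b0
  cyto_term <- dc$rho0_kBT_kPa * VC * state$chi_u
  PsiC <- passive_energy_density(config$lI[cyto], config$lII[cyto],
                                 "cytoplasm", params)
  PsiN <- passive_energy_density(config$lI[!cyto], config$lII[!cyto],
                                 "nucleus", params)
  passive_cyto <- sum(mesh$area[cyto] * PsiC) * b0
  passive_nucleus <- sum(mesh$area[!cyto] * PsiN) * b0
  pen <- penalty_density(config$lI * config$lII, params)
  penalty_term <- sum(mesh$area * pen) * b0
  G <- cyto_term + passive_cyto + passive_nucleus
  structure(list(G = G,
                 G_hat = if (is.null(GS)) NA_real_ else G / abs(GS),
                 cyto_term = cyto_term, passive_cyto = passive_cyto,
                 passive_nucleus = passive_nucleus,
                 penalty_term = penalty_term,
                 Nu_hat = state$Nu_hat, state = state),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("G = %.5f kPa R0^3 (cyto %.5f, passive cyto %.5f, nucleus %.5f; penalty %.2e)\n",
              x$G, x$cyto_term, x$passive_cyto, x$passive_nucleus,
              x$penalty_term))
  if (is.finite(x$G_hat)) cat(sprintf("G_hat = %.5f\n", x$G_hat))
  invisible(x)
}

#' Total Cauchy stress field
#'
#' Additive decomposition `Sigma = sigma_A + sigma_p` per element, with the
#' passive principal stresses rotated to the x1-x2 frame along the deformed
#' (left-stretch) principal directions.
#'
#' @param config a [deform()] configuration.
#' @param state the matching [solve_unbound()] state.
#' @param mesh the mesh.
#' @param params [cell_parameters()].
#' @return E x 3 matrix (S11, S12, S22) in kPa.
#' @export
total_stress <- function(config, state, mesh, params = cell_parameters()) {
  act <- active_stress(config, state, params)
  Fm <- config$F
  B11 <- Fm[, 1]^2 + Fm[, 2]^2
  B12 <- Fm[, 1] * Fm[, 3] + Fm[, 2] * Fm[, 4]
  B22 <- Fm[, 3]^2 + Fm[, 4]^2
  # principal directions of the left stretch tensor (current frame)
  v1 <- ifelse(abs(B12) > 1e-14, B12, 1)
  v2 <- ifelse(abs(B12) > 1e-14, config$lI^2 - B11, 0)
  nv <- sqrt(v1^2 + v2^2)
  v1 <- v1 / nv; v2 <- v2 / nv
  pas <- vapply(seq_len(nrow(Fm)), function(e) {
    reg <- if (mesh$region[e] == "cytoplasm") "cytoplasm" else "nucleus"
    pr <- passive_principal_stresses(config$lI[e], config$lII[e], reg, params)
    c(pr[1] * v1[e]^2 + pr[2] * v2[e]^2,
      (pr[1] - pr[2]) * v1[e] * v2[e],
      pr[1] * v2[e]^2 + pr[2] * v1[e]^2)
  }, numeric(3))
  act + t(pas)
}

#' Nodal traction field
#'
#' The tractions the substrate exerts on the cell, `T = -b div(Sigma)`,
#' assembled as nodal equivalent forces on the deformed mesh. In-plane
#' incompressibility makes `A_current * b_current = A_ref * b0` per element,
#' so the assembly reduces to reference area times resting thickness times the
#' deformed shape-function gradients. The forces sum to zero (global
#' equilibrium) and vanish at interior nodes for a spatially uniform stress.
#'
#' @param mesh the mesh.
#' @param config a [deform()] configuration.
#' @param Sigma E x 3 total stress per element (see [total_stress()]).
#' @param params [cell_parameters()] (resting thickness).
#' @return N x 2 matrix of nodal forces (kPa R0^2, i.e. force per unit R0^2
#'   normalised scale).
#' @export
traction_field <- function(mesh, config, Sigma, params = cell_parameters()) {
  tr <- mesh$triangles
  x <- config$x
  out <- matrix(0, nrow(x), 2)
  fac <- mesh$area * params$b0_over_R0
  # deformed-geometry CST shape-function gradients
  x1 <- x[tr[, 1], ]; x2 <- x[tr[, 2], ]; x3 <- x[tr[, 3], ]
  det <- (x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
         (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2])
  gx <- cbind(x2[, 2] - x3[, 2], x3[, 2] - x1[, 2], x1[, 2] - x2[, 2]) / det
  gy <- cbind(x3[, 1] - x2[, 1], x1[, 1] - x3[, 1], x2[, 1] - x1[, 1]) / det
  for (a in 1:3) {
    fx <- fac * (Sigma[, 1] * gx[, a] + Sigma[, 2] * gy[, a])
    fy <- fac * (Sigma[, 2] * gx[, a] + Sigma[, 3] * gy[, a])
    idx <- tr[, a]
    acc <- rowsum(cbind(fx, fy), idx)
    rows <- as.integer(rownames(acc))
    out[rows, ] <- out[rows, ] + acc
  }
  out
}

#' Pseudo-staining fields of a configuration
#'
#' The bound stress-fibre density `Nb_hat` (angular integral of
#' `eta_hat * nss_hat`), the dominant fibre direction `phi_max` per element
#' (argmax over angular bins, ties broken toward the smallest `|phi|`), and
#' the nodal traction magnitudes used as a focal-adhesion proxy.
#'
#' @param mesh the mesh.
#' @param config a [deform()] configuration.
#' @param state the matching [solve_unbound()] state.
#' @param tractions optional N x 2 traction field (see [traction_field()]).
#' @return list with `elements` (data.frame: element, x1, x2 deformed
#'   centroid, region, Nb_hat, phi_max, traction_mag) and `node_traction`
#'   (per-node magnitudes, or NULL).
#' @export
staining_fields <- function(mesh, config, state, tractions = NULL) {
  grid <- state$grid
  nE <- nrow(mesh$triangles)
  Nb <- numeric(nE); phm <- rep(NA_real_, nE)
  dens <- state$eta_hat * state$nss_hat
  Nb[state$cyto] <- as.numeric(dens %*% grid$w)
  ord <- order(abs(grid$phi), grid$phi)  # tie-break: smallest |phi| first
  phm[state$cyto] <- apply(dens[, ord, drop = FALSE], 1, function(v) {
    near <- v >= max(v) - 1e-10 * max(abs(v), 1e-300)  # ties up to round-off
    grid$phi[ord][which(near)[1]]
  })
  tr <- mesh$triangles
  cx <- (config$x[tr[, 1], 1] + config$x[tr[, 2], 1] + config$x[tr[, 3], 1]) / 3
  cy <- (config$x[tr[, 1], 2] + config$x[tr[, 2], 2] + config$x[tr[, 3], 2]) / 3
  tmag_node <- if (is.null(tractions)) NULL else sqrt(rowSums(tractions^2))
  tmag_el <- if (is.null(tmag_node)) NA_real_ else
    (tmag_node[tr[, 1]] + tmag_node[tr[, 2]] + tmag_node[tr[, 3]]) / 3
  list(elements = data.frame(element = seq_len(nE), x1 = cx, x2 = cy,
                             region = mesh$region, Nb_hat = Nb,
                             phi_max = phm, traction_mag = tmag_el),
       node_traction = tmag_node)
}
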