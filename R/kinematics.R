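#' Deform the reference mesh by a control net
#'
#' Evaluates the spline displacement at every mesh node and computes the
#' per-element kinematics of the constant strain triangles: deformation
#' gradient, principal stretches and directions, and the current thickness
#' `b = b0/(lI*lII)` implied by incompressibility (the out-of-plane stretch is
#' `1/(lI*lII)`).
#'
#' @param mesh a [build_reference_mesh()] mesh.
#' @param net a [control_net()].
#' @param params a [cell_parameters()] object (for the resting thickness).
#' @return An object of class `deformed_configuration`: list with `x` (deformed
#'   nodes), `F` (E x 4 matrix, columns F11, F12, F21, F22), `lI`, `lII`
#'   (principal stretches, `lI >= lII`), `principal_dirs` (E x 2 unit vector of
#'   the major principal direction), `C` (E x 3 right Cauchy-Green components
#'   C11, C12, C22), `thickness`, `boundary` (ordered deformed rim polygon),
#'   `centroid`, and `admissible` (`FALSE` when any element folds over,
#'   `det F <= 0`).
#' @examples
#' mesh <- build_reference_mesh(cell_parameters(), 0.25)
#' cfg <- deform(mesh, affine_net(diag(c(0.2, -0.1))))
#' range(cfg$lI) # 1.2 on every element
#' @export
deform <- function(mesh, net, params = cell_parameters()) {
  stopifnot(inherits(mesh, "reference_mesh"), inherits(net, "control_net"))
  u <- patch_basis(mesh$nodes) %*% net$d
  x <- mesh$nodes + u
  tr <- mesh$triangles
  ds1 <- x[tr[, 2], ] - x[tr[, 1], ]
  ds2 <- x[tr[, 3], ] - x[tr[, 1], ]
  Di <- mesh$Dm_inv                       # columns: m11 m12 m21 m22
  F11 <- ds1[, 1] * Di[, 1] + ds2[, 1] * Di[, 3]
  F12 <- ds1[, 1] * Di[, 2] + ds2[, 1] * Di[, 4]
  F21 <- ds1[, 2] * Di[, 1] + ds2[, 2] * Di[, 3]
  F22 <- ds1[, 2] * Di[, 2] + ds2[, 2] * Di[, 4]
  detF <- F11 * F22 - F12 * F21
  C11 <- F11^2 + F21^2
  C12 <- F11 * F12 + F21 * F22
  C22 <- F12^2 + F22^2
  trC <- C11 + C22
  disc <- sqrt(pmax(0, (C11 - C22)^2 + 4 * C12^2))
  eI <- (trC + disc) / 2
  eII <- pmax((trC - disc) / 2, 0)
  lI <- sqrt(eI); lII <- sqrt(eII)
  # major principal direction of C (reference frame)
  v1 <- ifelse(abs(C12) > 1e-14, C12, eI - C22)
  v2 <- ifelse(abs(C12) > 1e-14, eI - C11, C12)
  flat <- abs(C12) <= 1e-14 & abs(C11 - C22) <= 1e-14
  v1[flat] <- 1; v2[flat] <- 0
  nv <- sqrt(v1^2 + v2^2)
  boundary <- x[mesh$rim, , drop = FALSE]
  structure(list(
    x = x, F = cbind(F11, F12, F21, F22),
    lI = lI, lII = lII,
    principal_dirs = cbind(v1 / nv, v2 / nv),
    C = cbind(C11, C12, C22),
    thickness = params$b0_over_R0 / pmax(detF, .Machine$double.eps),
    boundary = boundary,
    centroid = polygon_centroid(boundary),
    admissible = all(detF > 0)),
    class = "deformed_configuration")
}

#' @export
print.deformed_configuration <- function(x, ...) {
  cat(sprintf("Deformed configuration: %d elements, stretches [%.3f, %.3f], %s\n",
              length(x$lI), min(x$lII), max(x$lI),
              if (x$admissible) "admissible" else "FOLDED (det F <= 0)"))
  invisible(x)
}

#' Substrate stripe pattern
#'
#' @param W_hat normalised stripe width `W / (2 R0)`; `Inf` for an unpatterned
#'   (fully adhesive) substrate. The stripe axis is the x2 direction, so
#'   adhesion requires `|x1| <= W_hat * R0`.
#' @return An object of class `stripe_pattern`.
#' @export
stripe_pattern <- function(W_hat = Inf) {
  stopifnot(is.numeric(W_hat), length(W_hat) == 1, W_hat > 0)
  structure(list(W_hat = W_hat, axis = "x2"), class = "stripe_pattern")
}

#' @export
print.stripe_pattern <- function(x, ...) {
  if (is.finite(x$W_hat))
    cat(sprintf("Adhesive stripe along x2, width W = %g * 2R0\n", x$W_hat))
  else cat("Unpatterned (fully adhesive) substrate\n")
  invisible(x)
}

#' Stripe admissibility and barrier energy
#'
#' A configuration is admissible on a stripe when every deformed node lies
#' within the adhesive band `|x1| <= W_hat * R0`. For the Langevin integrator,
#' which needs a differentiable forcing rather than hard rejection, a smooth
#' quartic barrier energy `kappa_w * sum(max(0, |x1| - W_hat)^4)` over the
#' nodes is also returned (dimensionless, in units of `|G_S|`).
#'
#' @param config a [deform()] configuration.
#' @param pattern a [stripe_pattern()].
#' @param kappa_w barrier stiffness; the default keeps the equilibrium
#'   protrusion depth well below half an element edge for order-one driving
#'   forces.
#' @return list with `admissible` (logical) and `barrier` (numeric energy).
#' @export
stripe_admissible <- function(config, pattern, kappa_w = 250) {
  if (!is.finite(pattern$W_hat))
    return(list(admissible = TRUE, barrier = 0))
  over <- pmax(0, abs(config$x[, 1]) - pattern$W_hat)
  list(admissible = !any(over > 0), barrier = kappa_w * sum(over^4))
}
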