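#' Assemble a full-cell energy model
#'
#' Precomputes everything the fast core needs to evaluate the normalised free
#' energy of a microstate: mesh arrays, the spline basis at the mesh nodes,
#' the angular quadrature, the chemistry and elasticity constants, and the
#' suspension normalisation `|G_S|` (evaluated on this mesh so that the
#' suspension configuration has `G_hat` exactly equal to `sign(G_S)`).
#'
#' @param params [cell_parameters()].
#' @param mesh a [build_reference_mesh()] mesh (built at the default edge when
#'   omitted).
#' @param pattern a [stripe_pattern()].
#' @param n_phi angular bins for the stress-fibre quadrature.
#' @param kappa_w stripe barrier stiffness for the Langevin integrator (the
#'   Monte Carlo sampler uses hard rejection instead).
#' @return An object of class `hle_model`.
#' @examples
#' mod <- hle_model(cell_parameters(), build_reference_mesh(target_edge = 0.25))
#' microstate_energy(mod, suspension_net(mod$lambda_susp))$G_hat  # -1
#' @export
hle_model <- function(params = cell_parameters(),
                      mesh = build_reference_mesh(params),
                      pattern = stripe_pattern(Inf),
                      n_phi = 36, kappa_w = 250) {
  dc <- derived_constants(params)
  grid <- angular_grid(n_phi)
  cpp <- list(
    nodes = unname(mesh$nodes), basis = patch_basis(mesh$nodes),
    tris0 = mesh$triangles - 1L, Dm_inv = unname(mesh$Dm_inv),
    area = unname(mesh$area),
    is_cyto = as.integer(mesh$region == "cytoplasm"),
    rim0 = as.integer(mesh$rim - 1L),
    s2 = grid$s2, sc2 = grid$sc2, c2 = grid$c2, w_phi = grid$w,
    eps_ss = params$eps_ss, eta_max = params$eta_max, dmu_hat = dc$dmu_hat,
    rho0_kBT = dc$rho0_kBT_kPa, b0 = params$b0_over_R0,
    chi_const = params$mu_u - log(params$pi_NL),
    mu_C = params$mu_C, m_C = params$m_C, kappa_C = params$kappa_C,
    mu_N = params$mu_N, m_N = params$m_N, kappa_N = params$kappa_N,
    kappa_bar = params$kappa_bar, Jc = params$Jc,
    GS_abs = 1, W_hat = pattern$W_hat, kappa_w = kappa_w)
  susp <- suspension_state(params)
  raw <- cpp_energy(cpp, as.numeric(suspension_net(susp$lambda)$d))
  GS <- raw$cyto_term + raw$passive_cyto + raw$passive_nucleus
  cpp$GS_abs <- abs(GS)
  structure(list(cpp = cpp, params = params, mesh = mesh, pattern = pattern,
                 grid = grid, GS = GS, GS_hat = sign(GS),
                 lambda_susp = susp$lambda, kappa_w = kappa_w),
            class = "hle_model")
}

#' @export
print.hle_model <- function(x, ...) {
  cat(sprintf("HLE cell model: %d elements, %d angular bins, G_S = %.4f kPa R0^3\n",
              nrow(x$mesh$triangles), length(x$grid$phi), x$GS))
  print(x$pattern)
  invisible(x)
}

#' Normalised microstate energy under a model
#'
#' @param model an [hle_model()].
#' @param net a [control_net()] (or bare 32-vector of control displacements).
#' @return list with `G_hat` (includes the stripe barrier, if any),
#'   `admissible`, `Nu_hat` and the energy components in kPa R0^3.
#' @export
microstate_energy <- function(model, net) {
  d <- if (inherits(net, "control_net")) as.numeric(net$d) else as.numeric(net)
  cpp_energy(model$cpp, d)
}

#' Gradient of the normalised free energy
#'
#' Numerical differentiation of `G_hat` with respect to the 32 control-point
#' displacement degrees of freedom (or of an arbitrary scalar function).
#' `"richardson"` uses adaptive central differences with Richardson
#' extrapolation; `"central"` and `"forward"` are plain fixed-step schemes
#' evaluated in the fast core (with one-sided fallback when a perturbation
#' folds the mesh).
#'
#' @param object an [hle_model()] or a scalar-valued function.
#' @param x the evaluation point: a [control_net()]/32-vector for a model, or
#'   a numeric vector for a function.
#' @param scheme differentiation scheme.
#' @param h base step for the fixed-step schemes.
#' @return gradient vector.
#' @export
energy_gradient <- function(object, x, scheme = c("central", "forward",
                                                  "richardson"), h = 1e-6) {
  scheme <- match.arg(scheme)
  if (inherits(object, "hle_model")) {
    d <- if (inherits(x, "control_net")) as.numeric(x$d) else as.numeric(x)
    if (scheme == "richardson")
      return(pracma::grad(function(v) cpp_energy(object$cpp, v)$G_hat, d))
    return(cpp_gradient(object$cpp, d, h, if (scheme == "forward") 1L else 0L))
  }
  stopifnot(is.function(object))
  x <- as.numeric(x)
  if (scheme == "richardson") return(pracma::grad(object, x))
  if (scheme == "forward") {
    e0 <- object(x)
    vapply(seq_along(x), function(q) {
      xp <- x; xp[q] <- xp[q] + h; (object(xp) - e0) / h
    }, numeric(1))
  } else {
    vapply(seq_along(x), function(q) {
      xp <- x; xm <- x
      xp[q] <- xp[q] + h; xm[q] <- xm[q] - h
      (object(xp) - object(xm)) / (2 * h)
    }, numeric(1))
  }
}
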