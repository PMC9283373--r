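#' Cell model parameters
#'
#' Constructs the full parameter set of the cell free-energy model: the
#' stress-fibre chemo-mechanics constants, the 2D Ogden elasticity of the
#' cytoplasm and nucleus, the geometric ratios of the resting cell, and the
#' numerical penalty that guards against severe in-plane compression. The
#' defaults are the myofibroblast calibration used throughout the package.
#'
#' Lengths are measured in units of the resting cell radius `R0` and stresses
#' in kPa, so free energies carry units of kPa·R0^3. The reference chemical
#' potential of the unbound proteins (`mu_u`, per protein packet, in kBT) and
#' the lattice-site constant `pi_NL` (the product pi*N_L) only shift or scale
#' the free energy uniformly; both default to the conventional choice
#' `mu_u = 0`, `pi_NL = 1`.
#'
#' @param T_K cell temperature (K).
#' @param dmu_over_kBT difference between the reference bound and unbound
#'   chemical potential, `mu_b0 - mu_u`, in units of kBT (per packet).
#' @param sigma_max isometric (maximum) stress-fibre tension (kPa).
#' @param eps_ss steady-state nominal strain of a stress-fibre functional unit
#'   (dimensionless).
#' @param eta_max maximum normalised angular stress-fibre density.
#' @param rho0 density of protein packets available to form functional units
#'   (packets per um^3).
#' @param mu_C,m_C,kappa_C cytoplasm Ogden shear modulus (kPa), shear exponent,
#'   and in-plane bulk modulus (kPa).
#' @param mu_N,m_N,kappa_N nucleus counterparts of `mu_C`, `m_C`, `kappa_C`.
#' @param b0_over_R0 resting thickness over resting radius.
#' @param RN_over_R0 resting nucleus radius over resting cell radius.
#' @param H0 volume fraction of stress-fibre proteins.
#' @param Omega_log10_um3 log10 of the volume (um^3) of the reference number of
#'   stress-fibre functional units. The printed table gives the magnitude
#'   1e-7.1 with an inverse-volume unit; dimensional consistency of the bound
#'   enthalpy requires a volume, which is the reading used here.
#' @param kappa_bar numerical penalty modulus (kPa).
#' @param Jc area-ratio threshold below which the compression penalty activates.
#' @param mu_u reference internal energy of unbound proteins per packet (kBT).
#' @param pi_NL the constant pi*N_L entering the unbound chemical potential.
#' @return An object of class `cell_parameters` (a validated named list).
#' @examples
#' p <- cell_parameters()
#' p$sigma_max
#' @export
cell_parameters <- function(T_K = 310,
                            dmu_over_kBT = 1,
                            sigma_max = 240,
                            eps_ss = 0.354,
                            eta_max = 0.75,
                            rho0 = 3e6,
                            mu_C = 1.67, m_C = 5, kappa_C = 35,
                            mu_N = 3.3, m_N = 20, kappa_N = 35,
                            b0_over_R0 = 0.05,
                            RN_over_R0 = 0.256 * sqrt(pi),
                            H0 = 0.032,
                            Omega_log10_um3 = -7.1,
                            kappa_bar = 1e5,
                            Jc = 0.6,
                            mu_u = 0,
                            pi_NL = 1) {
  p <- list(T_K = T_K, dmu_over_kBT = dmu_over_kBT, sigma_max = sigma_max,
            eps_ss = eps_ss, eta_max = eta_max, rho0 = rho0,
            mu_C = mu_C, m_C = m_C, kappa_C = kappa_C,
            mu_N = mu_N, m_N = m_N, kappa_N = kappa_N,
            b0_over_R0 = b0_over_R0, RN_over_R0 = RN_over_R0,
            H0 = H0, Omega_log10_um3 = Omega_log10_um3,
            kappa_bar = kappa_bar, Jc = Jc, mu_u = mu_u, pi_NL = pi_NL)
  validate_cell_parameters(p)
  class(p) <- "cell_parameters"
  p
}

validate_cell_parameters <- function(p) {
  stopifnot(is.numeric(unlist(p)), all(is.finite(unlist(p))))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$T_K > 0, "T_K must be positive")
  chk(p$sigma_max >= 0, "sigma_max must be non-negative")
  chk(p$eps_ss > -1, "eps_ss must exceed -1")
  chk(p$eta_max > 0 && p$eta_max <= 1, "eta_max must lie in (0, 1]")
  chk(p$rho0 > 0, "rho0 must be positive")
  for (k in c("mu_C", "kappa_C", "mu_N", "kappa_N", "kappa_bar"))
    chk(p[[k]] >= 0, paste(k, "must be non-negative"))
  chk(p$Jc > 0 && p$Jc < 1, "Jc must lie in (0, 1)")
  chk(p$b0_over_R0 > 0, "b0_over_R0 must be positive")
  chk(p$RN_over_R0 > 0 && p$RN_over_R0 < 1, "RN_over_R0 must lie in (0, 1)")
  chk(p$H0 > 0 && p$H0 < 1, "H0 must lie in (0, 1)")
  chk(p$pi_NL > 0, "pi_NL must be positive")
  invisible(p)
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("Cell model parameters (stresses kPa, lengths R0)\n")
  cat(sprintf("  T = %g K, mu_b0 - mu_u = %g kBT, sigma_max = %g kPa\n",
              x$T_K, x$dmu_over_kBT, x$sigma_max))
  cat(sprintf("  eps_ss = %g, eta_max = %g, H0 = %g, Omega = 10^%g um^3\n",
              x$eps_ss, x$eta_max, x$H0, x$Omega_log10_um3))
  cat(sprintf("  cytoplasm: mu = %g, m = %g, kappa = %g | nucleus: mu = %g, m = %g, kappa = %g\n",
              x$mu_C, x$m_C, x$kappa_C, x$mu_N, x$m_N, x$kappa_N))
  cat(sprintf("  b0/R0 = %g, RN/R0 = %g, penalty: kappa_bar = %g, Jc = %g\n",
              x$b0_over_R0, x$RN_over_R0, x$kappa_bar, x$Jc))
  invisible(x)
}

# Derived constants used throughout the energy model.
#  - kBT_J: thermal energy in Joules
#  - dmu_hat: (mu_u - mu_b)/kBT per packet, combining the reference potential
#    difference with the isometric mechanical work term of the bound enthalpy
#  - rho0_kBT_kPa: rho0 * kB * T expressed in kPa (1 J/um^3 = 1e15 kPa)
derived_constants <- function(p) {
  kBT_J <- .kB * p$T_K
  Omega_m3 <- 10^p$Omega_log10_um3 * 1e-18
  sOmega <- p$sigma_max * 1e3 * Omega_m3 / kBT_J      # sigma_max*Omega in kBT
  list(kBT_J = kBT_J,
       mu_b = p$mu_u + p$dmu_over_kBT - sOmega * (1 + p$eps_ss),
       dmu_hat = -p$dmu_over_kBT + sOmega * (1 + p$eps_ss),
       rho0_kBT_kPa = p$rho0 * kBT_J * 1e15,
       VC_hat = pi * (1 - p$RN_over_R0^2) * p$b0_over_R0,
       VN_hat = pi * p$RN_over_R0^2 * p$b0_over_R0)
}

#' Read or write a model configuration file
#'
#' Flat YAML key-value files holding any subset of the [cell_parameters()]
#' arguments; absent keys take the myofibroblast defaults, unknown keys are
#' rejected.
#'
#' @param path file path.
#' @return `load_config()` returns a `cell_parameters` object;
#'   `save_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_config(cell_parameters(sigma_max = 200), f)
#' load_config(f)$sigma_max
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cell_parameters))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(cell_parameters, vals)
}

#' @rdname load_config
#' @param params a `cell_parameters` object.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "cell_parameters"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}
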