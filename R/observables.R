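#' Normalised spreading area
#'
#' `A_hat = (A - A_R)/(A_inf - A_R)`: 0 at seeding (suspension area `A_R`)
#' and fluctuating around 1 at convergence.
#'
#' @param A ensemble-averaged area series.
#' @param A_R suspension (seeding) area; `pi * (lambda_susp * R0)^2`.
#' @param A_inf converged area.
#' @return normalised series.
#' @export
normalized_area <- function(A, A_R, A_inf) {
  if (!is.finite(A_inf - A_R) || A_inf == A_R)
    stop("degenerate normalisation: A_inf must differ from A_R", call. = FALSE)
  (A - A_R) / (A_inf - A_R)
}

#' Squared displacement and ensemble MSD
#'
#' Per-trajectory normalised squared displacement
#' `R2_k = (x_k^2 + y_k^2)/R0^2` from the seeding origin, the ensemble mean
#' `MSD = mean_k(R2_k)`, and a linear slope fitted over a stated window.
#'
#' @param X,Y matrices of centroid coordinates (frames x trajectories), units
#'   of R0; all trajectories share the time grid and are seeded at the origin.
#' @param t_hat frame times.
#' @param window fraction of the time range used for the slope fit (the early
#'   transient is skipped); default `c(0.1, 1)`.
#' @return list with `R2` (frames x trajectories), `MSD`, `MSD_y`, `slope`
#'   (of MSD vs t_hat over the window) and `window`.
#' @export
msd <- function(X, Y, t_hat = seq_len(nrow(as.matrix(X))) - 1,
                window = c(0.1, 1)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("mismatched centroid matrices")
  R2 <- X^2 + Y^2
  MSD <- rowMeans(R2)
  MSDy <- rowMeans(Y^2)
  tw <- range(t_hat) [1] + window * diff(range(t_hat))
  sel <- t_hat >= tw[1] & t_hat <= tw[2]
  slope <- unname(stats::coef(stats::lm(MSD[sel] ~ t_hat[sel]))[2])
  list(R2 = R2, MSD = MSD, MSD_y = MSDy, slope = slope, window = window)
}

#' Directional MSD and motility dimensionality
#'
#' `Lambda_hat = 2 (MSD - MSD_y)/MSD`: 1 for isotropic 2D motion, 0 for
#' motion confined to the stripe (y) axis. Undefined where `MSD = 0`
#' (reported as `NA`, e.g. at seeding).
#'
#' @inheritParams msd
#' @return list with `MSD`, `MSD_y` and `Lambda_hat` series.
#' @export
directional_msd <- function(X, Y) {
  m <- msd(X, Y)
  L <- ifelse(m$MSD > 1e-12, 2 * (m$MSD - m$MSD_y) / m$MSD, NA_real_)
  list(MSD = m$MSD, MSD_y = m$MSD_y, Lambda_hat = L)
}

#' Nematic order parameter of axial angles
#'
#' `Theta = sqrt(<cos 2phi>^2 + <sin 2phi>^2)`: 0 for uniformly distributed
#' orientations, 1 when all angles coincide (mod pi). Optionally weighted.
#'
#' @param phi angles in radians (axial, i.e. defined mod pi).
#' @param w optional non-negative weights.
#' @return scalar in `[0, 1]`.
#' @examples
#' order_parameter(c(0, pi / 4)) # sqrt(0.5)
#' @export
order_parameter <- function(phi, w = NULL) {
  phi <- phi[is.finite(phi)]
  if (!length(phi)) stop("no angles supplied", call. = FALSE)
  if (is.null(w)) w <- rep(1, length(phi))
  w <- w / sum(w)
  sqrt(sum(w * cos(2 * phi))^2 + sum(w * sin(2 * phi))^2)
}

#' Cytoskeletal order parameter
#'
#' Rotationally invariant stress-fibre order: per configuration the dominant
#' fibre direction field is centred by its volume average,
#' `phi_centred = phi_max - <phi_max>_V`, and the nematic order functional is
#' applied to the volume-weighted spatial distribution of `phi_centred`. For
#' an ensemble, the configuration values are averaged.
#'
#' @param phi_max per-element dominant fibre directions (vector), or a list
#'   of such vectors (one per trajectory/configuration).
#' @param volume matching element volumes (reference volumes; any common
#'   scale).
#' @return scalar `Theta_cyto` in `[0, 1]` (ensemble mean when given a list).
#' @export
cyto_order <- function(phi_max, volume) {
  one <- function(ph) {
    ok <- is.finite(ph)
    ph <- ph[ok]; w <- volume[ok]
    ctr <- ph - sum(w * ph) / sum(w)
    order_parameter(ctr, w)
  }
  if (is.list(phi_max)) mean(vapply(phi_max, one, numeric(1))) else one(phi_max)
}

#' Exponential timescale fit
#'
#' Fits `x(t) = x_inf - (x_inf - x_R) exp(-t/tau)` with `x_R` and `x_inf`
#' fixed from the data endpoints, so the time constant `tau` is the only
#' fitted parameter (least squares via a bounded 1D optimisation).
#'
#' @param t_hat time grid.
#' @param x observable series.
#' @param x_R seeding value (default `x[1]`).
#' @param x_inf converged value (default: mean of the last tenth of the
#'   frames).
#' @return list of class `timescale_fit`: `tau`, `x_R`, `x_inf`, `rss`.
#' @examples
#' t <- seq(0, 60, 0.5)
#' fit_timescale(t, 2 - exp(-t / 7))$tau # 7
#' @export
fit_timescale <- function(t_hat, x, x_R = x[1],
                          x_inf = mean(x[t_hat >= 0.9 * max(t_hat)])) {
  if (!is.finite(x_inf - x_R) || abs(x_inf - x_R) < 1e-12 * (1 + abs(x_inf)))
    stop("no timescale: series is flat (x_inf = x_R)", call. = FALSE)
  rss <- function(tau) sum((x - (x_inf - (x_inf - x_R) * exp(-t_hat / tau)))^2)
  span <- max(t_hat) - min(t_hat)
  opt <- optimize(rss, c(span * 1e-6, span * 100), tol = 1e-10)
  structure(list(tau = opt$minimum, x_R = x_R, x_inf = x_inf,
                 rss = opt$objective),
            class = "timescale_fit")
}

#' @export
print.timescale_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: tau = %.4g (x_R = %.4g -> x_inf = %.4g, rss %.3g)\n",
              x$tau, x$x_R, x$x_inf, x$rss))
  invisible(x)
}

#' Ensemble summary of trajectory observables
#'
#' Aligns an ensemble on its common time grid and reports per-frame means and
#' standard deviations of the morphological observables, the normalised area,
#' the MSD family, the dimensionality parameter and the orientational order.
#'
#' @param ensemble an [run_ensemble()] result (list of trajectories sharing a
#'   time grid).
#' @param A_R seeding (suspension) area used for the area normalisation;
#'   defaults to `pi * lambda_susp^2` recovered from the first frame.
#' @return list of class `ensemble_summary` with `t_hat`, data.frame `mean`
#'   / `sd` (columns A, AS, FF, A_hat), `MSD`, `MSD_y`, `Lambda_hat`,
#'   `Theta` (per-frame order parameter of cell orientations), `n`.
#' @export
ensemble_summary <- function(ensemble, A_R = NULL) {
  t_hat <- ensemble[[1]]$t_hat
  get <- function(col) sapply(ensemble, function(tr) tr[[col]])
  A <- get("A"); AS <- get("AS"); FF <- get("FF")
  X <- get("x_c"); Y <- get("y_c"); PHI <- get("phi_cell")
  if (is.null(A_R)) A_R <- A[1, 1]
  Abar <- rowMeans(A)
  A_inf <- mean(Abar[t_hat >= 0.9 * max(t_hat)])
  dm <- directional_msd(X, Y)
  msd_all <- msd(X, Y, t_hat)
  structure(list(
    t_hat = t_hat, n = length(ensemble),
    mean = data.frame(A = Abar, AS = rowMeans(AS), FF = rowMeans(FF),
                      A_hat = normalized_area(Abar, A_R, A_inf)),
    sd = data.frame(A = apply(A, 1, sd), AS = apply(AS, 1, sd),
                    FF = apply(FF, 1, sd)),
    A_R = A_R, A_inf = A_inf,
    MSD = dm$MSD, MSD_y = dm$MSD_y, Lambda_hat = dm$Lambda_hat,
    msd_slope = msd_all$slope,
    Theta = apply(PHI, 1, order_parameter)),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  n <- length(x$t_hat)
  cat(sprintf("Ensemble summary: n = %d trajectories, %d frames to t_hat = %.4g\n",
              x$n, n, max(x$t_hat)))
  cat(sprintf("  final <A>/A_R = %.3f, <AS> = %.3f, MSD = %.3f (slope %.4f), Theta = %.3f\n",
              x$mean$A[n] / x$A_R, x$mean$AS[n], x$MSD[n], x$msd_slope,
              x$Theta[n]))
  invisible(x)
}
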