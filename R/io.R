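#' Trajectory store
#'
#' Writes a trajectory to a self-describing directory store: `meta.yaml`
#' (full configuration echo, seed, homeostatic temperature, pattern) plus
#' `observables.csv`, and optionally `nets.csv` when control nets were
#' stored. A finished store is immutable; reads are lossless and support time
#' windows.
#'
#' @param traj an [run_trajectory()] result.
#' @param path store directory (created; must not already contain a store).
#' @param params the [cell_parameters()] used (echoed into the metadata).
#' @return `read_trajectory()` returns an `hle_trajectory`.
#' @export
write_trajectory <- function(traj, path, params = NULL) {
  stopifnot(inherits(traj, "hle_trajectory"))
  if (file.exists(file.path(path, "meta.yaml")))
    stop("store already exists at ", path, call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  st <- attr(traj, "settings")
  pat <- attr(traj, "pattern")
  meta <- list(format = "hlecell-trajectory-1",
               seed = attr(traj, "seed"),
               zeta_hat = attr(traj, "zeta_hat"),
               GS = attr(traj, "GS"),
               W_hat = if (is.finite(pat$W_hat)) pat$W_hat else "Inf",
               n_frames = nrow(traj),
               settings = unclass(st),
               params = if (is.null(params)) NULL else unclass(params))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"), precision = 15)
  utils::write.csv(as.data.frame(traj), file.path(path, "observables.csv"),
                   row.names = FALSE)
  nets <- attr(traj, "nets")
  if (!is.null(nets))
    utils::write.csv(as.data.frame(nets), file.path(path, "nets.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param path store directory.
#' @param t_window optional `c(t1, t2)`: return exactly the frames with
#'   `t1 <= t_hat <= t2`.
#' @export
read_trajectory <- function(path, t_window = NULL) {
  mf <- file.path(path, "meta.yaml")
  if (!file.exists(mf)) stop("not a trajectory store: ", path, call. = FALSE)
  meta <- yaml::read_yaml(mf)
  if (!identical(meta$format, "hlecell-trajectory-1"))
    stop("unrecognised store format", call. = FALSE)
  frames <- utils::read.csv(file.path(path, "observables.csv"))
  if (nrow(frames) != meta$n_frames)
    stop(sprintf("store integrity error: expected %d frames, found %d (last valid frame %d)",
                 meta$n_frames, nrow(frames), nrow(frames)), call. = FALSE)
  nets <- NULL
  nf <- file.path(path, "nets.csv")
  if (file.exists(nf)) nets <- as.matrix(utils::read.csv(nf))
  if (!is.null(t_window)) {
    sel <- frames$t_hat >= t_window[1] & frames$t_hat <= t_window[2]
    frames <- frames[sel, , drop = FALSE]
    if (!is.null(nets)) nets <- nets[sel, , drop = FALSE]
  }
  W <- meta$W_hat
  pat <- stripe_pattern(if (identical(W, "Inf")) Inf else as.numeric(W))
  st <- meta$settings
  structure(frames, class = c("hle_trajectory", "data.frame"),
            seed = meta$seed, zeta_hat = meta$zeta_hat, GS = meta$GS,
            settings = st, pattern = pat, nets = nets)
}
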