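#' Morphological control net
#'
#' A morphological microstate is a bicubic tensor-product spline displacement
#' field over the bounding square of the reference disc, determined by a 4 x 4
#' grid of control-point displacements (32 scalars). With open knot vectors
#' \{0,0,0,0,1,1,1,1\} in each direction and unit weights the spline is a
#' single bicubic Bezier patch, so the basis functions are products of cubic
#' Bernstein polynomials.
#'
#' @param d a 16 x 2 matrix of control-point displacements (units of R0);
#'   row `k = 4*(i-1)+j` holds the control point at Greville position
#'   `(g[i], g[j])` with `g = (-1, -1/3, 1/3, 1)`. A 4 x 4 x 2 array is also
#'   accepted.
#' @return An object of class `control_net`.
#' @examples
#' z <- control_net()                        # identity (zero displacement)
#' tr <- translate_net(z, c(0.5, 0))         # rigid translation
#' @export
control_net <- function(d = matrix(0, 16, 2)) {
  if (is.array(d) && length(dim(d)) == 3) d <- matrix(d, 16, 2)
  d <- as.matrix(d)
  stopifnot(identical(dim(d), c(16L, 2L)), all(is.finite(d)))
  structure(list(d = d), class = "control_net")
}

#' @export
print.control_net <- function(x, ...) {
  cat("4 x 4 control net, displacement ranges:",
      sprintf("x1 [%.3f, %.3f], x2 [%.3f, %.3f] R0\n",
              min(x$d[, 1]), max(x$d[, 1]), min(x$d[, 2]), max(x$d[, 2])))
  invisible(x)
}

# Greville abscissae of the cubic Bezier basis over [-1, 1].
greville <- function() c(-1, -1 / 3, 1 / 3, 1)

#' Construct the control net of an affine displacement field
#'
#' Exploits the linear precision of the Bezier patch: placing control values on
#' the Greville grid reproduces `u(X) = A X + c` exactly.
#'
#' @param A 2 x 2 displacement-gradient matrix.
#' @param shift length-2 translation.
#' @return A `control_net`.
#' @export
affine_net <- function(A = matrix(0, 2, 2), shift = c(0, 0)) {
  g <- greville()
  pts <- as.matrix(expand.grid(j = g, i = g))[, c("i", "j")]  # row k=4(i-1)+j
  control_net(t(A %*% t(pts)) + rep(shift, each = 16))
}

#' @rdname affine_net
#' @param net a `control_net`.
#' @param v length-2 rigid translation (units of R0).
#' @export
translate_net <- function(net, v) {
  control_net(net$d + rep(as.numeric(v), each = 16))
}

#' Control net of the uniformly compressed suspension circle
#'
#' @param lambda equibiaxial stretch of the suspension state (see
#'   [suspension_state()]).
#' @param centre seeding position of the cell centroid.
#' @return A `control_net` realising `x = lambda * X + centre`.
#' @export
suspension_net <- function(lambda, centre = c(0, 0)) {
  affine_net(diag(lambda - 1, 2), centre)
}

# Cubic Bernstein basis values at parameters s in [0, 1]: length(s) x 4.
bernstein3 <- function(s) {
  cbind((1 - s)^3, 3 * s * (1 - s)^2, 3 * s^2 * (1 - s), s^3)
}

# Tensor-product basis at reference points X (n x 2, inside [-1,1]^2): n x 16,
# column k = 4*(i-1)+j equals Bx_i(s) * By_j(t).
patch_basis <- function(X) {
  X <- rbind(X)
  if (any(X < -1 - 1e-12 | X > 1 + 1e-12))
    stop("evaluation point outside the spline parameter domain [-1, 1]^2",
         call. = FALSE)
  Bs <- bernstein3(pmin(1, pmax(0, (X[, 1] + 1) / 2)))
  Bt <- bernstein3(pmin(1, pmax(0, (X[, 2] + 1) / 2)))
  out <- matrix(0, nrow(X), 16)
  for (i in 1:4) for (j in 1:4)
    out[, 4 * (i - 1) + j] <- Bs[, i] * Bt[, j]
  out
}

#' Evaluate the spline displacement field
#'
#' @param net a [control_net()].
#' @param X reference points (n x 2 matrix or length-2 vector), in units of R0
#'   inside the bounding square `[-1, 1]^2`.
#' @return n x 2 matrix of displacements `u(X)`.
#' @examples
#' net <- affine_net(diag(0.1, 2))
#' nurbs_displacement(net, c(0.5, -0.25)) # 0.1 * X exactly
#' @export
nurbs_displacement <- function(net, X) {
  stopifnot(inherits(net, "control_net"))
  patch_basis(rbind(X)) %*% net$d
}
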