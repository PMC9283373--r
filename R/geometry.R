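#' Polygon area, centroid and second moments
#'
#' Signed-area (Green's theorem) formulas for a simple polygon given as an
#' ordered vertex matrix; used for cell area, centroid and the moment-based
#' best-fit ellipse.
#'
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return `polygon_moments()` returns list with `A` (area), `centroid`,
#'   and the central second area moments `mxx`, `mxy`, `myy`.
#' @export
polygon_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (A < 0) { # ensure counter-clockwise
    return(polygon_moments(poly[rev(seq_len(nrow(poly))), , drop = FALSE]))
  }
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  mxx <- sum((x^2 + x * x2 + x2^2) * cr) / 12 - A * cx^2
  myy <- sum((y^2 + y * y2 + y2^2) * cr) / 12 - A * cy^2
  mxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24 - A * cx * cy
  list(A = A, centroid = c(cx, cy), mxx = mxx, mxy = mxy, myy = myy)
}

polygon_centroid <- function(poly) polygon_moments(poly)$centroid

polygon_perimeter <- function(poly) {
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# O(n^2) simplicity check: no two non-adjacent edges intersect.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  p1 <- poly; p2 <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                               p2[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

segments_intersect <- function(a1, a2, b1, b2) {
  b1 <- rbind(b1); b2 <- rbind(b2)
  d1 <- a2 - a1
  cross <- function(ox, oy, px, py) ox * py - oy * px
  s1 <- cross(d1[1], d1[2], b1[, 1] - a1[1], b1[, 2] - a1[2])
  s2 <- cross(d1[1], d1[2], b2[, 1] - a1[1], b2[, 2] - a1[2])
  db <- b2 - b1
  s3 <- cross(db[, 1], db[, 2], a1[1] - b1[, 1], a1[2] - b1[, 2])
  s4 <- cross(db[, 1], db[, 2], a2[1] - b1[, 1], a2[2] - b1[, 2])
  (s1 * s2 < 0) & (s3 * s4 < 0)
}

#' Morphological observables of a configuration
#'
#' Computes the coarse-grained shape metrics used throughout: spread area,
#' perimeter, form factor `FF = p^2/(4 pi A)`, and the aspect ratio and
#' orientation of the best-fit ellipse. The best-fit ellipse is the ellipse
#' with the same area and the same central second area moments as the boundary
#' polygon (the standard image-analysis construction); its aspect ratio is the
#' major/minor axis ratio, and `phi_cell` is the angle of the major axis
#' measured from the stripe (x2) axis, in `(-pi/2, pi/2]`.
#'
#' @param config a [deform()] configuration, or an n x 2 boundary polygon.
#' @return list with `A`, `p`, `AS`, `phi_cell`, `FF`, `centroid`, and
#'   `simple` (boundary simplicity flag; the other metrics are still reported
#'   when the polygon self-intersects, but flagged).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)[-1]
#' circ <- 0.92 * cbind(cos(th), sin(th))
#' geometry_observables(circ)$FF # ~1
#' @export
geometry_observables <- function(config) {
  poly <- if (inherits(config, "deformed_configuration")) config$boundary
          else as.matrix(config)
  m <- polygon_moments(poly)
  if (m$A <= 0) stop("degenerate boundary polygon (non-positive area)")
  p <- polygon_perimeter(poly)
  # equal-moment ellipse: eigenvalues of the normalised moment tensor give
  # (semi-axis/2)^2
  M <- matrix(c(m$mxx, m$mxy, m$mxy, m$myy), 2) / m$A
  ev <- eigen(M, symmetric = TRUE)
  AS <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
  v <- ev$vectors[, 1]
  phi <- atan2(-v[1], v[2])     # angle from x2, direction m = (-sin, cos)
  phi <- fold_axial(phi)
  list(A = m$A, p = p, AS = AS, phi_cell = phi, FF = p^2 / (4 * pi * m$A),
       centroid = m$centroid, simple = polygon_is_simple(poly))
}

# Fold an axial angle into (-pi/2, pi/2].
fold_axial <- function(phi) {
  phi <- (phi + pi / 2) %% pi - pi / 2
  ifelse(phi <= -pi / 2 + 1e-12, phi + pi, phi)
}
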