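#' Triangulated reference cell
#'
#' Builds a quasi-uniform constant-strain-triangle mesh of the resting cell: a
#' disc of radius 1 (lengths in units of R0) with a concentric nucleus disc of
#' radius `RN_over_R0`. Nodes are laid out on concentric rings, with one ring
#' snapped exactly to the nucleus boundary so every element is wholly nucleus
#' or wholly cytoplasm. Alternate rings are staggered by half an angular step
#' to keep triangles close to equilateral.
#'
#' @param params a [cell_parameters()] object (only the geometric ratios are
#'   used).
#' @param target_edge requested element edge length (units of R0); the mesh is
#'   quasi-uniform at roughly this size. Default R0/10.
#' @return An object of class `reference_mesh`: list with `nodes` (N x 2),
#'   `triangles` (E x 3, 1-based, counter-clockwise), `region` (factor
#'   `"nucleus"`/`"cytoplasm"` per element), `area` (reference area per
#'   element), `rim` (indices of the outer boundary nodes in order),
#'   `Dm_inv` (E x 4 flattened inverse reference edge matrices) and
#'   `target_edge`.
#' @examples
#' m <- build_reference_mesh(cell_parameters(), target_edge = 0.2)
#' sum(m$area) / pi # close to 1
#' @export
build_reference_mesh <- function(params = cell_parameters(), target_edge = 0.1) {
  stopifnot(target_edge > 0, target_edge < 1)
  RN <- params$RN_over_R0
  for (attempt in 0:4) {
    stagger <- 0.5 + attempt * 0.08
    mesh <- ring_mesh(RN, target_edge, stagger)
    if (mesh$min_angle >= 15) break
  }
  if (mesh$min_angle < 15)
    stop("mesh generation produced degenerate triangles (min angle ",
         round(mesh$min_angle, 1), " deg)", call. = FALSE)
  mesh$target_edge <- target_edge
  class(mesh) <- "reference_mesh"
  mesh
}

ring_mesh <- function(RN, e, stagger) {
  n_in <- max(2L, round(RN / e))
  n_out <- max(2L, round((1 - RN) / e))
  radii <- c(RN * seq_len(n_in) / n_in,
             RN + (1 - RN) * seq_len(n_out) / n_out)
  nodes <- matrix(0, nrow = 1, ncol = 2)          # centre node
  ring_idx <- list()
  ring_off <- numeric(length(radii))
  for (k in seq_along(radii)) {
    m <- max(6L, round(2 * pi * radii[k] / e))
    off <- if (k %% 2 == 0) stagger else 0
    th <- 2 * pi * (seq_len(m) - 1 + off) / m
    ring_idx[[k]] <- nrow(nodes) + seq_len(m)
    ring_off[k] <- off / m                         # parametric offset in turns
    nodes <- rbind(nodes, radii[k] * cbind(cos(th), sin(th)))
  }
  # centre fan
  first <- ring_idx[[1]]
  m1 <- length(first)
  tris <- cbind(1L, first, first[c(2:m1, 1)])
  # stitch consecutive rings by merging their angular parameterisations
  for (k in seq_len(length(radii) - 1)) {
    tris <- rbind(tris, stitch_rings(ring_idx[[k]], ring_idx[[k + 1]],
                                     ring_off[k], ring_off[k + 1]))
  }
  region <- ring_regions(nodes, tris, RN)
  geo <- triangle_geometry(nodes, tris)
  list(nodes = nodes, triangles = tris, region = region,
       area = geo$area, Dm_inv = geo$Dm_inv,
       rim = ring_idx[[length(radii)]],
       min_angle = geo$min_angle)
}

# Triangulate the annulus between an inner ring A and outer ring B by walking
# both angular parameterisations in step (two-pointer merge).
stitch_rings <- function(A, B, offA, offB) {
  mA <- length(A); mB <- length(B)
  tris <- matrix(0L, nrow = mA + mB, ncol = 3)
  i <- 0L; j <- 0L; t <- 0L
  while (i < mA || j < mB) {
    t <- t + 1L
    adv_inner <- if (i >= mA) FALSE else if (j >= mB) TRUE else
      (i + 1) / mA + offA <= (j + 1) / mB + offB
    if (adv_inner) {
      tris[t, ] <- c(A[i %% mA + 1L], B[j %% mB + 1L], A[(i + 1L) %% mA + 1L])
      i <- i + 1L
    } else {
      tris[t, ] <- c(A[i %% mA + 1L], B[j %% mB + 1L], B[(j + 1L) %% mB + 1L])
      j <- j + 1L
    }
  }
  tris
}

ring_regions <- function(nodes, tris, RN) {
  cx <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
  cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  factor(ifelse(sqrt(cx^2 + cy^2) < RN, "nucleus", "cytoplasm"),
         levels = c("nucleus", "cytoplasm"))
}

triangle_geometry <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c_ <- nodes[tris[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  det <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  if (any(det <= 0)) stop("mesh produced a non-CCW or degenerate triangle")
  area <- det / 2
  # inverse of the reference edge matrix Dm = [e1 e2] (columns)
  Dm_inv <- cbind(e2[, 2] / det, -e2[, 1] / det, -e1[, 2] / det, e1[, 1] / det)
  # minimum interior angle over the mesh (degrees)
  la <- rowSums((b - c_)^2); lb <- rowSums((a - c_)^2); lc <- rowSums((a - b)^2)
  ang <- function(opp, s1, s2) acos(pmin(1, pmax(-1, (s1 + s2 - opp) /
                                                   (2 * sqrt(s1 * s2)))))
  min_angle <- min(ang(la, lb, lc), ang(lb, la, lc), ang(lc, la, lb)) * 180 / pi
  list(area = area, Dm_inv = Dm_inv, min_angle = min_angle)
}

#' @export
print.reference_mesh <- function(x, ...) {
  cat(sprintf("Reference cell mesh: %d nodes, %d triangles (%d nucleus), e = %g R0\n",
              nrow(x$nodes), nrow(x$triangles), sum(x$region == "nucleus"),
              x$target_edge))
  cat(sprintf("  total area %.4f pi R0^2, rim of %d nodes\n",
              sum(x$area) / pi, length(x$rim)))
  invisible(x)
}

#' Export / import a reference mesh as plain text
#'
#' Writes the node table, connectivity and region labels to a single
#' whitespace-delimited text file, and reads it back.
#'
#' @param mesh a `reference_mesh`.
#' @param path file path.
#' @return `read_mesh()` returns a `reference_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("mesh %d %d %.17g", nrow(mesh$nodes),
                     nrow(mesh$triangles), mesh$target_edge), con)
  write.table(format(mesh$nodes, digits = 17), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(cbind(mesh$triangles, as.character(mesh$region)), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " ")[[1]]
  nn <- as.integer(hdr[2]); ne <- as.integer(hdr[3])
  tab <- read.table(path, skip = 1, nrows = nn)
  nodes <- as.matrix(tab[, 1:2])
  dimnames(nodes) <- NULL
  tt <- read.table(path, skip = 1 + nn, nrows = ne,
                   colClasses = c("integer", "integer", "integer", "character"))
  tris <- as.matrix(tt[, 1:3])
  dimnames(tris) <- NULL
  geo <- triangle_geometry(nodes, tris)
  rim <- boundary_ring(nodes, tris)
  mesh <- list(nodes = nodes, triangles = tris,
               region = factor(tt[[4]], levels = c("nucleus", "cytoplasm")),
               area = geo$area, Dm_inv = geo$Dm_inv, rim = rim,
               min_angle = geo$min_angle, target_edge = as.numeric(hdr[4]))
  class(mesh) <- "reference_mesh"
  mesh
}

# Recover the ordered outer boundary ring from connectivity (edges used once).
boundary_ring <- function(nodes, tris) {
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
  ring <- integer(nrow(once))
  ring[1:2] <- once[1, ]
  used <- 1
  for (k in 3:length(ring)) {
    nxt <- which((once[, 1] == ring[k - 1] | once[, 2] == ring[k - 1]) &
                   !(seq_len(nrow(once)) %in% used))
    nxt <- nxt[1]
    used <- c(used, nxt)
    ring[k] <- setdiff(once[nxt, ], ring[k - 1])
  }
  # orient counter-clockwise
  x <- nodes[ring, 1]; y <- nodes[ring, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) ring <- rev(ring)
  ring
}
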