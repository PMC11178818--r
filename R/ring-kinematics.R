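# Rigid-body motion of the round-window bony edge.
#
# The edge ring nodes carry complex z-displacements (one frequency, one
# direction).  Triplets of ring nodes define triangles; for each triangle the
# small-rotation rigid model
#     w_s = w + gamma * y_s - phi * x_s,   s = i, j, k
# is inverted exactly (3x3 system), and the (w, gamma, phi) triple is
# averaged over the triangles.  Complex arithmetic carries the separate
# real/imaginary channels in one pass; the two bookkeepings are identical
# because the model is linear.

#' Fit the rigid motion of one edge triangle
#'
#' Inverts the three-vertex rigid model exactly: the translation `w` along
#' the local z-axis and rotations `gamma` (about x) and `phi` (about y) that
#' reproduce the three complex nodal z-displacements.
#'
#' @param coords 3x2 numeric matrix of vertex (x, y) coordinates in the
#'   round-window frame, mm.
#' @param wz complex length-3 vector of vertex z-displacements, mm.
#' @return list of class `rw_triangle_motion` with complex `w` (mm),
#'   `gamma`, `phi` (rad).
#' @export
fit_triangle_motion <- function(coords, wz) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 3L, ncol(coords) == 2L, length(wz) == 3L)
  wz <- as.complex(wz)
  x <- coords[, 1L]; y <- coords[, 2L]
  den <- (y[3L] - y[1L]) * x[2L] + (y[2L] - y[3L]) * x[1L] +
    (y[1L] - y[2L]) * x[3L]
  if (abs(den) < 1e-12)
    stop(sprintf(
      "fit_triangle_motion(): degenerate (collinear) triangle (%g,%g) (%g,%g) (%g,%g)",
      x[1L], y[1L], x[2L], y[2L], x[3L], y[3L]))
  Minv <- matrix(c(
    x[2L] * y[3L] - y[2L] * x[3L], y[1L] * x[3L] - x[1L] * y[3L], x[1L] * y[2L] - y[1L] * x[2L],
    x[3L] - x[2L],                 x[1L] - x[3L],                 x[2L] - x[1L],
    y[3L] - y[2L],                 y[1L] - y[3L],                 y[2L] - y[1L]),
    3L, 3L, byrow = TRUE) / den
  m <- as.vector(Minv %*% wz)
  structure(list(w = m[1L], gamma = m[2L], phi = m[3L]),
            class = "rw_triangle_motion")
}

#' Evaluate the rigid z-field of a triangle motion at points
#'
#' Forward model `w + gamma * y - phi * x`; inverse of
#' [fit_triangle_motion()].
#'
#' @param motion a `rw_triangle_motion` or `rw_ring_motion`.
#' @param xy n x 2 matrix of (x, y) points, mm.
#' @return complex length-n vector of z-displacements.
#' @export
rigid_field <- function(motion, xy) {
  xy <- as.matrix(xy)
  motion$w + motion$gamma * xy[, 2L] - motion$phi * xy[, 1L]
}

#' Average triangle motions into the ring motion
#'
#' Complex arithmetic mean of `w`, `gamma`, `phi` over the triangle fits
#' (real and imaginary channels average independently).
#'
#' @param motions list of `rw_triangle_motion`.
#' @return list of class `rw_ring_motion` with complex `w`, `gamma`, `phi`.
#' @export
average_ring_motion <- function(motions) {
  if (length(motions) == 0L)
    stop("average_ring_motion(): empty motion list")
  w <- mean(vapply(motions, function(m) m$w, complex(1)))
  g <- mean(vapply(motions, function(m) m$gamma, complex(1)))
  p <- mean(vapply(motions, function(m) m$phi, complex(1)))
  structure(list(w = w, gamma = g, phi = p), class = "rw_ring_motion")
}

#' @export
print.rw_ring_motion <- function(x, ...) {
  cat("<rw_ring_motion>  w =", format(x$w), "mm, gamma =", format(x$gamma),
      "rad, phi =", format(x$phi), "rad\n")
  invisible(x)
}

#' Build the edge-ring triangulation
#'
#' Sorts the edge nodes by polar angle about the round-window origin in the
#' local xy-plane and groups consecutive disjoint triples into triangles:
#' (1,2,3), (4,5,6), ...  The canonical edge has 48 nodes and 16 triangles;
#' any node count divisible by 3 is accepted for synthetic rings.
#'
#' @param xy n x 2 matrix of node (x, y) coordinates in the round-window
#'   frame, mm.
#' @param node_ids optional node identifiers (default `seq_len(n)`).
#' @param triangles optional m x 3 matrix of row-index triples overriding the
#'   consecutive grouping (for sensitivity checks).
#' @return list of class `rw_ring` with `node_ids`, `xy` (sorted by angle)
#'   and `triangles` (m x 3 index matrix into the sorted order).
#' @export
build_ring <- function(xy, node_ids = NULL, triangles = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(node_ids)) node_ids <- seq_len(n)
  stopifnot(length(node_ids) == n, ncol(xy) == 2L)
  if (n %% 3L != 0L)
    stop("build_ring(): node count must be divisible by 3, got ", n)
  ang <- atan2(xy[, 2L], xy[, 1L])
  ord <- order(ang)
  if (any(diff(sort(ang)) < 1e-12))
    stop("build_ring(): duplicate polar angles in edge ring")
  xy <- xy[ord, , drop = FALSE]
  node_ids <- node_ids[ord]
  if (is.null(triangles))
    triangles <- matrix(seq_len(n), ncol = 3L, byrow = TRUE)
  triangles <- as.matrix(triangles)
  stopifnot(ncol(triangles) == 3L)
  for (t in seq_len(nrow(triangles))) {
    tri <- triangles[t, ]
    x <- xy[tri, 1L]; y <- xy[tri, 2L]
    den <- (y[3L] - y[1L]) * x[2L] + (y[2L] - y[3L]) * x[1L] +
      (y[1L] - y[2L]) * x[3L]
    if (abs(den) < 1e-12)
      stop("build_ring(): degenerate triangle at triple ", t)
  }
  structure(list(node_ids = node_ids, xy = xy, triangles = triangles),
            class = "rw_ring")
}

#' Read an edge ring from a CSV of node coordinates
#'
#' Expects columns `node_id`, `x_mm`, `y_mm`.
#'
#' @param path CSV file path.
#' @return an `rw_ring`.
#' @export
read_ring_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("node_id", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("ring CSV must have columns: ", paste(need, collapse = ", "))
  build_ring(cbind(d$x_mm, d$y_mm), node_ids = d$node_id)
}

#' Fit the averaged rigid edge motion from ring displacements
#'
#' Convenience wrapper: fits every ring triangle and averages.
#'
#' @param ring an `rw_ring`.
#' @param wz complex nodal z-displacements in the ring's sorted node order, mm.
#' @return an `rw_ring_motion`.
#' @export
ring_motion <- function(ring, wz) {
  stopifnot(inherits(ring, "rw_ring"), length(wz) == nrow(ring$xy))
  wz <- as.complex(wz)
  motions <- lapply(seq_len(nrow(ring$triangles)), function(t) {
    tri <- ring$triangles[t, ]
    fit_triangle_motion(ring$xy[tri, , drop = FALSE], wz[tri])
  })
  average_ring_motion(motions)
}
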