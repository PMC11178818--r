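# Fluid volume displacement of the round-window membrane.
#
# The membrane surface is a quadrilateral mesh; each quad (A,B,C,D) splits
# along the A-C diagonal into triangles (A,B,C) and (A,C,D).  The volume
# displacement is the integral of the nodal z-displacement *relative to the
# fitted rigid edge motion*, evaluated triangle-wise as signed projected area
# times the vertex-average relative displacement:
#     V = sum_t (A_t / 3) (dw_A + dw_B + dw_C).
# Positive area corresponds to counterclockwise winding viewed from +z
# (toward the cochlea), so outward deflection gives positive V.

#' Split quadrilaterals into triangles along the A-C diagonal
#'
#' Each quad (A,B,C,D) yields (A,B,C) and (A,C,D); with `diagonal = "BD"`
#' the alternative split (A,B,D), (B,C,D) is used for sensitivity checks.
#'
#' @param quads m x 4 integer matrix of node indices with consistent winding.
#' @param diagonal `"AC"` (canonical) or `"BD"`.
#' @return 2m x 3 integer matrix of triangle node indices.
#' @export
split_quads <- function(quads, diagonal = c("AC", "BD")) {
  diagonal <- match.arg(diagonal)
  quads <- as.matrix(quads)
  stopifnot(ncol(quads) == 4L)
  if (diagonal == "AC")
    tri <- rbind(quads[, c(1L, 2L, 3L), drop = FALSE],
                 quads[, c(1L, 3L, 4L), drop = FALSE])
  else
    tri <- rbind(quads[, c(1L, 2L, 4L), drop = FALSE],
                 quads[, c(2L, 3L, 4L), drop = FALSE])
  m <- nrow(quads)
  # interleave so triangles 2t-1, 2t come from quad t
  idx <- as.vector(rbind(seq_len(m), seq_len(m) + m))
  tri[idx, , drop = FALSE]
}

#' Signed projected area of a triangle on the xy-plane
#'
#' Shoelace half-sum: positive for counterclockwise winding viewed from +z.
#'
#' @param tri 3 x 2 numeric matrix of vertex (x, y), mm.
#' @return signed area, mm^2.
#' @export
projected_area <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) == 2L)
  x <- tri[, 1L]; y <- tri[, 2L]
  0.5 * (x[1L] * y[2L] + x[2L] * y[3L] + x[3L] * y[1L] -
           x[1L] * y[3L] - x[2L] * y[1L] - x[3L] * y[2L])
}

#' Membrane mesh container
#'
#' @param nodes n x 2 (or n x 3; z ignored for area projection) matrix of
#'   node coordinates in the round-window frame, mm.
#' @param quads m x 4 integer matrix of node indices, consistent winding.
#' @param rewind logical; re-wind quads whose split triangles have negative
#'   projected area under the canonical orientation (a notice is emitted).
#' @return list of class `rw_membrane` with `nodes` (xy), `quads`,
#'   `triangles` (2m x 3), `areas` (per triangle, mm^2) and `area_total`.
#' @export
membrane_mesh <- function(nodes, quads, rewind = TRUE) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) >= 3L) nodes <- nodes[, 1:2, drop = FALSE]
  quads <- as.matrix(quads)
  stopifnot(ncol(nodes) == 2L, ncol(quads) == 4L,
            max(quads) <= nrow(nodes), min(quads) >= 1L)
  tri_areas <- function(q) {
    tr <- split_quads(q)
    a <- vapply(seq_len(nrow(tr)), function(t)
      projected_area(nodes[tr[t, ], , drop = FALSE]), numeric(1))
    list(tr = tr, a = a)
  }
  ta <- tri_areas(quads)
  neg_quads <- unique(ceiling(which(ta$a < 0) / 2))
  if (length(neg_quads) && rewind) {
    flip <- ta$a[2 * neg_quads - 1] < 0 & ta$a[2 * neg_quads] < 0
    rev_ids <- neg_quads[flip]
    if (length(rev_ids)) {
      message("membrane_mesh(): re-winding ", length(rev_ids),
              " quad(s) to canonical orientation")
      quads[rev_ids, ] <- quads[rev_ids, c(1L, 4L, 3L, 2L), drop = FALSE]
      ta <- tri_areas(quads)
    }
  }
  mixed <- which(sign(ta$a[seq(1, length(ta$a), 2)]) *
                   sign(ta$a[seq(2, length(ta$a), 2)]) < 0)
  for (q in mixed)
    warning("membrane_mesh(): quad ", q,
            " splits into opposite-sign triangles (self-intersecting?)")
  structure(list(nodes = nodes, quads = quads, triangles = ta$tr,
                 areas = ta$a, area_total = sum(ta$a)),
            class = "rw_membrane")
}

#' Relative membrane displacement with the rigid edge motion removed
#'
#' dw = wz - (w + gamma * y - phi * x), complex.
#'
#' @param xy n x 2 matrix of vertex coordinates, mm.
#' @param wz complex nodal z-displacements, mm.
#' @param ring an `rw_ring_motion`.
#' @return complex length-n vector, mm.
#' @export
relative_displacement <- function(xy, wz, ring) {
  stopifnot(inherits(ring, "rw_ring_motion"))
  as.complex(wz) - rigid_field(ring, xy)
}

#' Amplitude and phase of a complex scalar
#'
#' @param z complex scalar or vector.
#' @return list with `amplitude` (= |z|) and `phase_deg` = atan2(Im, Re) in
#'   degrees, in (-180, 180]; the phase of 0 is 0.
#' @export
amplitude_phase <- function(z) {
  z <- as.complex(z)
  ph <- atan2(Im(z), Re(z)) * 180 / pi
  ph[ph <= -180] <- ph[ph <= -180] + 360
  list(amplitude = Mod(z), phase_deg = ph)
}

#' Total fluid volume displacement of the membrane
#'
#' Sums (A_t / 3) times the vertex-sum of relative displacements over all
#' split triangles.
#'
#' @param mesh an `rw_membrane`.
#' @param field complex z-displacements at all membrane nodes, mm (same order
#'   as `mesh$nodes`).
#' @param ring an `rw_ring_motion` fitted from the edge.
#' @return list of class `rw_vd` with complex `V` (mm^3), `amplitude` and
#'   `phase_deg`.
#' @export
total_vd <- function(mesh, field, ring) {
  stopifnot(inherits(mesh, "rw_membrane"))
  if (length(field) != nrow(mesh$nodes))
    stop("total_vd(): field length ", length(field),
         " does not match node count ", nrow(mesh$nodes))
  dw <- relative_displacement(mesh$nodes, field, ring)
  tr <- mesh$triangles
  V <- sum(mesh$areas / 3 *
             (dw[tr[, 1L]] + dw[tr[, 2L]] + dw[tr[, 3L]]))
  ap <- amplitude_phase(V)
  structure(list(V = V, amplitude = ap$amplitude, phase_deg = ap$phase_deg),
            class = "rw_vd")
}

#' @export
print.rw_vd <- function(x, ...) {
  cat("<rw_vd>  V =", format(x$V), "mm^3  |V| =", format(x$amplitude),
      " phase =", format(x$phase_deg), "deg\n")
  invisible(x)
}
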