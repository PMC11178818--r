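# Coordinate frames and the two-angle (alpha, beta) parametrization of the
# stimulating-force direction.
#
# The stimulation frame is a right-handed orthonormal triad (x00, y00, z00)
# attached to the excitation site on the otic capsule.  A force direction is
# obtained from the primary direction z00 by two successive axis rotations:
# alpha about x00 (carrying y00 to y_a0), then beta about y_a0.  All public
# angles are degrees; radians appear only inside trig calls.

DEG <- pi / 180

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.norm3 <- function(v) sqrt(sum(v * v))

#' Construct an orthonormal right-handed coordinate frame
#'
#' Builds a frame from an origin and three versors.  Versors printed to a few
#' decimals (as in published model descriptions) are slightly non-orthonormal;
#' by default one Gram--Schmidt pass anchored on `x_hat` restores an exact
#' right-handed orthonormal triad, changing each versor by less than the
#' rounding error that broke it (about 2e-3).
#'
#' @param origin numeric length-3, frame origin in global skull coordinates (mm).
#' @param x_hat,y_hat,z_hat numeric length-3 versors in global coordinates.
#' @param reorthonormalize logical; re-orthonormalize the triad (default `TRUE`).
#' @return An object of class `rw_frame` with fields `origin`, `x_hat`,
#'   `y_hat`, `z_hat`.
#' @examples
#' fr <- stimulation_frame()
#' crossprod(cbind(fr$x_hat, fr$y_hat, fr$z_hat))  # identity
#' @export
frame <- function(origin, x_hat, y_hat, z_hat, reorthonormalize = TRUE) {
  origin <- as.numeric(origin)
  x <- as.numeric(x_hat); y <- as.numeric(y_hat); z <- as.numeric(z_hat)
  stopifnot(length(origin) == 3L, length(x) == 3L, length(y) == 3L,
            length(z) == 3L, all(is.finite(c(origin, x, y, z))))
  if (reorthonormalize) {
    x0 <- x; y0 <- y; z0 <- z
    x <- x / .norm3(x)
    y <- y - sum(y * x) * x
    y <- y / .norm3(y)
    z <- .cross3(x, y)
    if (sum(z * z0) < 0)
      stop("frame(): supplied versors are not right-handed")
    drift <- max(.norm3(x - x0), .norm3(y - y0), .norm3(z - z0))
    if (drift > 5e-3)
      warning(sprintf("frame(): re-orthonormalization moved a versor by %.2g", drift))
  }
  fr <- structure(list(origin = origin, x_hat = x, y_hat = y, z_hat = z),
                  class = "rw_frame")
  .check_frame(fr)
  fr
}

.check_frame <- function(fr, tol = 1e-9) {
  B <- cbind(fr$x_hat, fr$y_hat, fr$z_hat)
  if (max(abs(crossprod(B) - diag(3))) > tol)
    stop("frame(): versors not orthonormal within tolerance")
  if (.norm3(.cross3(fr$x_hat, fr$y_hat) - fr$z_hat) > tol)
    stop("frame(): versors not right-handed within tolerance")
  invisible(fr)
}

#' @export
print.rw_frame <- function(x, ...) {
  cat("<rw_frame>\n  origin (mm):", format(x$origin, digits = 6), "\n")
  cat("  x_hat:", format(x$x_hat, digits = 6), "\n")
  cat("  y_hat:", format(x$y_hat, digits = 6), "\n")
  cat("  z_hat:", format(x$z_hat, digits = 6), "\n")
  invisible(x)
}

#' The default stimulation frame at the otic capsule
#'
#' The frame of the bone-conduction excitation site used throughout the
#' package examples: origin (-45.92, 6.24, -25.28) mm in skull coordinates,
#' with the primary stimulation direction along `z_hat`.  Loaded from the
#' packaged YAML fixture and re-orthonormalized.
#'
#' @return An `rw_frame`.
#' @export
stimulation_frame <- function() {
  path <- system.file("extdata", "stimulation_frame.yaml", package = "rwdirect",
                      mustWork = TRUE)
  read_frame(path)
}

#' Read / write a frame as a YAML config block
#'
#' The block holds `origin_mm`, `x_hat`, `y_hat`, `z_hat`, each a length-3
#' list.  Versors are re-orthonormalized on load.
#'
#' @param path file path.
#' @param fr an `rw_frame` (for writing).
#' @return `read_frame` returns an `rw_frame`; `write_frame` returns `path`
#'   invisibly.
#' @export
read_frame <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("origin_mm", "x_hat", "y_hat", "z_hat")
  if (!all(need %in% names(cfg)))
    stop("frame config must contain fields: ", paste(need, collapse = ", "))
  frame(cfg$origin_mm, cfg$x_hat, cfg$y_hat, cfg$z_hat)
}

#' @rdname read_frame
#' @export
write_frame <- function(fr, path) {
  stopifnot(inherits(fr, "rw_frame"))
  yaml::write_yaml(list(origin_mm = fr$origin, x_hat = fr$x_hat,
                        y_hat = fr$y_hat, z_hat = fr$z_hat), path,
                   precision = 15L)
  invisible(path)
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues form)
#'
#' R = k k^T (1 - cos t) + I cos t + [k]_x sin t for unit axis k and angle t.
#'
#' @param axis unit length-3 vector.
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix (orthogonal, det +1).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3L, is.finite(angle_deg))
  if (abs(.norm3(axis) - 1) > 1e-9)
    stop("rotation_about_axis(): axis must be a unit vector")
  th <- angle_deg * DEG
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
  tcrossprod(axis) * (1 - cos(th)) + diag(3) * cos(th) + K * sin(th)
}

#' Force direction vector for a pair of rotation angles
#'
#' Applies the two-step parametrization: z_ab = B(beta about y_a0) %*%
#' A(alpha about x00) %*% z00.  Angles in degrees; the result has unit norm.
#' `(0, 0)` returns the primary direction `z_hat`.
#'
#' @param fr an `rw_frame`.
#' @param alpha,beta rotation angles, degrees (any finite values; the
#'   canonical sampling range is \eqn{[-90, 90]}).
#' @return unit length-3 vector in global coordinates.
#' @export
direction_vector <- function(fr, alpha, beta) {
  stopifnot(inherits(fr, "rw_frame"), is.finite(alpha), is.finite(beta))
  A <- rotation_about_axis(fr$x_hat, alpha)
  z_a0 <- as.vector(A %*% fr$z_hat)
  y_a0 <- as.vector(A %*% fr$y_hat)
  B <- rotation_about_axis(y_a0, beta)
  v <- as.vector(B %*% z_a0)
  v / .norm3(v)
}

#' Recover (alpha, beta) from a direction vector
#'
#' Inverse of [direction_vector()]: beta = arcsin(v . x00), alpha =
#' atan2(-v . y00, v . z00).  If the recovered alpha falls outside
#' \eqn{[-90, 90]} the antipodal representative `-v` is used instead (the two
#' describe the same stimulation axis up to phase).  If both or neither
#' representative qualifies, the one with `v . z_hat >= 0` is preferred.  At
#' the poles (|beta| = 90) alpha is undefined; 0 is returned with
#' `degenerate = TRUE`.
#'
#' @param fr an `rw_frame`.
#' @param v length-3 vector with unit norm (tolerance 1e-9).
#' @return list with `alpha`, `beta` (degrees) and logical `degenerate`.
#' @export
angles_from_direction <- function(fr, v) {
  v <- as.numeric(v)
  stopifnot(inherits(fr, "rw_frame"), length(v) == 3L)
  if (abs(.norm3(v) - 1) > 1e-9)
    stop("angles_from_direction(): v must be a unit vector")
  decomp <- function(u) {
    s <- max(-1, min(1, sum(u * fr$x_hat)))
    beta <- asin(s) / DEG
    alpha <- atan2(-sum(u * fr$y_hat), sum(u * fr$z_hat)) / DEG
    list(alpha = alpha, beta = beta, cz = sum(u * fr$z_hat))
  }
  a0 <- decomp(v)
  if (abs(abs(a0$beta) - 90) < 1e-7)  # gimbal pole: alpha undefined
    return(list(alpha = 0, beta = a0$beta, degenerate = TRUE))
  a1 <- a0; a2 <- decomp(-v)
  ok1 <- abs(a1$alpha) <= 90 + 1e-12
  ok2 <- abs(a2$alpha) <= 90 + 1e-12
  pick <-
    if (ok1 && !ok2) a1
    else if (ok2 && !ok1) a2
    else if (a1$cz >= a2$cz) a1
    else a2
  if (abs(abs(pick$beta) - 90) < 1e-7)
    return(list(alpha = 0, beta = pick$beta, degenerate = TRUE))
  list(alpha = pick$alpha, beta = pick$beta, degenerate = FALSE)
}

#' Angle between two vectors, degrees
#'
#' arccos of the dot product of the normalized inputs, clamped to [-1, 1].
#'
#' @param u,v nonzero length-3 vectors.
#' @return angle in degrees, in \eqn{[0, 180]}.
#' @export
angle_between <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- .norm3(u); nv <- .norm3(v)
  if (nu == 0 || nv == 0)
    stop("angle_between(): zero vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) / DEG
}

#' Cartesian grid of (alpha, beta) direction angles
#'
#' Full grid at the given step, ordered beta-major (beta varies slowest).  The
#' defaults reproduce the 15-degree sampling of \eqn{[-90, 90]^2}: 13 x 13 =
#' 169 pairs including (0, 0).
#'
#' @param step grid step, degrees; must divide `hi - lo`.
#' @param lo,hi grid bounds, degrees.
#' @return data.frame with columns `alpha_deg`, `beta_deg`.
#' @export
angle_grid <- function(step = 15, lo = -90, hi = 90) {
  stopifnot(step > 0, hi > lo)
  n <- (hi - lo) / step
  if (abs(n - round(n)) > 1e-9)
    stop("angle_grid(): step must divide (hi - lo)")
  ticks <- lo + step * seq_len(round(n) + 1L) - step
  g <- expand.grid(alpha_deg = ticks, beta_deg = ticks,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$beta_deg, g$alpha_deg), , drop = FALSE][, c("alpha_deg", "beta_deg")]
}

#' Export a direction grid with global-coordinate direction components
#'
#' @param fr an `rw_frame`.
#' @param grid data.frame from [angle_grid()].
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame with `alpha_deg`, `beta_deg`, `dx`, `dy`, `dz`.
#' @export
direction_table <- function(fr, grid = angle_grid(), path = NULL) {
  dirs <- t(mapply(function(a, b) direction_vector(fr, a, b),
                   grid$alpha_deg, grid$beta_deg))
  out <- data.frame(alpha_deg = grid$alpha_deg, beta_deg = grid$beta_deg,
                    dx = dirs[, 1L], dy = dirs[, 2L], dz = dirs[, 3L])
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Symmetry image of an angle pair
#'
#' The rotation algebra maps the pair (alpha + 180, beta + 180) onto the same
#' direction vector as (alpha, -beta); the returned `phase_sign` (+1) records
#' the sign of that vector identity as realized by [direction_vector()].
#' Response amplitudes at the image pair therefore equal those at the
#' original, and phases follow the recorded sign.
#'
#' @param alpha,beta angles in degrees, possibly outside \eqn{[-90, 90]}.
#' @return list with `alpha`, `beta` (canonical image) and `phase_sign`.
#' @export
symmetry_image <- function(alpha, beta) {
  list(alpha = alpha - 180, beta = -(beta - 180), phase_sign = 1)
}

#' Canonicalize an angle pair to the sampled square, amplitude-equivalent
#'
#' Reduces any (alpha, beta) to a representative inside \eqn{[-90, 90]^2}
#' whose direction vector is the same axis up to sign, so response
#' *amplitudes* (moduli) agree.  Used to complete refinement stencils that
#' cross the grid boundary.  Reductions: beta -> beta -/+ 180 (same axis);
#' alpha -> alpha -/+ 180 with beta -> -beta (antipodal axis).
#'
#' @param alpha,beta angles in degrees.
#' @return list with `alpha`, `beta` in \eqn{[-90, 90]}.
#' @export
wrap_angles <- function(alpha, beta) {
  for (i in 1:8) {
    if (beta > 90) beta <- beta - 180
    else if (beta < -90) beta <- beta + 180
    else break
  }
  for (i in 1:8) {
    if (alpha > 90) { alpha <- alpha - 180; beta <- -beta }
    else if (alpha < -90) { alpha <- alpha + 180; beta <- -beta }
    else break
  }
  list(alpha = alpha, beta = beta)
}
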