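# Sub-grid refinement of coarse direction-grid extremes.
#
# Around a coarse extremum at grid node (alpha, beta) the 3x3 stencil of
# criterion values at (alpha +/- step, beta +/- step) defines a biquadratic
# interpolant through the tensor product of 1-D quadratic Lagrange bases on
# nodes {-1, 0, 1}.  Its extremum over the biunit square is located by dense
# sampling followed by one Newton polish, then mapped back to degrees.

#' 1-D quadratic Lagrange basis on nodes -1, 0, 1
#'
#' @param x evaluation points in `[-1, 1]`.
#' @param deriv derivative order 0, 1 or 2.
#' @return length(x) x 3 matrix of basis values (columns: nodes -1, 0, +1).
#' @export
lagrange3_basis <- function(x, deriv = 0L) {
  x <- as.numeric(x)
  switch(as.character(deriv),
    "0" = cbind(x * (x - 1) / 2, (1 - x) * (1 + x), x * (x + 1) / 2),
    "1" = cbind(x - 0.5, -2 * x, x + 0.5),
    "2" = cbind(rep(1, length(x)), rep(-2, length(x)), rep(1, length(x))),
    stop("lagrange3_basis(): deriv must be 0, 1 or 2"))
}

#' A 3x3 refinement stencil
#'
#' @param center list or vector with the center grid angles `alpha`, `beta`
#'   (degrees).
#' @param spacing grid spacing, degrees.
#' @param values 3x3 matrix of criterion values; rows index alpha nodes
#'   (-spacing, 0, +spacing), columns index beta nodes.
#' @return list of class `rw_stencil`.
#' @export
stencil3x3 <- function(center, spacing, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == 3L, ncol(values) == 3L, all(is.finite(values)),
            spacing > 0)
  center <- as.numeric(unlist(center)[1:2])
  structure(list(center = center, spacing = spacing, values = values),
            class = "rw_stencil")
}

#' Evaluate the biquadratic interpolant of a stencil
#'
#' Tensor-product 9-node Lagrangian interpolation: v(xi, eta) =
#' sum_ij N_i(xi) N_j(eta) value_ij, exact at the 9 nodes.
#'
#' @param stencil an `rw_stencil`.
#' @param xi,eta local coordinates in `[-1, 1]` (vectors of equal length, or
#'   outer = TRUE for a tensor grid).
#' @param outer logical; when TRUE returns the length(xi) x length(eta)
#'   matrix over the tensor grid.
#' @return interpolated value(s).
#' @export
lagrange9_interpolate <- function(stencil, xi, eta, outer = FALSE) {
  stopifnot(inherits(stencil, "rw_stencil"))
  Na <- lagrange3_basis(xi)
  Nb <- lagrange3_basis(eta)
  if (outer) return(Na %*% stencil$values %*% t(Nb))
  stopifnot(length(xi) == length(eta))
  rowSums((Na %*% stencil$values) * Nb)
}

.biquad_grad_hess <- function(stencil, xi, eta) {
  V <- stencil$values
  N0a <- lagrange3_basis(xi); N1a <- lagrange3_basis(xi, 1L)
  N2a <- lagrange3_basis(xi, 2L)
  N0b <- lagrange3_basis(eta); N1b <- lagrange3_basis(eta, 1L)
  N2b <- lagrange3_basis(eta, 2L)
  g <- c(sum((N1a %*% V) * N0b), sum((N0a %*% V) * N1b))
  H <- matrix(c(sum((N2a %*% V) * N0b), sum((N1a %*% V) * N1b),
                sum((N1a %*% V) * N1b), sum((N0a %*% V) * N2b)), 2L, 2L)
  list(g = g, H = H)
}

#' Refine a coarse extremum over its 3x3 stencil
#'
#' Locates the extremum of the biquadratic interpolant over the biunit
#' square by dense sampling (step 0.005) followed by one Newton polish,
#' clamped to the square, and maps the local optimum back to degrees.  If
#' the optimum sits on the stencil boundary the result carries
#' `boundary = TRUE` (the coarse extremum was likely misidentified).
#'
#' @param stencil an `rw_stencil`.
#' @param kind `"max"` or `"min"`.
#' @param step dense sampling step in local coordinates (<= 0.005).
#' @return list with `alpha_deg`, `beta_deg`, `value`, `xi`, `eta`,
#'   `boundary`.
#' @export
refine_extremum <- function(stencil, kind = c("max", "min"), step = 0.005) {
  kind <- match.arg(kind)
  stopifnot(inherits(stencil, "rw_stencil"), step <= 0.005, step > 0)
  s <- seq(-1, 1, by = step)
  field <- lagrange9_interpolate(stencil, s, s, outer = TRUE)
  idx <- if (kind == "max") which.max(field) else which.min(field)
  ij <- arrayInd(idx, dim(field))
  xi <- s[ij[1L]]; eta <- s[ij[2L]]
  best <- field[idx]
  # Newton polish on the polynomial (few iterations; clamp to the square)
  for (it in 1:5) {
    gh <- .biquad_grad_hess(stencil, xi, eta)
    stepv <- tryCatch(-solve(gh$H, gh$g), error = function(e) NULL)
    if (is.null(stepv) || any(!is.finite(stepv))) break
    xi2 <- max(-1, min(1, xi + stepv[1L]))
    eta2 <- max(-1, min(1, eta + stepv[2L]))
    v2 <- lagrange9_interpolate(stencil, xi2, eta2)
    improved <- if (kind == "max") v2 >= best else v2 <= best
    if (!improved) break
    if (abs(xi2 - xi) < 1e-14 && abs(eta2 - eta) < 1e-14) {
      xi <- xi2; eta <- eta2; best <- v2; break
    }
    xi <- xi2; eta <- eta2; best <- v2
  }
  boundary <- max(abs(xi), abs(eta)) > 1 - 1e-6
  list(alpha_deg = stencil$center[1L] + xi * stencil$spacing,
       beta_deg = stencil$center[2L] + eta * stencil$spacing,
       value = best, xi = xi, eta = eta, boundary = boundary)
}

#' Build the refinement stencil around a grid node of a criterion map
#'
#' Gathers the 3x3 neighborhood of criterion values.  Neighbors falling
#' outside the sampled square are completed through the direction-symmetry
#' map ([wrap_angles()]), which returns an in-range angle pair with the same
#' response amplitude, so the stencil always exists.
#'
#' @param map an `rw_criterion_map` on a regular [angle_grid()].
#' @param alpha_deg,beta_deg center grid node, degrees.
#' @param spacing grid spacing, degrees (default inferred from the grid).
#' @return an `rw_stencil`.
#' @export
map_stencil <- function(map, alpha_deg, beta_deg, spacing = NULL) {
  stopifnot(inherits(map, "rw_criterion_map"))
  g <- map$grid
  if (is.null(spacing)) {
    ticks <- sort(unique(g$alpha_deg))
    spacing <- min(diff(ticks))
  }
  lookup <- function(a, b) {
    wab <- wrap_angles(a, b)
    hit <- which(abs(g$alpha_deg - wab$alpha) < 1e-9 &
                   abs(g$beta_deg - wab$beta) < 1e-9)
    if (length(hit) != 1L)
      stop(sprintf("map_stencil(): no grid node at (%g, %g) [wrapped (%g, %g)]",
                   a, b, wab$alpha, wab$beta))
    map$values[hit]
  }
  vals <- outer(c(-1, 0, 1), c(-1, 0, 1),
                Vectorize(function(da, db)
                  lookup(alpha_deg + da * spacing, beta_deg + db * spacing)))
  stencil3x3(c(alpha_deg, beta_deg), spacing, vals)
}

#' Refined extreme directions of a criterion map
#'
#' Finds the coarse grid argmax and argmin, builds each 3x3 stencil
#' (symmetry-completed at the sampling boundary) and refines both to
#' sub-grid resolution.
#'
#' @param map an `rw_criterion_map`.
#' @return data.frame with one row per kind (`max`, `min`): `alpha_deg`,
#'   `beta_deg`, `value`, `boundary`.
#' @export
refined_extremes <- function(map) {
  coarse <- coarse_extremes(map)
  out <- lapply(seq_len(nrow(coarse)), function(i) {
    st <- map_stencil(map, coarse$alpha_deg[i], coarse$beta_deg[i])
    r <- refine_extremum(st, coarse$kind[i])
    data.frame(kind = coarse$kind[i], alpha_deg = r$alpha_deg,
               beta_deg = r$beta_deg, value = r$value,
               boundary = r$boundary)
  })
  do.call(rbind, out)
}
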