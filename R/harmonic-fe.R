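# Frequency-domain linear elastodynamics on 8-node hexahedra.
#
# Hysteretic (structural) damping enters through the complex modulus
# E (1 + i eta) per material, so the assembled operator is
# K* = K + i Kd with Kd the eta-weighted stiffness.  The harmonic system
# (K* - omega^2 M) u = F is factorized densely per frequency (LAPACK
# complex LU); one factorization serves every force direction at that
# frequency through a multi-RHS solve.  Internal units are SI (m, kg, s,
# Pa, N); geometry configs accept mm and are converted on construction.

.hex8_corners <- matrix(c(
  -1, -1, -1,   1, -1, -1,   1, 1, -1,  -1, 1, -1,
  -1, -1,  1,   1, -1,  1,   1, 1,  1,  -1, 1,  1), ncol = 3L, byrow = TRUE)

.hex8_shape <- function(xi) {
  s <- .hex8_corners
  N <- (1 + xi[1L] * s[, 1L]) * (1 + xi[2L] * s[, 2L]) * (1 + xi[3L] * s[, 3L]) / 8
  dN <- rbind(
    s[, 1L] * (1 + xi[2L] * s[, 2L]) * (1 + xi[3L] * s[, 3L]),
    s[, 2L] * (1 + xi[1L] * s[, 1L]) * (1 + xi[3L] * s[, 3L]),
    s[, 3L] * (1 + xi[1L] * s[, 1L]) * (1 + xi[2L] * s[, 2L])) / 8
  list(N = N, dN = dN)  # dN: 3 x 8, rows d/dxi_i
}

.isotropic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6L, 6L)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Element stiffness and consistent mass of one hex8 element
#'
#' 2x2x2 Gauss quadrature; engineering strain ordering
#' (xx, yy, zz, xy, yz, zx).  DOFs are node-major (ux, uy, uz per node).
#'
#' @param coords 8 x 3 matrix of corner coordinates, m (standard corner
#'   ordering: bottom face counterclockwise, then top face).
#' @param E,nu,rho material Young's modulus (Pa), Poisson ratio, density
#'   (kg/m^3).
#' @return list with `K` (24 x 24), `M` (24 x 24), `volume` (m^3).
#' @export
hex8_element <- function(coords, E, nu, rho) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 8L, ncol(coords) == 3L)
  gp <- 1 / sqrt(3)
  D <- .isotropic_D(E, nu)
  K <- matrix(0, 24L, 24L)
  M <- matrix(0, 24L, 24L)
  vol <- 0
  ia <- 3L * (1:8) - 2L
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    sh <- .hex8_shape(c(gx, gy, gz))
    J <- sh$dN %*% coords
    detJ <- det(J)
    if (detJ <= 0) stop("hex8_element(): non-positive Jacobian")
    g <- solve(J, sh$dN)  # 3 x 8, global gradients
    B <- matrix(0, 6L, 24L)
    B[1L, ia] <- g[1L, ]; B[2L, ia + 1L] <- g[2L, ]; B[3L, ia + 2L] <- g[3L, ]
    B[4L, ia] <- g[2L, ]; B[4L, ia + 1L] <- g[1L, ]
    B[5L, ia + 1L] <- g[3L, ]; B[5L, ia + 2L] <- g[2L, ]
    B[6L, ia] <- g[3L, ]; B[6L, ia + 2L] <- g[1L, ]
    K <- K + crossprod(B, D %*% B) * detJ
    NN <- tcrossprod(sh$N) * (rho * detJ)
    for (d in 0:2) M[ia + d, ia + d] <- M[ia + d, ia + d] + NN
    vol <- vol + detJ
  }
  list(K = K, M = M, volume = vol)
}

#' Construct a finite-element model
#'
#' @param nodes n x 3 node coordinates, m.
#' @param elems m x 8 integer matrix of hex8 connectivities.
#' @param elem_material character vector (length m) of material names.
#' @param materials named list; each entry a list with `E` (Pa), `nu`,
#'   `rho` (kg/m^3), `eta` (hysteretic loss factor).
#' @param fixed_nodes integer node indices with all DOFs fixed (non-empty).
#' @param attachment list with `mass_kg` and `nodes` (integer indices of the
#'   attachment circle); the concentrated implant mass and the force are
#'   both split equally over these nodes.
#' @param surface_mass optional list with `quads` (q x 4 node indices on the
#'   boundary) and `density` (kg/m^2), lumped to the quad nodes.
#' @param node_sets named list of integer node-index vectors.
#' @param rw optional round-window post-processing block (see
#'   [make_toy_bone()]).
#' @return list of class `fe_model`.
#' @export
fe_model <- function(nodes, elems, elem_material, materials, fixed_nodes,
                     attachment = NULL, surface_mass = NULL,
                     node_sets = list(), rw = NULL) {
  nodes <- as.matrix(nodes); elems <- as.matrix(elems)
  stopifnot(ncol(nodes) == 3L, ncol(elems) == 8L,
            length(elem_material) == nrow(elems),
            all(elem_material %in% names(materials)))
  if (length(fixed_nodes) == 0L)
    stop("fe_model(): fixed node set must be non-empty")
  used <- sort(unique(as.vector(elems)))
  if (!identical(used, seq_len(nrow(nodes))))
    stop("fe_model(): orphan nodes present (",
         nrow(nodes) - length(used), " unused)")
  if (!is.null(attachment) && length(attachment$nodes) == 0L)
    stop("fe_model(): attachment node set must be non-empty")
  structure(list(nodes = nodes, elems = elems,
                 elem_material = elem_material, materials = materials,
                 fixed_nodes = as.integer(fixed_nodes),
                 attachment = attachment, surface_mass = surface_mass,
                 node_sets = node_sets, rw = rw),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat("<fe_model> ", nrow(x$nodes), "nodes,", nrow(x$elems), "hex8 elements,",
      length(x$fixed_nodes), "fixed nodes\n")
  cat("  materials:", paste(names(x$materials), collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

.quad_area3d <- function(p) {
  # area of a (possibly warped) quad from its two triangles
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  a1 <- 0.5 * sqrt(sum(cr(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
  a2 <- 0.5 * sqrt(sum(cr(p[3, ] - p[1, ], p[4, ] - p[1, ])^2))
  a1 + a2
}

#' Assemble the global harmonic operators
#'
#' Returns the real stiffness `K`, the loss-factor-weighted stiffness `Kd`
#' (so K* = K + i Kd), and the mass `M` including consistent element mass,
#' lumped surface mass and the lumped attachment mass.  All three are dense
#' symmetric matrices over every DOF; `free` indexes the unconstrained DOFs.
#'
#' @param model an `fe_model`.
#' @return list of class `fe_assembly` with `K`, `Kd`, `M`, `free`, `ndof`.
#' @export
assemble <- function(model) {
  stopifnot(inherits(model, "fe_model"))
  n <- nrow(model$nodes)
  ndof <- 3L * n
  nel <- nrow(model$elems)
  # triplet accumulation (duplicate entries sum), then densify once
  ii <- vector("list", nel); jj <- vector("list", nel)
  kk <- vector("list", nel); kd <- vector("list", nel)
  mm <- vector("list", nel)
  for (e in seq_len(nel)) {
    conn <- model$elems[e, ]
    mat <- model$materials[[model$elem_material[e]]]
    el <- tryCatch(
      hex8_element(model$nodes[conn, , drop = FALSE], mat$E, mat$nu, mat$rho),
      error = function(err)
        stop("assemble(): element ", e, ": ", conditionMessage(err)))
    dofs <- as.vector(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    ii[[e]] <- rep(dofs, times = 24L)
    jj[[e]] <- rep(dofs, each = 24L)
    kk[[e]] <- as.vector(el$K)
    kd[[e]] <- as.vector(el$K) * mat$eta
    mm[[e]] <- as.vector(el$M)
  }
  i <- unlist(ii); j <- unlist(jj)
  dense <- function(x) as.matrix(Matrix::sparseMatrix(
    i = i, j = j, x = x, dims = c(ndof, ndof)))
  K <- dense(unlist(kk))
  Kd <- dense(unlist(kd))
  M <- dense(unlist(mm))
  mdiag <- numeric(ndof)
  if (!is.null(model$surface_mass)) {
    sq <- as.matrix(model$surface_mass$quads)
    for (q in seq_len(nrow(sq))) {
      a <- .quad_area3d(model$nodes[sq[q, ], , drop = FALSE])
      add <- a * model$surface_mass$density / 4
      for (nd in sq[q, ])
        mdiag[3L * nd - c(2L, 1L, 0L)] <- mdiag[3L * nd - c(2L, 1L, 0L)] + add
    }
  }
  if (!is.null(model$attachment)) {
    per <- model$attachment$mass_kg / length(model$attachment$nodes)
    for (nd in model$attachment$nodes)
      mdiag[3L * nd - c(2L, 1L, 0L)] <- mdiag[3L * nd - c(2L, 1L, 0L)] + per
  }
  diag(M) <- diag(M) + mdiag
  fixed_dofs <- as.vector(rbind(3L * model$fixed_nodes - 2L,
                                3L * model$fixed_nodes - 1L,
                                3L * model$fixed_nodes))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  structure(list(K = K, Kd = Kd, M = M, free = free, ndof = ndof),
            class = "fe_assembly")
}

.load_vector <- function(model, amplitude, direction) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("harmonic load: direction must be a unit vector")
  if (amplitude <= 0) stop("harmonic load: amplitude must be positive")
  F <- numeric(3L * nrow(model$nodes))
  nodes <- model$attachment$nodes
  per <- amplitude / length(nodes)
  for (nd in nodes)
    F[3L * nd - c(2L, 1L, 0L)] <- F[3L * nd - c(2L, 1L, 0L)] + per * direction
  F
}

#' Solve the harmonic response for one load
#'
#' Solves (K + i Kd - omega^2 M) u = F on the free DOFs, with the force
#' amplitude split equally over the attachment nodes along the load
#' direction.  At f = 0 with eta = 0 this is the static solution.
#'
#' @param model an `fe_model`.
#' @param asm its [assemble()] result.
#' @param amplitude force amplitude, N.
#' @param direction unit length-3 force direction (global coordinates).
#' @param frequency frequency, Hz (>= 0).
#' @return complex n x 3 matrix of nodal displacements, m (zero rows at
#'   fixed nodes).
#' @export
solve_harmonic <- function(model, asm, amplitude, direction, frequency) {
  stopifnot(inherits(asm, "fe_assembly"), frequency >= 0)
  w2 <- (2 * pi * frequency)^2
  A <- (asm$K[asm$free, asm$free] - w2 * asm$M[asm$free, asm$free]) +
    1i * asm$Kd[asm$free, asm$free]
  F <- .load_vector(model, amplitude, direction)[asm$free]
  u_free <- tryCatch(solve(A, F), error = function(e)
    stop("solve_harmonic(): singular system at ", frequency, " Hz: ",
         conditionMessage(e)))
  u <- complex(real = numeric(asm$ndof), imaginary = numeric(asm$ndof))
  u[asm$free] <- u_free
  matrix(u, ncol = 3L, byrow = TRUE)
}

#' Sweep directions and frequencies
#'
#' One factorization per frequency; all force directions solved together as
#' multiple right-hand sides.  Deterministic given the model and inputs.
#'
#' @param model an `fe_model`.
#' @param directions k x 3 matrix of unit force directions.
#' @param frequencies numeric frequencies, Hz.
#' @param amplitude force amplitude, N (default 0.1).
#' @param asm optional precomputed [assemble()] result.
#' @return list of class `fe_sweep`: `fields[[f]][[d]]` complex n x 3
#'   displacement matrices (m), plus `directions`, `frequencies`,
#'   `amplitude`.
#' @export
sweep_harmonic <- function(model, directions, frequencies, amplitude = 0.1,
                           asm = NULL) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L)
  if (is.null(asm)) asm <- assemble(model)
  Fmat <- vapply(seq_len(nrow(directions)), function(d)
    .load_vector(model, amplitude, directions[d, ])[asm$free],
    numeric(length(asm$free)))
  Kf <- asm$K[asm$free, asm$free]
  Kdf <- asm$Kd[asm$free, asm$free]
  Mf <- asm$M[asm$free, asm$free]
  fields <- lapply(frequencies, function(f) {
    A <- (Kf - (2 * pi * f)^2 * Mf) + 1i * Kdf
    U <- solve(A, Fmat)
    lapply(seq_len(ncol(U)), function(d) {
      u <- complex(real = numeric(asm$ndof), imaginary = numeric(asm$ndof))
      u[asm$free] <- U[, d]
      matrix(u, ncol = 3L, byrow = TRUE)
    })
  })
  structure(list(fields = fields, directions = directions,
                 frequencies = frequencies, amplitude = amplitude),
            class = "fe_sweep")
}

#' Regular hexahedral grid over a box
#'
#' @param dims length-3 box dimensions, m.
#' @param n length-3 cell counts per axis.
#' @return list with `nodes` ((nx+1)(ny+1)(nz+1) x 3), `elems` (prod(n) x 8),
#'   `cell_index` (prod(n) x 3 integer cell coordinates, 1-based) and
#'   `node_id(ix, iy, iz)` helper.
#' @export
hex_grid <- function(dims, n) {
  n <- as.integer(n)
  stopifnot(length(dims) == 3L, length(n) == 3L, all(n >= 1L), all(dims > 0))
  nx <- n[1L]; ny <- n[2L]; nz <- n[3L]
  xs <- seq(0, dims[1L], length.out = nx + 1L)
  ys <- seq(0, dims[2L], length.out = ny + 1L)
  zs <- seq(0, dims[3L], length.out = nz + 1L)
  nid <- function(ix, iy, iz)
    (iz - 1L) * (nx + 1L) * (ny + 1L) + (iy - 1L) * (nx + 1L) + ix
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz),
                       KEEP.OUT.ATTRS = FALSE)
  elems <- t(apply(cells, 1L, function(c3) {
    ix <- c3[[1L]]; iy <- c3[[2L]]; iz <- c3[[3L]]
    c(nid(ix, iy, iz), nid(ix + 1L, iy, iz), nid(ix + 1L, iy + 1L, iz),
      nid(ix, iy + 1L, iz), nid(ix, iy, iz + 1L), nid(ix + 1L, iy, iz + 1L),
      nid(ix + 1L, iy + 1L, iz + 1L), nid(ix, iy + 1L, iz + 1L))
  }))
  list(nodes = nodes, elems = elems, cell_index = as.matrix(cells),
       node_id = nid)
}
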