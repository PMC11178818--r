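# Synthetic fixtures: round-window geometries, harmonic fields with planted
# rigid-body and deflection ground truth, direction-dependent response
# surfaces with a planted extremum, and the toy temporal-bone FE model.
# Every generator is a pure function of (config, seed).

#' Circular edge ring plus quasi-circular membrane quad mesh
#'
#' The edge ring is a circle of `n_edge` nodes at `radius`.  The membrane is
#' a structured patch: the `n_quads` square cells of a regular grid whose
#' centers lie nearest the origin, forming a quasi-circular disc of
#' comparable radius; any quad count is achievable exactly.  Both parts are
#' expressed in the round-window frame (origin at the ring center, z toward
#' the cochlea) and wound counterclockwise viewed from +z.
#'
#' @param n_edge edge node count, divisible by 3 (canonical 48).
#' @param n_quads membrane quad count (canonical 218).
#' @param radius ring radius, mm.
#' @param jitter relative angular jitter of ring nodes (0 = regular polygon).
#' @param seed RNG seed controlling the jitter.
#' @return list with `ring` (an [build_ring()] result) and `membrane`
#'   (a [membrane_mesh()]).
#' @export
make_rw_fixture <- function(n_edge = 48L, n_quads = 218L, radius = 1.5,
                            jitter = 0, seed = 1L) {
  stopifnot(n_edge %% 3L == 0L, n_edge >= 6L, n_quads >= 1L, radius > 0)
  th <- 2 * pi * (seq_len(n_edge) - 1L) / n_edge
  if (jitter > 0) {
    set.seed(seed)
    th <- th + stats::runif(n_edge, -jitter, jitter) * 2 * pi / n_edge
  }
  ring <- build_ring(radius * cbind(cos(th), sin(th)))

  # membrane: m x m cell grid, keep the n_quads cells with centers nearest 0
  m <- max(3L, ceiling(2 * sqrt(n_quads / pi)) + 2L)
  h <- 2 * radius / (2 * sqrt(n_quads / pi))  # cell size -> blob radius ~ radius
  half <- m * h / 2
  cells <- expand.grid(ix = seq_len(m), iy = seq_len(m),
                       KEEP.OUT.ATTRS = FALSE)
  cx <- (cells$ix - 0.5) * h - half
  cy <- (cells$iy - 0.5) * h - half
  ord <- order(cx^2 + cy^2, cells$ix, cells$iy)
  if (n_quads > nrow(cells))
    stop("make_rw_fixture(): n_quads too large for the disc template")
  keep <- cells[ord[seq_len(n_quads)], , drop = FALSE]
  nid_key <- function(ix, iy) paste(ix, iy)
  corner_ix <- c(0L, 1L, 1L, 0L); corner_iy <- c(0L, 0L, 1L, 1L)
  keys <- unlist(lapply(seq_len(n_quads), function(q)
    nid_key(keep$ix[q] + corner_ix, keep$iy[q] + corner_iy)))
  uniq <- unique(keys)
  node_of <- match(keys, uniq)
  quads <- matrix(node_of, ncol = 4L, byrow = TRUE)
  parts <- do.call(rbind, strsplit(uniq, " "))
  nx <- as.integer(parts[, 1L]); ny <- as.integer(parts[, 2L])
  nodes <- cbind((nx - 1L) * h - half, (ny - 1L) * h - half)
  membrane <- membrane_mesh(nodes, quads)
  list(ring = ring, membrane = membrane)
}

#' Planted ground truth for a synthetic harmonic field
#'
#' @param w,gamma,phi complex rigid translation (mm) and rotations (rad).
#' @param profile membrane deflection profile: `"piston"`, `"paraboloid"`,
#'   `"mode"` or `"none"`.
#' @param d complex deflection amplitude, mm.
#' @param mode_m angular wavenumber for `profile = "mode"`.
#' @param sigma additive complex gaussian noise sd per channel, mm.
#' @param seed RNG seed for the noise.
#' @return list of class `rw_truth`; `expected_V` is populated when the
#'   profile has a closed form (piston: `A_total * d`; none: 0).
#' @export
field_truth <- function(w = 0, gamma = 0, phi = 0,
                        profile = c("piston", "paraboloid", "mode", "none"),
                        d = 0, mode_m = 2L, sigma = 0, seed = 1L) {
  profile <- match.arg(profile)
  structure(list(w = as.complex(w), gamma = as.complex(gamma),
                 phi = as.complex(phi), profile = profile, d = as.complex(d),
                 mode_m = as.integer(mode_m), sigma = sigma,
                 seed = as.integer(seed)),
            class = "rw_truth")
}

.profile_values <- function(profile, xy, mode_m) {
  r2 <- rowSums(xy^2)
  R2 <- max(r2)
  switch(profile,
         piston = rep(1, nrow(xy)),
         paraboloid = 1 - r2 / R2,
         mode = (1 - r2 / R2) * cos(mode_m * atan2(xy[, 2L], xy[, 1L])),
         none = rep(0, nrow(xy)),
         stop("unknown membrane profile: ", profile))
}

#' Synthetic harmonic field over ring and membrane nodes
#'
#' Ring nodes carry exactly the planted rigid z-field w + gamma y - phi x;
#' membrane nodes carry the rigid field plus `profile * d` plus complex
#' gaussian noise (independent real/imaginary channels, sd `sigma`).
#'
#' @param fixture result of [make_rw_fixture()].
#' @param truth an [field_truth()].
#' @return list with complex `ring_wz`, `membrane_wz` (mm), the `truth`, and
#'   `expected_V` (complex mm^3 or NA when no closed form exists).
#' @export
make_field <- function(fixture, truth) {
  stopifnot(inherits(truth, "rw_truth"))
  rigid <- structure(list(w = truth$w, gamma = truth$gamma, phi = truth$phi),
                     class = "rw_ring_motion")
  ring_wz <- rigid_field(rigid, fixture$ring$xy)
  mem_xy <- fixture$membrane$nodes
  prof <- .profile_values(truth$profile, mem_xy, truth$mode_m)
  membrane_wz <- rigid_field(rigid, mem_xy) + prof * truth$d
  if (truth$sigma > 0) {
    set.seed(truth$seed)
    nmem <- nrow(mem_xy)
    membrane_wz <- membrane_wz +
      complex(real = stats::rnorm(nmem, 0, truth$sigma),
              imaginary = stats::rnorm(nmem, 0, truth$sigma))
  }
  expected_V <- switch(truth$profile,
                       piston = fixture$membrane$area_total * truth$d,
                       none = as.complex(0),
                       NA_complex_)
  list(ring_wz = ring_wz, membrane_wz = membrane_wz, truth = truth,
       expected_V = expected_V)
}

#' A response surface with a planted extremum direction
#'
#' Generator rule: amplitude(alpha, beta, f) = c(f) * (floor +
#' max(0, z_ab . d_star)^sharpness), optionally with multiplicative
#' log-normal noise.  The continuum argmax is the planted direction for any
#' floor >= 0 and sharpness > 0.
#'
#' @param fr an `rw_frame` used to evaluate direction vectors.
#' @param grid data.frame from [angle_grid()].
#' @param frequencies frequency set, Hz.
#' @param d_star planted unit direction (global coordinates).
#' @param scale per-frequency positive scale c(f) (recycled).
#' @param sharpness exponent p > 0.
#' @param floor additive floor >= 0.
#' @param noise_sd sd of multiplicative log-normal noise (0 = none).
#' @param seed RNG seed.
#' @return an `rw_surface`.
#' @export
make_surface <- function(fr, grid, frequencies, d_star,
                         scale = 1, sharpness = 2, floor = 0.05,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(fr, "rw_frame"), sharpness > 0, floor >= 0)
  d_star <- as.numeric(d_star)
  d_star <- d_star / sqrt(sum(d_star^2))
  scale <- rep_len(scale, length(frequencies))
  stopifnot(all(scale > 0))
  dirs <- t(mapply(function(a, b) direction_vector(fr, a, b),
                   grid$alpha_deg, grid$beta_deg))
  base <- floor + pmax(0, dirs %*% d_star)^sharpness
  amps <- outer(as.vector(base), scale)
  if (noise_sd > 0) {
    set.seed(seed)
    amps <- amps * exp(matrix(stats::rnorm(length(amps), 0, noise_sd),
                              nrow(amps), ncol(amps)))
  }
  response_surface(grid, frequencies, amps)
}

#' Default configuration of the toy temporal-bone model
#'
#' A bone block with an interior fluid cavity; a soft membrane column spans
#' the cavity wall on the z-min side so the window membrane can bulge toward
#' the free outer surface; the opposite outer face carries the stimulation
#' patch (implant attachment circle), and one lateral face is fixed where
#' the bone would connect to the rest of the skull.  Dimensions in mm,
#' materials in SI.
#'
#' @return named list of configuration values.
#' @export
toy_bone_config <- function() {
  list(
    dims_mm = c(20, 20, 20),
    n_cells = c(8L, 8L, 8L),
    cavity_cells = list(x = 4:6, y = 4:6, z = 4:6),
    window_cells = list(x = 4:6, y = 4:6, z = 1:3),
    fixed_face = "xmin",
    attach_face = "xmax",
    attachment_mass_g = 0.16,
    attachment_radius_mm = 1.5,
    surface_density_g_mm2 = 2.5e-3,
    force_N = 0.1,
    materials = list(
      bone = list(E = 1.4e10, nu = 0.30, rho = 1900, eta = 0.05),
      fluid = list(E = 1.32e7, nu = 0.499, rho = 1000, eta = 0.05),
      membrane = list(E = 3.5e6, nu = 0.45, rho = 1200, eta = 0.10)))
}

#' Build the toy temporal-bone FE model
#'
#' Structured hex mesh of the configured block with fluid cavity, membrane
#' window column, fixed boundary face, outer-surface added mass, attachment
#' circle with concentrated implant mass, and named node sets `rw_edge`,
#' `rw_membrane`, `stimulation_patch`.  The round-window post-processing
#' block (`$rw`) holds local in-plane coordinates (mm) of the edge ring and
#' membrane interface nodes plus the membrane interface quads.
#'
#' @param config list from [toy_bone_config()] (possibly modified).
#' @param seed unused placeholder for generator-interface uniformity
#'   (geometry is deterministic).
#' @return an `fe_model`.
#' @export
make_toy_bone <- function(config = toy_bone_config(), seed = 1L) {
  dims <- config$dims_mm / 1000
  n <- as.integer(config$n_cells)
  g <- hex_grid(dims, n)
  ci <- g$cell_index
  in_block <- function(ix, iy, iz, blk)
    ix %in% blk$x & iy %in% blk$y & iz %in% blk$z
  cav <- config$cavity_cells; win <- config$window_cells
  if (any(cav$x <= 1L) || any(cav$x >= n[1L]) || any(cav$y <= 1L) ||
      any(cav$y >= n[2L]) || any(cav$z <= 1L) || any(cav$z >= n[3L]))
    stop("make_toy_bone(): cavity must be strictly interior")
  if (!setequal(win$x, cav$x) || !setequal(win$y, cav$y) ||
      max(win$z) + 1L != min(cav$z) || min(win$z) != 1L)
    stop("make_toy_bone(): window column must span the wall under the cavity")
  mat <- rep("bone", nrow(ci))
  mat[in_block(ci[, 1L], ci[, 2L], ci[, 3L], cav)] <- "fluid"
  mat[in_block(ci[, 1L], ci[, 2L], ci[, 3L], win)] <- "membrane"

  nx <- n[1L]; ny <- n[2L]; nz <- n[3L]
  nid <- g$node_id
  face_nodes <- function(face) {
    tol <- 1e-12
    which(switch(face,
      xmin = abs(g$nodes[, 1L]) < tol,
      xmax = abs(g$nodes[, 1L] - dims[1L]) < tol,
      ymin = abs(g$nodes[, 2L]) < tol,
      ymax = abs(g$nodes[, 2L] - dims[2L]) < tol,
      zmin = abs(g$nodes[, 3L]) < tol,
      zmax = abs(g$nodes[, 3L] - dims[3L]) < tol,
      stop("unsupported face: ", face)))
  }
  fixed <- face_nodes(config$fixed_face)

  # attachment circle on the attach face
  att_nodes_all <- face_nodes(config$attach_face)
  att_center <- c(if (config$attach_face == "xmax") dims[1L] else 0,
                  dims[2L] / 2, dims[3L] / 2)
  d2 <- rowSums((g$nodes[att_nodes_all, , drop = FALSE] -
                   matrix(att_center, length(att_nodes_all), 3L,
                          byrow = TRUE))^2)
  att <- att_nodes_all[d2 <= (config$attachment_radius_mm / 1000)^2 + 1e-15]
  if (length(att) == 0L) att <- att_nodes_all[which.min(d2)]

  # outer surface quads (all six faces) carry the soft-tissue surface mass
  sq <- list()
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) {
    sq[[length(sq) + 1L]] <- c(nid(1L, iy, iz), nid(1L, iy, iz + 1L),
                               nid(1L, iy + 1L, iz + 1L), nid(1L, iy + 1L, iz))
    sq[[length(sq) + 1L]] <- c(nid(nx + 1L, iy, iz), nid(nx + 1L, iy + 1L, iz),
                               nid(nx + 1L, iy + 1L, iz + 1L),
                               nid(nx + 1L, iy, iz + 1L))
  }
  for (iz in seq_len(nz)) for (ix in seq_len(nx)) {
    sq[[length(sq) + 1L]] <- c(nid(ix, 1L, iz), nid(ix + 1L, 1L, iz),
                               nid(ix + 1L, 1L, iz + 1L), nid(ix, 1L, iz + 1L))
    sq[[length(sq) + 1L]] <- c(nid(ix, ny + 1L, iz), nid(ix, ny + 1L, iz + 1L),
                               nid(ix + 1L, ny + 1L, iz + 1L),
                               nid(ix + 1L, ny + 1L, iz))
  }
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    sq[[length(sq) + 1L]] <- c(nid(ix, iy, 1L), nid(ix, iy + 1L, 1L),
                               nid(ix + 1L, iy + 1L, 1L), nid(ix + 1L, iy, 1L))
    sq[[length(sq) + 1L]] <- c(nid(ix, iy, nz + 1L), nid(ix + 1L, iy, nz + 1L),
                               nid(ix + 1L, iy + 1L, nz + 1L),
                               nid(ix, iy + 1L, nz + 1L))
  }
  surface_mass <- list(quads = do.call(rbind, sq),
                       density = config$surface_density_g_mm2 * 1e-3 / 1e-6)

  # round-window interface: membrane-column top plane (touching the fluid)
  izp <- max(win$z) + 1L  # node plane index
  patch_ix <- c(min(win$x), max(win$x) + 1L)
  mem_nodes <- as.vector(outer(seq(patch_ix[1L], patch_ix[2L]),
                               seq(min(win$y), max(win$y) + 1L),
                               function(ix, iy) nid(ix, iy, izp)))
  mem_xyz <- g$nodes[mem_nodes, , drop = FALSE]
  rw_origin <- colMeans(mem_xyz)
  loc <- function(ids) {
    p <- g$nodes[ids, , drop = FALSE]
    cbind((p[, 1L] - rw_origin[1L]) * 1000, (p[, 2L] - rw_origin[2L]) * 1000)
  }
  mem_xy <- loc(mem_nodes)
  edge_mask <- abs(abs(mem_xy[, 1L]) - max(abs(mem_xy[, 1L]))) < 1e-9 |
    abs(abs(mem_xy[, 2L]) - max(abs(mem_xy[, 2L]))) < 1e-9
  edge_nodes <- mem_nodes[edge_mask]
  # membrane interface quads in local node numbering, CCW viewed from +z
  wn <- length(win$x); hn <- length(win$y)
  lid <- function(ix, iy) (iy - 1L) * (wn + 1L) + ix
  mq <- list()
  for (iy in seq_len(hn)) for (ix in seq_len(wn))
    mq[[length(mq) + 1L]] <- c(lid(ix, iy), lid(ix + 1L, iy),
                               lid(ix + 1L, iy + 1L), lid(ix, iy + 1L))
  rw <- list(origin_m = rw_origin,
             z_hat = c(0, 0, 1),  # toward the fluid cavity ("cochlea")
             edge_ids = edge_nodes, edge_xy_mm = loc(edge_nodes),
             membrane_ids = mem_nodes, membrane_xy_mm = mem_xy,
             membrane_quads = do.call(rbind, mq))

  fe_model(g$nodes, g$elems, mat, config$materials, fixed_nodes = fixed,
           attachment = list(mass_kg = config$attachment_mass_g * 1e-3,
                             nodes = att),
           surface_mass = surface_mass,
           node_sets = list(rw_edge = edge_nodes, rw_membrane = mem_nodes,
                            stimulation_patch = att),
           rw = rw)
}

#' Stable hash of any R object (for fixture golden hashes)
#'
#' Serializes the object (version 2, no header diffs) to a temp file and
#' returns its MD5.
#'
#' @param x any serializable R object.
#' @return character MD5 hash.
#' @export
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
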