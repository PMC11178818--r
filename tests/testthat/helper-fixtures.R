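# Shared fixtures and independent oracles used across the test files.

# --- quaternion rotation oracle (independent of the Rodrigues matrix path) ---
quat_rotate <- function(axis, angle_deg, v) {
  th <- angle_deg * pi / 360  # half angle, radians
  q <- c(cos(th), sin(th) * axis)  # (w, x, y, z)
  qmul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
  qc <- c(q[1], -q[2:4])
  qmul(qmul(q, c(0, v)), qc)[2:4]
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_complex <- function(n, scale = 1) {
  complex(real = stats::rnorm(n, 0, scale),
          imaginary = stats::rnorm(n, 0, scale))
}

# --- subdivision integration oracle for the volume displacement ---
# Integrates the linear interpolant of dw over each triangle after `levels`
# rounds of midpoint 4-way subdivision; identical to the one-shot rule for
# linear fields, and an independent code path for arbitrary nodal values.
subdivide_integral <- function(coords, values, levels = 2L) {
  tri_int <- function(p, v, lev) {
    if (lev == 0L) {
      a <- 0.5 * (p[1, 1] * p[2, 2] + p[2, 1] * p[3, 2] + p[3, 1] * p[1, 2] -
                    p[1, 1] * p[3, 2] - p[2, 1] * p[1, 2] - p[3, 1] * p[2, 2])
      return(a / 3 * sum(v))
    }
    m12 <- (p[1, ] + p[2, ]) / 2; m23 <- (p[2, ] + p[3, ]) / 2
    m13 <- (p[1, ] + p[3, ]) / 2
    v12 <- (v[1] + v[2]) / 2; v23 <- (v[2] + v[3]) / 2; v13 <- (v[1] + v[3]) / 2
    tri_int(rbind(p[1, ], m12, m13), c(v[1], v12, v13), lev - 1L) +
      tri_int(rbind(m12, p[2, ], m23), c(v12, v[2], v23), lev - 1L) +
      tri_int(rbind(m13, m23, p[3, ]), c(v13, v23, v[3]), lev - 1L) +
      tri_int(rbind(m12, m23, m13), c(v12, v23, v13), lev - 1L)
  }
  tri_int(coords, values, levels)
}

oracle_vd <- function(mesh, field, ring, levels = 2L) {
  dw <- relative_displacement(mesh$nodes, field, ring)
  tot <- 0 + 0i
  for (t in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[t, ]
    tot <- tot + subdivide_integral(mesh$nodes[tri, , drop = FALSE],
                                    dw[tri], levels)
  }
  unname(tot)
}

# --- cached toy-bone model (assembly is the slow step; share across files) ---
.toy_cache <- new.env(parent = emptyenv())
get_toy_model <- function() {
  if (is.null(.toy_cache$model)) .toy_cache$model <- make_toy_bone()
  .toy_cache$model
}
get_toy_assembly <- function() {
  if (is.null(.toy_cache$asm)) .toy_cache$asm <- assemble(get_toy_model())
  .toy_cache$asm
}

# --- minimal field container writer for hand-built synthetic containers ---
write_test_container <- function(dir, ring, membrane, directions, freqs,
                                 field_fun) {
  # field_fun(d, f) -> list(ring_wz, membrane_wz), in the *raw* (unsorted)
  # node order written to the CSVs below
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs_df <- data.frame(dir_id = seq_len(nrow(directions)),
                        alpha_deg = directions$alpha_deg,
                        beta_deg = directions$beta_deg,
                        dx = NA_real_, dy = NA_real_, dz = NA_real_)
  utils::write.csv(dirs_df, file.path(dir, "directions.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(freq_id = seq_along(freqs), freq_hz = freqs),
                   file.path(dir, "frequencies.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node_id = ring$node_ids,
                              x_mm = ring$xy[, 1], y_mm = ring$xy[, 2]),
                   file.path(dir, "ring_nodes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node_id = seq_len(nrow(membrane$nodes)),
                              x_mm = membrane$nodes[, 1],
                              y_mm = membrane$nodes[, 2]),
                   file.path(dir, "membrane_nodes.csv"), row.names = FALSE)
  q <- as.data.frame(membrane$quads)
  names(q) <- c("A", "B", "C", "D")
  utils::write.csv(q, file.path(dir, "membrane_quads.csv"),
                   row.names = FALSE)
  rows <- list()
  for (f in seq_along(freqs)) for (d in seq_len(nrow(directions))) {
    fl <- field_fun(d, f)
    rows[[length(rows) + 1L]] <- data.frame(
      dir_id = d, freq_id = f,
      set = rep(c("rw_edge", "rw_membrane"),
                c(length(fl$ring_wz), length(fl$membrane_wz))),
      node_row = c(seq_along(fl$ring_wz), seq_along(fl$membrane_wz)),
      re_mm = c(Re(fl$ring_wz), Re(fl$membrane_wz)),
      im_mm = c(Im(fl$ring_wz), Im(fl$membrane_wz)))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "fields.csv"),
                   row.names = FALSE)
  dir
}
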