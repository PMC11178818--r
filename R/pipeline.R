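# Reproducible pipeline stages: simulate (toy FE sweep -> field container),
# analyze (container -> per-direction, per-frequency ring motion and volume
# displacement tables), criteria (tables -> weighted criterion maps and
# refined extreme directions).
#
# The field container is a directory of plain CSV files plus a
# manifest.json carrying the config hash, seed and package version, so
# reruns are verifiable and results survive as text.

.run_config_keys <- c("frame", "frequencies", "grid", "force_N", "model",
                      "seed")

#' Validate a run configuration
#'
#' Checks the schema before any computation: unknown keys are rejected,
#' required model fields (fixed face, materials, attachment) must be
#' present, the grid spec must be divisible, frequencies positive and
#' increasing.
#'
#' @param config list with optional fields `frame` (origin_mm/x_hat/y_hat/
#'   z_hat block), `frequencies`, `grid` (step, lo, hi), `force_N`, `model`
#'   (overrides of [toy_bone_config()]), `seed`.
#' @return the completed configuration (defaults filled in), invisibly
#'   classed `rw_run_config`.
#' @export
validate_run_config <- function(config = list()) {
  unknown <- setdiff(names(config), .run_config_keys)
  if (length(unknown))
    stop("run config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    frame = config$frame,
    frequencies = config$frequencies %||% third_octave_frequencies(),
    grid = utils::modifyList(list(step = 15, lo = -90, hi = 90),
                             config$grid %||% list()),
    force_N = config$force_N %||% 0.1,
    model = utils::modifyList(toy_bone_config(), config$model %||% list()),
    seed = config$seed %||% 1L)
  if (any(cfg$frequencies <= 0) || any(diff(cfg$frequencies) <= 0))
    stop("run config: frequencies must be positive and strictly increasing")
  if (cfg$force_N <= 0) stop("run config: force_N must be positive")
  n <- (cfg$grid$hi - cfg$grid$lo) / cfg$grid$step
  if (abs(n - round(n)) > 1e-9)
    stop("run config: grid step must divide (hi - lo)")
  for (key in c("fixed_face", "materials", "attachment_mass_g",
                "attachment_radius_mm"))
    if (is.null(cfg$model[[key]]))
      stop("run config: model is missing required field '", key, "'")
  class(cfg) <- "rw_run_config"
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  object_hash(unclass(cfg))
}

.toy_frame <- function(model, config) {
  att_center <- colMeans(model$nodes[model$attachment$nodes, , drop = FALSE])
  # primary direction points into the bone (toward the otic capsule)
  frame(origin = att_center * 1000, x_hat = c(0, 0, 1), y_hat = c(0, 1, 0),
        z_hat = c(-1, 0, 0))
}

#' Run the harmonic sweep and write the field container
#'
#' Builds the toy bone model from the configuration, sweeps every grid
#' direction at every frequency, projects the response onto the
#' round-window z-axis for the edge-ring and membrane node sets, and writes
#' the container directory (CSV files + manifest.json).
#'
#' @param config run configuration (see [validate_run_config()]).
#' @param out_dir container directory (created).
#' @return the container directory path, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir) {
  cfg <- validate_run_config(config)
  model <- make_toy_bone(cfg$model, seed = cfg$seed)
  fr <- if (is.null(cfg$frame)) .toy_frame(model, cfg)
        else frame(cfg$frame$origin_mm, cfg$frame$x_hat, cfg$frame$y_hat,
                   cfg$frame$z_hat)
  grid <- angle_grid(cfg$grid$step, cfg$grid$lo, cfg$grid$hi)
  dirs <- t(mapply(function(a, b) direction_vector(fr, a, b),
                   grid$alpha_deg, grid$beta_deg))
  sw <- sweep_harmonic(model, dirs, cfg$frequencies, amplitude = cfg$force_N)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rw <- model$rw
  utils::write.csv(data.frame(dir_id = seq_len(nrow(grid)),
                              alpha_deg = grid$alpha_deg,
                              beta_deg = grid$beta_deg,
                              dx = dirs[, 1L], dy = dirs[, 2L],
                              dz = dirs[, 3L]),
                   file.path(out_dir, "directions.csv"), row.names = FALSE)
  utils::write.csv(data.frame(freq_id = seq_along(cfg$frequencies),
                              freq_hz = cfg$frequencies),
                   file.path(out_dir, "frequencies.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node_id = rw$edge_ids,
                              x_mm = rw$edge_xy_mm[, 1L],
                              y_mm = rw$edge_xy_mm[, 2L]),
                   file.path(out_dir, "ring_nodes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node_id = rw$membrane_ids,
                              x_mm = rw$membrane_xy_mm[, 1L],
                              y_mm = rw$membrane_xy_mm[, 2L]),
                   file.path(out_dir, "membrane_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rw$membrane_quads) |>
                     stats::setNames(c("A", "B", "C", "D")),
                   file.path(out_dir, "membrane_quads.csv"),
                   row.names = FALSE)
  rows <- list()
  for (f in seq_along(cfg$frequencies)) for (d in seq_len(nrow(grid))) {
    u <- sw$fields[[f]][[d]]  # n x 3 complex, m
    wz_edge <- (u[rw$edge_ids, , drop = FALSE] %*% rw$z_hat)[, 1L] * 1000
    wz_mem <- (u[rw$membrane_ids, , drop = FALSE] %*% rw$z_hat)[, 1L] * 1000
    rows[[length(rows) + 1L]] <- data.frame(
      dir_id = d, freq_id = f,
      set = rep(c("rw_edge", "rw_membrane"),
                c(length(wz_edge), length(wz_mem))),
      node_row = c(seq_along(wz_edge), seq_along(wz_mem)),
      re_mm = c(Re(wz_edge), Re(wz_mem)),
      im_mm = c(Im(wz_edge), Im(wz_mem)))
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "fields.csv"),
                   row.names = FALSE)
  manifest <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("rwdirect")),
                   n_directions = nrow(grid),
                   n_frequencies = length(cfg$frequencies),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a field container directory
#'
#' @param dir container path written by [run_simulate()].
#' @return list with `directions`, `frequencies`, `ring`, `membrane`,
#'   `fields` (long data.frame), `manifest`.
#' @export
read_container <- function(dir) {
  need <- c("directions.csv", "frequencies.csv", "ring_nodes.csv",
            "membrane_nodes.csv", "membrane_quads.csv", "fields.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("read_container(): missing file(s): ", paste(missing, collapse = ", "))
  ring_csv <- utils::read.csv(file.path(dir, "ring_nodes.csv"))
  mem_csv <- utils::read.csv(file.path(dir, "membrane_nodes.csv"))
  quads <- as.matrix(utils::read.csv(file.path(dir, "membrane_quads.csv")))
  list(directions = utils::read.csv(file.path(dir, "directions.csv")),
       frequencies = utils::read.csv(file.path(dir, "frequencies.csv")),
       ring = build_ring(cbind(ring_csv$x_mm, ring_csv$y_mm),
                         node_ids = ring_csv$node_id),
       ring_ids_raw = ring_csv$node_id,
       membrane = membrane_mesh(cbind(mem_csv$x_mm, mem_csv$y_mm), quads),
       fields = utils::read.csv(file.path(dir, "fields.csv")),
       manifest = if (file.exists(file.path(dir, "manifest.json")))
         jsonlite::read_json(file.path(dir, "manifest.json")) else NULL)
}

#' Ring motion and volume displacement tables from a field container
#'
#' For every (direction, frequency): fits the averaged rigid edge motion
#' from the ring nodes and the membrane volume displacement relative to it.
#'
#' @param container a directory path or the list from [read_container()].
#' @param path optional CSV output path.
#' @return data.frame with columns `freq_hz`, `alpha_deg`, `beta_deg`,
#'   `w_re`, `w_im`, `w_amp_mm`, `w_phase_deg`, `V_re`, `V_im`, `amp_mm3`,
#'   `phase_deg`.
#' @export
run_analyze <- function(container, path = NULL) {
  if (is.character(container)) container <- read_container(container)
  ring <- container$ring
  mem <- container$membrane
  flds <- container$fields
  # field rows are in raw container order; the ring is angular-sorted
  ring_perm <- match(ring$node_ids, container$ring_ids_raw)
  out <- list()
  for (f in container$frequencies$freq_id) {
    for (d in container$directions$dir_id) {
      sel <- flds$dir_id == d & flds$freq_id == f
      fe <- flds[sel & flds$set == "rw_edge", ]
      fm <- flds[sel & flds$set == "rw_membrane", ]
      wz_edge_raw <- complex(real = fe$re_mm, imaginary = fe$im_mm)[
        order(fe$node_row)]
      wz_mem <- complex(real = fm$re_mm, imaginary = fm$im_mm)[
        order(fm$node_row)]
      wz_edge <- wz_edge_raw[ring_perm]
      rm <- ring_motion(ring, wz_edge)
      vd <- total_vd(mem, wz_mem, rm)
      wap <- amplitude_phase(rm$w)
      out[[length(out) + 1L]] <- data.frame(
        freq_hz = container$frequencies$freq_hz[
          container$frequencies$freq_id == f],
        alpha_deg = container$directions$alpha_deg[
          container$directions$dir_id == d],
        beta_deg = container$directions$beta_deg[
          container$directions$dir_id == d],
        w_re = Re(rm$w), w_im = Im(rm$w),
        w_amp_mm = wap$amplitude, w_phase_deg = wap$phase_deg,
        V_re = Re(vd$V), V_im = Im(vd$V),
        amp_mm3 = vd$amplitude, phase_deg = vd$phase_deg)
    }
  }
  tab <- do.call(rbind, out)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Criterion maps and refined extreme directions from analysis tables
#'
#' Assembles the edge-displacement and volume-displacement amplitude
#' surfaces, computes per-frequency weights and the two weighted-sum
#' criteria, and refines the grid extremes of each to sub-grid resolution.
#'
#' @param tables data.frame from [run_analyze()].
#' @param path optional JSON output path for the summary.
#' @return list with `V` and `w`, each holding `surface`, `mu`, `map`
#'   (an `rw_criterion_map`) and `extremes` (from [refined_extremes()]).
#' @export
run_criteria <- function(tables, path = NULL) {
  freqs <- sort(unique(tables$freq_hz))
  key <- paste(tables$alpha_deg, tables$beta_deg)
  grid <- unique(tables[, c("alpha_deg", "beta_deg")])
  grid <- grid[order(grid$beta_deg, grid$alpha_deg), , drop = FALSE]
  gkey <- paste(grid$alpha_deg, grid$beta_deg)
  build <- function(col) {
    amp <- matrix(NA_real_, nrow(grid), length(freqs))
    for (j in seq_along(freqs)) {
      sub <- tables[tables$freq_hz == freqs[j], ]
      amp[, j] <- sub[[col]][match(gkey, paste(sub$alpha_deg, sub$beta_deg))]
    }
    if (anyNA(amp)) stop("run_criteria(): incomplete grid x frequency table")
    response_surface(grid, freqs, amp)
  }
  one <- function(col) {
    surface <- build(col)
    mu <- weight_coefficients(surface)
    map <- weighted_criterion(normalize_surface(surface), mu)
    list(surface = surface, mu = mu, map = map,
         extremes = refined_extremes(map))
  }
  res <- list(V = one("amp_mm3"), w = one("w_amp_mm"))
  if (!is.null(path)) {
    summ <- lapply(res, function(r) list(
      mu = data.frame(freq_hz = freqs, mu = r$mu),
      extremes = r$extremes))
    jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  res
}
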