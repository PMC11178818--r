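# Frequency-weighted directional criteria.
#
# For each frequency f the per-direction amplitudes (|V| of the membrane
# volume displacement, |w| of the averaged edge displacement) are normalized
# by their grid maximum; the weight mu_f = 1 - min/max measures how much the
# direction matters at f; and the criterion is the mu-weighted mean of the
# normalized maps over the frequency set.

#' The one-third-octave frequency ladder covering the hearing range
#'
#' Seventeen frequencies from 0.2 to 10 kHz with ratio 2^(1/3) between
#' steps (rounded to the standard preferred values).
#'
#' @return numeric vector of 17 frequencies, Hz.
#' @export
third_octave_frequencies <- function() {
  c(200, 300, 400, 500, 630, 800, 1000, 1250, 1600, 2000,
    2500, 3150, 4000, 5000, 6300, 8000, 10000)
}

#' Per-direction, per-frequency amplitude surface
#'
#' @param grid data.frame of `alpha_deg`, `beta_deg` (one row per direction).
#' @param frequencies strictly increasing positive frequencies, Hz.
#' @param amplitudes numeric matrix, directions x frequencies, all >= 0.
#' @return list of class `rw_surface`.
#' @export
response_surface <- function(grid, frequencies, amplitudes) {
  amplitudes <- as.matrix(amplitudes)
  stopifnot(is.data.frame(grid),
            all(c("alpha_deg", "beta_deg") %in% names(grid)),
            nrow(amplitudes) == nrow(grid),
            ncol(amplitudes) == length(frequencies),
            all(diff(frequencies) > 0), all(frequencies > 0),
            all(is.finite(amplitudes)), all(amplitudes >= 0))
  structure(list(grid = grid[, c("alpha_deg", "beta_deg")],
                 frequencies = as.numeric(frequencies),
                 amplitudes = amplitudes),
            class = "rw_surface")
}

.check_surface_maxima <- function(surface, what) {
  mx <- apply(surface$amplitudes, 2L, max)
  bad <- which(mx <= 0)
  if (length(bad))
    stop(what, "(): zero maximum amplitude at frequency ",
         paste(surface$frequencies[bad], collapse = ", "), " Hz")
  mx
}

#' Normalize a response surface per frequency
#'
#' Divides each frequency's column by its grid maximum; the per-frequency
#' maximum of the result is exactly 1.
#'
#' @param surface an `rw_surface`.
#' @return an `rw_surface` of normalized amplitudes.
#' @export
normalize_surface <- function(surface) {
  stopifnot(inherits(surface, "rw_surface"))
  mx <- .check_surface_maxima(surface, "normalize_surface")
  response_surface(surface$grid, surface$frequencies,
                   sweep(surface$amplitudes, 2L, mx, "/"))
}

#' Direction-sensitivity weight coefficients per frequency
#'
#' mu_f = 1 - min/max of the amplitudes over the direction grid at frequency
#' f; mu near 1 means the response depends strongly on the force direction,
#' mu = 0 means direction is irrelevant at that frequency.
#'
#' @param surface an `rw_surface`.
#' @return numeric vector of weights in `[0, 1]`, one per frequency.
#' @export
weight_coefficients <- function(surface) {
  stopifnot(inherits(surface, "rw_surface"))
  mx <- .check_surface_maxima(surface, "weight_coefficients")
  mn <- apply(surface$amplitudes, 2L, min)
  1 - mn / mx
}

#' Weighted-sum directional criterion
#'
#' criterion(direction) = sum_f n(direction, f) mu_f / sum_f mu_f, where n
#' is the normalized amplitude.  Values lie in `[0, 1]`; 1 is attained only
#' at a direction that maximizes every frequency carrying weight.
#'
#' @param normalized an `rw_surface` of normalized amplitudes (from
#'   [normalize_surface()]).
#' @param mu numeric weights per frequency, in `[0, 1]`.
#' @return list of class `rw_criterion_map` with `grid`, `values`, `mu`,
#'   `frequencies`.
#' @export
weighted_criterion <- function(normalized, mu) {
  stopifnot(inherits(normalized, "rw_surface"),
            length(mu) == length(normalized$frequencies),
            all(mu >= 0), all(mu <= 1 + 1e-12))
  if (sum(mu) <= 0)
    stop("weighted_criterion(): all weight coefficients are zero ",
         "(fully direction-independent surface); criterion undefined")
  vals <- as.vector(normalized$amplitudes %*% mu) / sum(mu)
  structure(list(grid = normalized$grid, values = vals, mu = mu,
                 frequencies = normalized$frequencies),
            class = "rw_criterion_map")
}

#' Full criterion pipeline for one amplitude surface
#'
#' Normalizes, computes weights, and forms the weighted-sum criterion.
#'
#' @param surface an `rw_surface` of raw amplitudes.
#' @return an `rw_criterion_map`.
#' @export
criterion_map <- function(surface) {
  weighted_criterion(normalize_surface(surface), weight_coefficients(surface))
}

#' Coarse grid extremes of a criterion map
#'
#' Grid argmax and argmin.  Ties are broken deterministically by smallest
#' (|alpha|, |beta|, alpha, beta) lexicographic order, with a warning.
#'
#' @param map an `rw_criterion_map`.
#' @param tol tie tolerance on criterion values.
#' @return data.frame with rows `max` and `min`: columns `kind`,
#'   `alpha_deg`, `beta_deg`, `value`, `tie`.
#' @export
coarse_extremes <- function(map, tol = 0) {
  stopifnot(inherits(map, "rw_criterion_map"))
  pick <- function(target, kind) {
    hit <- which(abs(map$values - target) <= tol)
    tie <- length(hit) > 1L
    if (tie) {
      warning("coarse_extremes(): ", length(hit), " tied ", kind,
              " values; deterministic tie-break applied")
      g <- map$grid[hit, , drop = FALSE]
      ord <- order(abs(g$alpha_deg), abs(g$beta_deg), g$alpha_deg, g$beta_deg)
      hit <- hit[ord[1L]]
    }
    data.frame(kind = kind, alpha_deg = map$grid$alpha_deg[hit],
               beta_deg = map$grid$beta_deg[hit],
               value = map$values[hit], tie = tie)
  }
  rbind(pick(max(map$values), "max"), pick(min(map$values), "min"))
}

#' Force amplitude generated by the B81 transducer from its output force level
#'
#' F = (2.5 / 2.83) 1e-6 * 10^(OFL / 20) newtons, for the transducer driven
#' by a stepped sine of 2.5 Vpp given its output force level (dB re 1 uN)
#' measured at 1 Vrms on an artificial mastoid.
#'
#' @param ofl_db_re_1uN numeric output force level(s), dB re 1 uN.
#' @return force amplitude(s), N.
#' @export
b81_force <- function(ofl_db_re_1uN) {
  stopifnot(all(is.finite(ofl_db_re_1uN)))
  (2.5 / 2.83) * 1e-6 * 10^(ofl_db_re_1uN / 20)
}

#' Export a criterion map as a CSV table
#'
#' @param map an `rw_criterion_map`.
#' @param path CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_criterion_csv <- function(map, path) {
  out <- cbind(map$grid, criterion = map$values)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
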