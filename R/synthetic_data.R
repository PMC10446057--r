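#' Generate a synthetic stationary concentration trace
#'
#' Produces NF and FF traces with the statistical structure a stationary
#' aerosol monitor would record next to the modelled process: the exact
#' two-zone model output on a regular grid, perturbed by multiplicative
#' lognormal noise (instrument error is proportional to the reading) and
#' an optional constant additive background.
#'
#' @param segments emission schedule accepted by [simulate_timeline()].
#' @param geometry a [zone_geometry()].
#' @param airflow an [airflow_params()].
#' @param noise_gsd geometric standard deviation of the multiplicative
#'   noise (>= 1; 1 means noiseless).
#' @param background constant additive background, mg/m^3 (>= 0).
#' @param initial starting [zone_state()].
#' @param grid sampling resolution, min.
#' @param seed integer seed.
#' @return Data frame with `time_min`, `C_NF`, `C_FF`; attribute
#'   `truth` holds the noiseless timeline.
#' @export
generate_trace <- function(segments, geometry, airflow, noise_gsd = 1,
                           background = 0, initial = zone_state(0, 0),
                           grid = 1, seed = NULL) {
  .check_num(noise_gsd, "noise_gsd"); .check_num(background, "background")
  if (noise_gsd < 1) stop("'noise_gsd' must be >= 1", call. = FALSE)
  if (background < 0) stop("'background' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tl <- simulate_timeline(segments, geometry, airflow, initial = initial,
                          grid = grid)
  n <- nrow(tl)
  noise <- function() if (noise_gsd == 1) rep.int(1, n)
                      else exp(stats::rnorm(n, 0, log(noise_gsd)))
  out <- data.frame(time_min = tl$time_min,
                    C_NF = tl$C_NF * noise() + background,
                    C_FF = tl$C_FF * noise() + background)
  attr(out, "truth") <- tl
  out
}

#' Generate a lognormal personal-measurement set
#'
#' I.i.d. lognormal exposure values with the given geometric mean and
#' geometric standard deviation, as used to exercise the EN 689
#' compliance tests.
#'
#' @param n number of measurements (>= 1).
#' @param gm geometric mean, mg/m^3 (> 0).
#' @param gsd geometric standard deviation (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_measurement_set <- function(n, gm, gsd, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  .check_num(gm, "gm"); .check_num(gsd, "gsd")
  if (gm <= 0) stop("'gm' must be > 0", call. = FALSE)
  if (gsd < 1) stop("'gsd' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  exp(stats::rnorm(n, log(gm), log(gsd)))
}
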