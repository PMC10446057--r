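#' Read or write a stationary concentration trace
#'
#' Traces are two-column CSV files with a header:
#' `time_min, concentration_mg_m3`.
#'
#' @param path file path.
#' @param trace data frame with columns `time_min` and
#'   `concentration_mg_m3` (for `write_trace()`, alternatively a
#'   timeline from [simulate_timeline()] plus a `zone` choice).
#' @param zone which zone column to export when `trace` carries both
#'   (`"NF"` or `"FF"`).
#' @return `read_trace()`: validated data frame with strictly increasing
#'   `time_min` and non-negative concentrations.
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  if (!all(c("time_min", "concentration_mg_m3") %in% names(tr)))
    stop("trace file must have columns 'time_min' and ",
         "'concentration_mg_m3'", call. = FALSE)
  if (is.unsorted(tr$time_min, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (any(tr$concentration_mg_m3 < 0))
    stop("trace concentrations must be >= 0", call. = FALSE)
  tr
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, zone = c("NF", "FF")) {
  if (!"concentration_mg_m3" %in% names(trace)) {
    zone <- match.arg(zone)
    col <- paste0("C_", zone)
    stopifnot(col %in% names(trace))
    trace <- data.frame(time_min = trace$time_min,
                        concentration_mg_m3 = trace[[col]])
  }
  utils::write.csv(trace[, c("time_min", "concentration_mg_m3")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Fit an exponential concentration decay
#'
#' Ordinary least squares of `log(C - background)` on time within a user
#' supplied window, the standard way to extract a ventilation decay rate
#' from a stationary trace after an emission stops. The decay rate is
#' `lambda = -slope` (1/min).
#'
#' @param trace data frame with `time_min` and `concentration_mg_m3`.
#' @param window `c(t_start, t_end)` in trace time units; at least three
#'   points must fall inside (inclusive).
#' @param background constant background concentration subtracted before
#'   the log transform (mg/m^3); all windowed values must stay positive.
#' @return List with `lambda` (1/min), `intercept` (fitted concentration
#'   at `t_start`, mg/m^3), `r_squared`, `se_lambda`, `n`, `window`.
#' @examples
#' tr <- data.frame(time_min = 0:10,
#'                  concentration_mg_m3 = 2 * exp(-0.5 * (0:10)))
#' fit_decay(tr, c(0, 10))$lambda  # 0.5
#' @export
fit_decay <- function(trace, window, background = 0) {
  stopifnot(is.numeric(window), length(window) == 2)
  if (!all(c("time_min", "concentration_mg_m3") %in% names(trace)))
    stop("trace must have columns 'time_min' and 'concentration_mg_m3'",
         call. = FALSE)
  sel <- trace$time_min >= window[1] & trace$time_min <= window[2]
  t <- trace$time_min[sel]
  conc <- trace$concentration_mg_m3[sel] - background
  if (length(t) < 3)
    stop("decay window contains fewer than 3 points", call. = FALSE)
  if (any(conc <= 0))
    stop("non-positive concentration in the decay window ",
         "(after background subtraction)", call. = FALSE)
  fit <- stats::lm(log(conc) ~ I(t - window[1]))
  # noiseless traces trigger summary.lm's perfect-fit warning; a perfect
  # fit is a legitimate outcome here
  sm <- suppressWarnings(summary(fit))
  list(lambda = -unname(stats::coef(fit)[2]),
       intercept = exp(unname(stats::coef(fit)[1])),
       r_squared = sm$r.squared,
       se_lambda = sm$coefficients[2, "Std. Error"],
       n = length(t), window = window)
}

#' Inter-zonal airflow from an NF decay rate
#'
#' With a low far-field concentration and no active NF emission, the NF
#' concentration decays as `exp(-(beta/V_NF) t)`, so
#' `beta = lambda * V_NF`.
#'
#' @param lambda decay rate from [fit_decay()], 1/min (> 0).
#' @param V_NF near-field volume, m^3 (> 0).
#' @return Inter-zonal airflow, m^3/min.
#' @export
beta_from_decay <- function(lambda, V_NF) {
  .check_num(lambda, "lambda"); .check_num(V_NF, "V_NF")
  if (lambda <= 0 || V_NF <= 0)
    stop("'lambda' and 'V_NF' must be > 0", call. = FALSE)
  lambda * V_NF
}

#' Back-calculate an emission rate from an observed mean concentration
#'
#' The two-zone model is linear in the emission rate, so the rate that
#' reproduces an observed time-average NF concentration is obtained by
#' simulating the schedule once with a unit emission rate on every
#' emitting segment and scaling:
#' `G = observed / simulated_mean(G = 1)`. At steady state this reduces
#' to `G = C_NF / (1/Q + 1/beta)` (no local exhaust).
#'
#' @param observed_mean_C_NF observed time-average NF concentration over
#'   the schedule, mg/m^3 (> 0).
#' @param schedule segment list or data frame accepted by
#'   [simulate_timeline()]; its `G` column only marks which segments
#'   emit.
#' @param geometry a [zone_geometry()].
#' @param airflow an [airflow_params()].
#' @return Emission rate G, mg/min.
#' @export
back_calculate_G <- function(observed_mean_C_NF, schedule, geometry,
                             airflow) {
  .check_num(observed_mean_C_NF, "observed_mean_C_NF")
  if (observed_mean_C_NF <= 0)
    stop("'observed_mean_C_NF' must be > 0", call. = FALSE)
  segs <- .as_segments(schedule)
  if (all(segs$G == 0))
    stop("schedule has no emitting segment", call. = FALSE)
  segs$G <- as.numeric(segs$G > 0)
  tl <- simulate_timeline(segs, geometry, airflow, grid = sum(segs$duration))
  unit_mean <- attr(tl, "integrals")[["int_NF"]] / sum(segs$duration)
  observed_mean_C_NF / unit_mean
}
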