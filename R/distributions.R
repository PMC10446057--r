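#' Distribution specifications for exposure determinants
#'
#' Scenario parameters (room volume, air exchange rate, emission rates,
#' task durations, inter-zonal airflow) are described either as point
#' values or as one of three parametric families commonly used in
#' probabilistic exposure assessment: continuous uniform ("linear range"),
#' triangular (min/mode/max) and lognormal (GM/GSD).
#'
#' @param value point value.
#' @param min,max support bounds (uniform, triangular).
#' @param mode most likely value (triangular); `min <= mode <= max` and
#'   `min < max`.
#' @param gm,gsd geometric mean (> 0) and geometric standard deviation
#'   (>= 1) of a lognormal distribution.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_triangular(0.43, 0.87, 1.74)  # emission rate, mg/min
#' dist_uniform(2, 8)                 # air exchange rate, 1/h
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(kind = "point", value = value), class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_uniform <- function(min, max) {
  .check_num(min, "min"); .check_num(max, "max")
  if (!(min < max)) stop("uniform: 'min' must be < 'max'", call. = FALSE)
  structure(list(kind = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_triangular <- function(min, mode, max) {
  .check_num(min, "min"); .check_num(mode, "mode"); .check_num(max, "max")
  if (!(min <= mode && mode <= max))
    stop("triangular: need 'min' <= 'mode' <= 'max' (got ",
         min, ", ", mode, ", ", max, ")", call. = FALSE)
  if (!(min < max)) stop("triangular: 'min' must be < 'max'", call. = FALSE)
  structure(list(kind = "triangular", min = min, mode = mode, max = max),
            class = "dist_spec")
}

#' @rdname dist_point
#' @export
dist_lognormal <- function(gm, gsd) {
  .check_num(gm, "gm"); .check_num(gsd, "gsd")
  if (gm <= 0) stop("lognormal: 'gm' must be > 0", call. = FALSE)
  if (gsd < 1) stop("lognormal: 'gsd' must be >= 1", call. = FALSE)
  structure(list(kind = "lognormal", gm = gm, gsd = gsd), class = "dist_spec")
}

.check_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
}

#' Coerce a scalar or a parameter list to a distribution specification
#'
#' Accepts an existing `dist_spec`, a single number (treated as a point
#' value) or a named list such as
#' `list(kind = "triangular", min = 0.43, mode = 0.87, max = 1.74)` as
#' read from a scenario configuration file.
#'
#' @param x object to coerce.
#' @param what parameter name used in error messages.
#' @return A `dist_spec`.
#' @export
as_dist_spec <- function(x, what = "parameter") {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1) return(dist_point(x))
  if (is.list(x)) {
    kind <- x$kind
    if (is.null(kind))
      stop(what, ": distribution list must contain a 'kind' field",
           call. = FALSE)
    out <- switch(kind,
      point      = dist_point(.field(x, "value", what)),
      uniform    = dist_uniform(.field(x, "min", what), .field(x, "max", what)),
      triangular = dist_triangular(.field(x, "min", what),
                                   .field(x, "mode", what),
                                   .field(x, "max", what)),
      lognormal  = dist_lognormal(.field(x, "gm", what), .field(x, "gsd", what)),
      stop(what, ": unknown distribution kind '", kind, "'", call. = FALSE))
    return(out)
  }
  stop(what, ": cannot interpret as a distribution specification",
       call. = FALSE)
}

.field <- function(x, f, what) {
  if (is.null(x[[f]]))
    stop(what, ": missing distribution field '", f, "'", call. = FALSE)
  x[[f]]
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.dist_spec <- function(x, ...) {
  switch(x$kind,
    point      = sprintf("point(%g)", x$value),
    uniform    = sprintf("uniform(%g, %g)", x$min, x$max),
    triangular = sprintf("triangular(%g, %g, %g)", x$min, x$mode, x$max),
    lognormal  = sprintf("lognormal(GM %g, GSD %g)", x$gm, x$gsd))
}

#' Draw random values from a distribution specification
#'
#' Sampling uses R's global random number stream, so draws are
#' reproducible under `set.seed()`. Triangular values are generated by
#' inverse-CDF transform of a uniform deviate; lognormal values as
#' `exp(rnorm(n, log(gm), log(gsd)))`.
#'
#' @param dist a `dist_spec`.
#' @param n number of draws.
#' @return Numeric vector of length `n`, inside the distribution support.
#' @export
draw_dist <- function(dist, n = 1) {
  dist <- as_dist_spec(dist)
  switch(dist$kind,
    point      = rep.int(dist$value, n),
    uniform    = stats::runif(n, dist$min, dist$max),
    triangular = .rtriangular(n, dist$min, dist$mode, dist$max),
    lognormal  = exp(stats::rnorm(n, log(dist$gm), log(dist$gsd))))
}

.rtriangular <- function(n, mn, md, mx) {
  u <- stats::runif(n)
  f <- (md - mn) / (mx - mn)
  ifelse(u < f,
         mn + sqrt(u * (mx - mn) * (md - mn)),
         mx - sqrt((1 - u) * (mx - mn) * (mx - md)))
}

#' Analytic mean, CDF and support of a distribution specification
#'
#' `dist_mean()` returns the expectation, `dist_cdf()` evaluates the
#' cumulative distribution function at `q`, and `dist_support()` the
#' (possibly infinite) support bounds. Used for validation and for
#' goodness-of-fit checks of the sampler.
#'
#' @param dist a `dist_spec`.
#' @param q quantile(s) at which to evaluate the CDF.
#' @return `dist_mean()`: a number; `dist_cdf()`: vector of probabilities;
#'   `dist_support()`: numeric length-2 vector.
#' @export
dist_mean <- function(dist) {
  dist <- as_dist_spec(dist)
  switch(dist$kind,
    point      = dist$value,
    uniform    = (dist$min + dist$max) / 2,
    triangular = (dist$min + dist$mode + dist$max) / 3,
    lognormal  = dist$gm * exp(log(dist$gsd)^2 / 2))
}

#' @rdname dist_mean
#' @export
dist_cdf <- function(dist, q) {
  dist <- as_dist_spec(dist)
  switch(dist$kind,
    point      = as.numeric(q >= dist$value),
    uniform    = stats::punif(q, dist$min, dist$max),
    triangular = .ptriangular(q, dist$min, dist$mode, dist$max),
    lognormal  = stats::plnorm(q, log(dist$gm), log(dist$gsd)))
}

.ptriangular <- function(q, mn, md, mx) {
  p <- numeric(length(q))
  lo <- q <= mn; hi <- q >= mx
  left <- !lo & !hi & q <= md
  right <- !lo & !hi & q > md
  p[lo] <- 0; p[hi] <- 1
  p[left] <- (q[left] - mn)^2 / ((mx - mn) * (md - mn))
  p[right] <- 1 - (mx - q[right])^2 / ((mx - mn) * (mx - md))
  p
}

#' @rdname dist_mean
#' @export
dist_support <- function(dist) {
  dist <- as_dist_spec(dist)
  switch(dist$kind,
    point      = c(dist$value, dist$value),
    uniform    = c(dist$min, dist$max),
    triangular = c(dist$min, dist$max),
    lognormal  = c(0, Inf))
}

#' Convert between near-field random air speed and inter-zonal airflow
#'
#' The air-mixing flow rate between the near field and the far field is
#' approximated as one half of the near-field free surface area times the
#' random air speed: `beta = 0.5 * FSA * s`. `airspeed_from_flow()` is the
#' inverse relation, recovering the random air speed implied by a measured
#' volumetric flow through a free surface.
#'
#' @param free_surface_area open (uncovered) surface area of the
#'   near-field volume, m^2.
#' @param airspeed random air speed, m/min.
#' @param flow volumetric airflow, m^3/min.
#' @return `beta_from_airspeed()`: airflow in m^3/min;
#'   `airspeed_from_flow()`: air speed in m/min.
#' @examples
#' beta_from_airspeed(2, 3.2)        # 3.2 m^3/min
#' airspeed_from_flow(1405, 6)       # ~468 m/min for an open 1-m cube
#' @export
beta_from_airspeed <- function(free_surface_area, airspeed) {
  if (!is.numeric(free_surface_area) || free_surface_area <= 0)
    stop("'free_surface_area' must be > 0", call. = FALSE)
  if (!is.numeric(airspeed) || airspeed <= 0)
    stop("'airspeed' must be > 0", call. = FALSE)
  0.5 * free_surface_area * airspeed
}

#' @rdname beta_from_airspeed
#' @export
airspeed_from_flow <- function(flow, free_surface_area) {
  if (!is.numeric(flow) || flow <= 0)
    stop("'flow' must be > 0", call. = FALSE)
  if (!is.numeric(free_surface_area) || free_surface_area <= 0)
    stop("'free_surface_area' must be > 0", call. = FALSE)
  flow / (0.5 * free_surface_area)
}
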