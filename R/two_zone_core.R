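#' Two-zone model geometry
#'
#' The room is split into a small well-mixed Near-Field (NF) volume
#' enclosing the emission source and the worker's breathing zone, and the
#' remaining Far-Field (FF) volume `V_FF = V_room - V_NF`.
#'
#' @param V_NF near-field volume, m^3 (`0 < V_NF < V_room`).
#' @param V_room total room volume, m^3.
#' @return A `zone_geometry` with fields `V_NF`, `V_room`, `V_FF`.
#' @export
zone_geometry <- function(V_NF, V_room) {
  .check_num(V_NF, "V_NF"); .check_num(V_room, "V_room")
  if (!(V_NF > 0 && V_NF < V_room))
    stop("need 0 < V_NF < V_room (got V_NF = ", V_NF,
         ", V_room = ", V_room, ")", call. = FALSE)
  structure(list(V_NF = V_NF, V_room = V_room, V_FF = V_room - V_NF),
            class = "zone_geometry")
}

#' Airflow parameters of the two-zone model
#'
#' `beta` is the inter-zonal air-mixing flow between NF and FF (m^3/min).
#' General ventilation supplies clean air at `Q = AER * V_room / 60`
#' (m^3/min) and exhausts from the FF. An optional local exhaust
#' ventilation (LEV) with zero source-capture efficiency draws `Q_lev`
#' directly from the NF; its make-up air comes from the FF, so the NF
#' receives `beta + Q_lev` from the FF and returns `beta` to it.
#'
#' @param beta inter-zonal airflow, m^3/min (> 0).
#' @param AER general-ventilation air exchange rate, 1/h (> 0).
#' @param V_room room volume, m^3 (used to convert AER to a flow).
#' @param Q_lev local exhaust flow from the NF, m^3/min
#'   (`0 <= Q_lev < Q`).
#' @return An `airflow_params` with fields `beta`, `AER`, `Q`, `Q_lev`.
#' @export
airflow_params <- function(beta, AER, V_room, Q_lev = 0) {
  .check_num(beta, "beta"); .check_num(AER, "AER")
  .check_num(V_room, "V_room"); .check_num(Q_lev, "Q_lev")
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (AER <= 0) stop("'AER' must be > 0", call. = FALSE)
  if (V_room <= 0) stop("'V_room' must be > 0", call. = FALSE)
  Q <- AER * V_room / 60
  if (Q_lev < 0 || Q_lev >= Q)
    stop("need 0 <= Q_lev < Q (Q = ", signif(Q, 6), " m^3/min)",
         call. = FALSE)
  structure(list(beta = beta, AER = AER, Q = Q, Q_lev = Q_lev),
            class = "airflow_params")
}

#' Instantaneous zone concentrations
#'
#' @param C_NF,C_FF near-field and far-field concentrations, mg/m^3
#'   (>= 0).
#' @return A `zone_state`.
#' @export
zone_state <- function(C_NF = 0, C_FF = 0) {
  .check_num(C_NF, "C_NF"); .check_num(C_FF, "C_FF")
  if (C_NF < 0 || C_FF < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(C_NF = C_NF, C_FF = C_FF), class = "zone_state")
}

#' A constant-emission segment of the work schedule
#'
#' @param duration segment length, min (> 0).
#' @param G constant emission rate into the NF over the segment, mg/min
#'   (>= 0).
#' @return An `emission_segment`.
#' @export
emission_segment <- function(duration, G) {
  .check_num(duration, "duration"); .check_num(G, "G")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (G < 0) stop("'G' must be >= 0", call. = FALSE)
  structure(list(duration = duration, G = G), class = "emission_segment")
}

# Coefficient matrix of the linear system
#   V_NF dC_NF/dt = G + (beta + Q_lev) (C_FF - C_NF)
#   V_FF dC_FF/dt = beta C_NF - (beta + Q) C_FF
# Eigenvalues are always real, distinct and negative: the off-diagonal
# product a12*a21 > 0 makes the discriminant strictly positive and
# det(A) = (beta + Q_lev) * Q / (V_NF * V_FF) > 0 with tr(A) < 0.
.two_zone_system <- function(V_NF, V_FF, beta, Q, Q_lev) {
  a11 <- -(beta + Q_lev) / V_NF
  a12 <- (beta + Q_lev) / V_NF
  a21 <- beta / V_FF
  a22 <- -(beta + Q) / V_FF
  tr <- a11 + a22
  det <- a11 * a22 - a12 * a21
  disc <- sqrt(tr * tr - 4 * det)
  list(a11 = a11, a12 = a12, a21 = a21, a22 = a22, det = det,
       l1 = (tr + disc) / 2, l2 = (tr - disc) / 2)
}

# Exact solution over one constant-G segment from state (x1, x2).
# Returns the end state and the exact time integrals of both
# concentrations over the segment (used for time-averaged exposure and
# mass-balance accounting). Decomposes the deviation from the fixed point
# onto the eigenvectors (a12, lambda - a11) of the 2x2 system.
.advance_segment <- function(sys, x1, x2, G, dt, V_NF) {
  b1 <- G / V_NF
  xs1 <- -sys$a22 * b1 / sys$det
  xs2 <- sys$a21 * b1 / sys$det
  y1 <- x1 - xs1
  y2 <- x2 - xs2
  denom <- sys$a12 * (sys$l2 - sys$l1)
  c1 <- (y1 * (sys$l2 - sys$a11) - sys$a12 * y2) / denom
  c2 <- (sys$a12 * y2 - y1 * (sys$l1 - sys$a11)) / denom
  e1 <- exp(sys$l1 * dt)
  e2 <- exp(sys$l2 * dt)
  g1 <- (e1 - 1) / sys$l1
  g2 <- (e2 - 1) / sys$l2
  c(C_NF = xs1 + (c1 * e1 + c2 * e2) * sys$a12,
    C_FF = xs2 + c1 * e1 * (sys$l1 - sys$a11) + c2 * e2 * (sys$l2 - sys$a11),
    int_NF = dt * xs1 + (c1 * g1 + c2 * g2) * sys$a12,
    int_FF = dt * xs2 + c1 * g1 * (sys$l1 - sys$a11) +
      c2 * g2 * (sys$l2 - sys$a11))
}

# Concentrations at offsets `tau` (vector) into a constant-G segment.
.eval_segment <- function(sys, x1, x2, G, tau, V_NF) {
  b1 <- G / V_NF
  xs1 <- -sys$a22 * b1 / sys$det
  xs2 <- sys$a21 * b1 / sys$det
  y1 <- x1 - xs1
  y2 <- x2 - xs2
  denom <- sys$a12 * (sys$l2 - sys$l1)
  c1 <- (y1 * (sys$l2 - sys$a11) - sys$a12 * y2) / denom
  c2 <- (sys$a12 * y2 - y1 * (sys$l1 - sys$a11)) / denom
  e1 <- exp(sys$l1 * tau)
  e2 <- exp(sys$l2 * tau)
  cbind(C_NF = xs1 + (c1 * e1 + c2 * e2) * sys$a12,
        C_FF = xs2 + c1 * e1 * (sys$l1 - sys$a11) +
          c2 * e2 * (sys$l2 - sys$a11))
}

.as_airflow <- function(airflow, geometry) {
  if (inherits(airflow, "airflow_params")) return(airflow)
  stop("'airflow' must be an airflow_params object", call. = FALSE)
}

#' Steady state of the two-zone model
#'
#' Fixed point of the mass-balance system under a constant emission rate.
#' With no local exhaust this is the familiar pair
#' `C_FF* = G/Q`, `C_NF* = C_FF* + G/beta`; with a local exhaust drawing
#' `Q_lev` from the NF the fixed point of the governing equations is
#' `C_FF* = beta G / (Q (beta + Q_lev))`,
#' `C_NF* = C_FF* + G/(beta + Q_lev)`.
#'
#' @param G emission rate, mg/min (>= 0).
#' @param geometry a [zone_geometry()].
#' @param airflow an [airflow_params()].
#' @return A [zone_state()].
#' @examples
#' g <- zone_geometry(V_NF = 1.5, V_room = 1400)
#' a <- airflow_params(beta = 3.2, AER = 5, V_room = 1400)
#' steady_state(0.87, g, a)
#' @export
steady_state <- function(G, geometry, airflow) {
  .check_num(G, "G")
  if (G < 0) stop("'G' must be >= 0", call. = FALSE)
  stopifnot(inherits(geometry, "zone_geometry"))
  airflow <- .as_airflow(airflow, geometry)
  C_FF <- airflow$beta * G / (airflow$Q * (airflow$beta + airflow$Q_lev))
  C_NF <- C_FF + G / (airflow$beta + airflow$Q_lev)
  zone_state(C_NF = C_NF, C_FF = C_FF)
}

#' Propagate the two-zone state over a time step
#'
#' Advances the coupled NF/FF mass balance exactly over `dt` minutes of
#' constant emission, using the closed-form eigen-decomposition of the
#' constant-coefficient linear system (no numerical integration error;
#' any reporting grid is purely cosmetic).
#'
#' @param state a [zone_state()] at the start of the step.
#' @param geometry a [zone_geometry()].
#' @param airflow an [airflow_params()].
#' @param G constant emission rate over the step, mg/min (>= 0).
#' @param dt step length, min (> 0).
#' @return A [zone_state()] at `t + dt`.
#' @export
propagate <- function(state, geometry, airflow, G, dt) {
  stopifnot(inherits(state, "zone_state"), inherits(geometry, "zone_geometry"))
  airflow <- .as_airflow(airflow, geometry)
  .check_num(G, "G"); .check_num(dt, "dt")
  if (G < 0) stop("'G' must be >= 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  sys <- .two_zone_system(geometry$V_NF, geometry$V_FF,
                          airflow$beta, airflow$Q, airflow$Q_lev)
  out <- .advance_segment(sys, state$C_NF, state$C_FF, G, dt, geometry$V_NF)
  zone_state(C_NF = max(out[["C_NF"]], 0), C_FF = max(out[["C_FF"]], 0))
}

#' Simulate a piecewise-constant emission schedule
#'
#' Chains the exact segment solution over an ordered list of
#' constant-emission segments and reports both zone concentrations on a
#' regular grid. Attributes carry the exact segment-boundary states and
#' the exact time integrals of both concentrations (so mass-balance
#' checks and time averages do not depend on the reporting grid).
#'
#' @param segments list of [emission_segment()]s, or a data frame with
#'   columns `duration` and `G`.
#' @param geometry a [zone_geometry()].
#' @param airflow an [airflow_params()].
#' @param initial starting [zone_state()]; default clean air.
#' @param grid reporting resolution, min (default 1).
#' @return A data frame with columns `time_min`, `C_NF`, `C_FF`; the
#'   final row is the exact end-of-schedule state. Attributes:
#'   `boundaries` (data frame of segment end times and states) and
#'   `integrals` (named vector with exact `int_NF`, `int_FF`, in
#'   mg/m^3 * min).
#' @export
simulate_timeline <- function(segments, geometry, airflow,
                              initial = zone_state(0, 0), grid = 1) {
  segs <- .as_segments(segments)
  if (nrow(segs) == 0) stop("empty emission schedule", call. = FALSE)
  stopifnot(inherits(geometry, "zone_geometry"), inherits(initial, "zone_state"))
  airflow <- .as_airflow(airflow, geometry)
  .check_num(grid, "grid")
  if (grid <= 0) stop("'grid' must be > 0", call. = FALSE)

  sys <- .two_zone_system(geometry$V_NF, geometry$V_FF,
                          airflow$beta, airflow$Q, airflow$Q_lev)
  ends <- cumsum(segs$duration)
  starts <- c(0, ends[-length(ends)])
  total <- ends[length(ends)]
  times <- seq(0, total, by = grid)

  out_NF <- numeric(length(times))
  out_FF <- numeric(length(times))
  bound <- matrix(NA_real_, nrow(segs), 3,
                  dimnames = list(NULL, c("time_min", "C_NF", "C_FF")))
  x1 <- initial$C_NF; x2 <- initial$C_FF
  int_NF <- 0; int_FF <- 0
  for (i in seq_len(nrow(segs))) {
    # half-open [start, end): within-segment grid points use the exact
    # solution from the segment-start state
    in_seg <- times >= starts[i] & times < ends[i]
    if (any(in_seg)) {
      vals <- .eval_segment(sys, x1, x2, segs$G[i],
                            times[in_seg] - starts[i], geometry$V_NF)
      out_NF[in_seg] <- vals[, "C_NF"]
      out_FF[in_seg] <- vals[, "C_FF"]
    }
    adv <- .advance_segment(sys, x1, x2, segs$G[i], segs$duration[i],
                            geometry$V_NF)
    x1 <- adv[["C_NF"]]; x2 <- adv[["C_FF"]]
    int_NF <- int_NF + adv[["int_NF"]]
    int_FF <- int_FF + adv[["int_FF"]]
    bound[i, ] <- c(ends[i], x1, x2)
  }
  at_end <- times >= total - 1e-12
  out_NF[at_end] <- x1
  out_FF[at_end] <- x2

  # round-off in the eigen arithmetic can leave values at -1e-20 where
  # the true concentration is 0
  res <- data.frame(time_min = times, C_NF = pmax(out_NF, 0),
                    C_FF = pmax(out_FF, 0))
  attr(res, "boundaries") <- as.data.frame(bound)
  attr(res, "integrals") <- c(int_NF = int_NF, int_FF = int_FF)
  res
}

.as_segments <- function(segments) {
  if (is.data.frame(segments)) {
    stopifnot(all(c("duration", "G") %in% names(segments)))
    segs <- segments[, c("duration", "G")]
  } else if (is.list(segments)) {
    if (inherits(segments, "emission_segment")) segments <- list(segments)
    segs <- data.frame(
      duration = vapply(segments, function(s) s$duration, numeric(1)),
      G = vapply(segments, function(s) s$G, numeric(1)))
  } else {
    stop("'segments' must be a list of emission_segment or a data frame",
         call. = FALSE)
  }
  if (any(segs$duration <= 0)) stop("segment durations must be > 0",
                                    call. = FALSE)
  if (any(segs$G < 0)) stop("emission rates must be >= 0", call. = FALSE)
  segs
}
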