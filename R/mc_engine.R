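#' Monte-Carlo simulation of a multi-task work shift
#'
#' Runs `N` independent iterations of the scenario: each iteration draws
#' the exposure determinants according to their sampling scopes, realizes
#' the ordered emission schedule, solves the two-zone model exactly
#' through the whole shift (the state carries across repetitions and
#' tasks, so residual concentrations propagate into later tasks) and
#' records time-averaged NF concentrations.
#'
#' Per-iteration determinant summaries are recorded per task as the mean
#' of the repetition-level draws (for a `per_shift` or `per_task` scope
#' this is simply the drawn value), which is what the task sensitivity
#' analysis correlates against.
#'
#' @param shift a [shift_spec()].
#' @param N number of iterations (default `shift$N_iterations`).
#' @param seed integer seed; each iteration runs on a child seed derived
#'   from it, so results are bitwise reproducible.
#' @param keep_traces store 1-min NF/FF traces for the first `K`
#'   iterations in the `traces` attribute (default 0, none).
#' @return A data frame with one row per iteration: sampled environment
#'   values (`V_room`, `AER`, `V_NF`, shift-mean `beta`), per-task
#'   determinant means (`beta_task<k>`, `G_task<k>`, `t_G_task<k>`,
#'   `t_pouring_task<k>`), per-task realized durations (`dur_task<k>`,
#'   min) and time-average NF concentrations (`avg_task<k>`, mg/m^3),
#'   the realized `shift_duration` and the time-weighted `shift_avg`.
#' @examples
#' sc <- observed_scenario()
#' head(run_monte_carlo(sc, N = 10, seed = 1))
#' @export
run_monte_carlo <- function(shift, N = shift$N_iterations, seed = 1,
                            keep_traces = 0) {
  stopifnot(inherits(shift, "shift_spec"))
  if (is.null(N)) N <- 10000L
  if (!is.numeric(N) || N < 1) stop("'N' must be >= 1", call. = FALSE)
  N <- as.integer(N)
  n_tasks <- length(shift$tasks)

  set.seed(seed)
  iter_seeds <- sample.int(2147483646L, N, replace = TRUE)

  per_task_cols <- as.vector(outer(
    c("beta_task", "G_task", "t_G_task", "t_pouring_task", "dur_task",
      "avg_task"), seq_len(n_tasks), paste0))
  cols <- c("iteration", "V_room", "AER", "V_NF", "beta", per_task_cols,
            "shift_duration", "shift_avg")
  out <- matrix(NA_real_, N, length(cols), dimnames = list(NULL, cols))
  traces <- if (keep_traces > 0) vector("list", min(keep_traces, N)) else NULL

  Q_lev <- shift$Q_lev
  gap <- shift$gap
  nrep <- vapply(shift$tasks, function(t) t$n_repetitions, integer(1))

  for (it in seq_len(N)) {
    set.seed(iter_seeds[it])
    d <- sample_determinants(shift)
    x1 <- 0; x2 <- 0
    int_task <- numeric(n_tasks)
    dur_task <- numeric(n_tasks)
    gap_time <- 0
    trace_t <- NULL; trace_nf <- NULL; trace_ff <- NULL
    want_trace <- !is.null(traces) && it <= length(traces)
    t_now <- 0

    for (k in seq_len(n_tasks)) {
      if (k > 1 && gap > 0) {
        sys <- .two_zone_system(d$V_NF[[k]][1],
                                d$V_room[[k]][1] - d$V_NF[[k]][1],
                                d$beta[[k]][1],
                                d$AER[[k]][1] * d$V_room[[k]][1] / 60, Q_lev)
        adv <- .advance_segment(sys, x1, x2, 0, gap, d$V_NF[[k]][1])
        x1 <- adv[[1]]; x2 <- adv[[2]]
        gap_time <- gap_time + gap
        t_now <- t_now + gap
      }
      for (r in seq_len(nrep[k])) {
        beta <- d$beta[[k]][r]
        V_NF <- d$V_NF[[k]][r]
        V_room <- d$V_room[[k]][r]
        Q <- d$AER[[k]][r] * V_room / 60
        sys <- .two_zone_system(V_NF, V_room - V_NF, beta, Q, Q_lev)
        tp <- d$t_pouring[[k]][r]
        tG <- min(d$t_G[[k]][r], tp)
        G <- d$G[[k]][r]
        for (seg in 1:2) {
          dt <- if (seg == 1) tG else tp - tG
          if (dt <= 1e-12) next
          Gs <- if (seg == 1) G else 0
          if (want_trace) {
            tau <- seq(0, dt, by = 1)
            tau <- tau[tau < dt]
            vals <- .eval_segment(sys, x1, x2, Gs, tau, V_NF)
            trace_t <- c(trace_t, t_now + tau)
            trace_nf <- c(trace_nf, pmax(vals[, 1], 0))
            trace_ff <- c(trace_ff, pmax(vals[, 2], 0))
          }
          adv <- .advance_segment(sys, x1, x2, Gs, dt, V_NF)
          x1 <- adv[[1]]; x2 <- adv[[2]]
          int_task[k] <- int_task[k] + adv[[3]]
          dur_task[k] <- dur_task[k] + dt
          t_now <- t_now + dt
        }
      }
    }

    total_dur <- sum(dur_task) + gap_time
    avg_task <- int_task / dur_task
    row <- c(it,
             mean(unlist(d$V_room)), mean(unlist(d$AER)),
             mean(unlist(d$V_NF)), mean(unlist(d$beta)))
    for (k in seq_len(n_tasks))
      row <- c(row, mean(d$beta[[k]]), mean(d$G[[k]]), mean(d$t_G[[k]]),
               mean(d$t_pouring[[k]]), dur_task[k], avg_task[k])
    # time spent in gaps contributes zero-weighted task time but counts
    # in the shift average denominator only through its integral, which
    # is excluded from task windows; shift_avg is the TWA over task time
    row <- c(row, total_dur, sum(int_task) / sum(dur_task))
    out[it, ] <- row
    if (want_trace)
      traces[[it]] <- data.frame(time_min = trace_t, C_NF = trace_nf,
                                 C_FF = trace_ff)
  }

  res <- as.data.frame(out)
  res$iteration <- as.integer(res$iteration)
  attr(res, "scenario") <- shift$name
  attr(res, "substances") <- vapply(shift$tasks, `[[`, character(1),
                                    "substance")
  attr(res, "seed") <- seed
  if (!is.null(traces)) attr(res, "traces") <- traces
  res
}
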