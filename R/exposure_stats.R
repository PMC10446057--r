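#' Geometric mean and geometric standard deviation
#'
#' The conventional summary of right-skewed exposure distributions:
#' `GM = exp(mean(log(x)))` and `GSD = exp(sd(log(x)))` with the sample
#' (n-1) standard deviation.
#'
#' @param values positive numeric vector (n >= 2 for a GSD).
#' @return Named numeric vector `c(gm, gsd)`.
#' @examples
#' gm_gsd(c(1, 10))  # gm 3.162, gsd 5.095
#' @export
gm_gsd <- function(values) {
  if (!is.numeric(values) || length(values) < 1)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("all values must be positive and finite; offending indices: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  lv <- log(values)
  c(gm = exp(mean(lv)),
    gsd = if (length(values) >= 2) exp(stats::sd(lv)) else NA_real_)
}

#' Empirical percentile
#'
#' Linear-interpolation empirical quantile, convention fixed package-wide
#' to the Hyndman-Fan type 7 definition (position `(n-1)p + 1` between
#' order statistics), i.e. `stats::quantile(type = 7)`.
#'
#' @param values non-empty numeric vector.
#' @param p probability in (0, 1).
#' @return The p-th empirical percentile.
#' @examples
#' empirical_percentile(1:100, 0.95)  # 95.05
#' @export
empirical_percentile <- function(values, p) {
  if (!is.numeric(values) || length(values) == 0)
    stop("'values' must be non-empty", call. = FALSE)
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("'p' must be in (0, 1)", call. = FALSE)
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' 8-h time-weighted average concentration
#'
#' Averages task-level mean concentrations over the 8-h (480-min)
#' reference period, with zero exposure outside the modelled shift:
#' `TWA = sum(C_i * d_i) / 480`.
#'
#' @param task_averages mean concentrations per task, mg/m^3.
#' @param durations realized task durations, min (sum <= 480).
#' @return 8-h TWA, mg/m^3.
#' @export
twa_8h <- function(task_averages, durations) {
  if (length(task_averages) != length(durations))
    stop("'task_averages' and 'durations' must have equal length",
         call. = FALSE)
  if (any(durations < 0)) stop("durations must be >= 0", call. = FALSE)
  if (sum(durations) > 480)
    stop("total task time ", signif(sum(durations), 5),
         " min exceeds the 480-min TWA window", call. = FALSE)
  sum(task_averages * durations) / 480
}

#' Per-substance 8-h TWA attribution
#'
#' Attributes each task's contribution to the 8-h TWA to the substance
#' handled in that task (attribution is strictly by task window, so the
#' residual concentration tail of a previous substance inside a later
#' task window is credited to the later task's substance).
#'
#' @param task_averages mean concentrations per task, mg/m^3.
#' @param durations realized task durations, min.
#' @param substance_map character vector mapping each task to one
#'   substance label.
#' @return Named numeric vector of per-substance 8-h TWAs; sums to
#'   `twa_8h(task_averages, durations)`.
#' @export
substance_twa <- function(task_averages, durations, substance_map) {
  if (length(substance_map) != length(task_averages))
    stop("every task must be mapped to exactly one substance",
         call. = FALSE)
  if (anyNA(substance_map))
    stop("unmapped task (NA substance label)", call. = FALSE)
  contrib <- task_averages * durations / 480
  if (sum(durations) > 480)
    stop("total task time exceeds the 480-min TWA window", call. = FALSE)
  tapply(contrib, substance_map, sum)
}

# Per-iteration 8-h TWA from a Monte-Carlo results table, optionally for
# a subset of tasks (a substance's tasks).
.iteration_twa <- function(results, tasks = NULL) {
  n_tasks <- .n_tasks(results)
  if (is.null(tasks)) tasks <- seq_len(n_tasks)
  tw <- 0
  for (k in tasks)
    tw <- tw + results[[paste0("avg_task", k)]] *
      results[[paste0("dur_task", k)]]
  tw / 480
}

.n_tasks <- function(results) {
  ks <- grep("^avg_task[0-9]+$", names(results), value = TRUE)
  if (!length(ks)) stop("not a Monte-Carlo results table", call. = FALSE)
  max(as.integer(sub("avg_task", "", ks)))
}

#' Summarize a Monte-Carlo run into a scenario summary
#'
#' Computes GM, GSD and the 5th/95th/99th percentiles of the shift-average
#' NF concentration, 8-h TWA statistics in total and per substance, and
#' optionally the GM normalized to a reference scenario's GM.
#'
#' @param results data frame from [run_monte_carlo()].
#' @param substances character vector mapping tasks to substance labels;
#'   defaults to the `substances` attribute of `results`.
#' @param reference_gm GM of the reference scenario for normalization
#'   (optional).
#' @return A `scenario_summary` list: `scenario`, `n_iterations`, `gm`,
#'   `gsd`, `p5`, `p95`, `p99`, `normalized_gm`, `twa_gm`, `twa_p95`,
#'   and `twa_by_substance` (data frame with `substance`, `twa_gm`,
#'   `twa_p95`).
#' @export
summarize_scenario <- function(results, substances = NULL,
                               reference_gm = NULL) {
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  if (is.null(substances)) substances <- attr(results, "substances")
  sa <- results$shift_avg
  gg <- gm_gsd(sa)
  twa <- .iteration_twa(results)
  twa_gg <- gm_gsd(twa)
  by_sub <- NULL
  if (!is.null(substances)) {
    labs <- unique(substances)
    by_sub <- do.call(rbind, lapply(labs, function(s) {
      tv <- .iteration_twa(results, which(substances == s))
      data.frame(substance = s,
                 twa_gm = if (all(tv > 0)) unname(gm_gsd(tv)["gm"])
                          else mean(tv),
                 twa_p95 = empirical_percentile(tv, 0.95))
    }))
  }
  structure(list(
    scenario = attr(results, "scenario"),
    n_iterations = nrow(results),
    gm = unname(gg["gm"]), gsd = unname(gg["gsd"]),
    p5 = empirical_percentile(sa, 0.05),
    p95 = empirical_percentile(sa, 0.95),
    p99 = empirical_percentile(sa, 0.99),
    normalized_gm = if (is.null(reference_gm)) NA_real_
                    else unname(gg["gm"]) / reference_gm,
    twa_gm = unname(twa_gg["gm"]),
    twa_p95 = empirical_percentile(twa, 0.95),
    twa_by_substance = by_sub), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("Scenario '%s' (N = %d iterations)\n", x$scenario,
              x$n_iterations))
  cat(sprintf("  shift NF concentration: GM %.3f mg/m^3, GSD %.3f\n",
              x$gm, x$gsd))
  cat(sprintf("  percentiles: P5 %.3f, P95 %.3f, P99 %.3f mg/m^3\n",
              x$p5, x$p95, x$p99))
  if (!is.na(x$normalized_gm))
    cat(sprintf("  GM normalized to reference: %.2f\n", x$normalized_gm))
  cat(sprintf("  8-h TWA: GM %.3f, P95 %.3f mg/m^3\n", x$twa_gm, x$twa_p95))
  if (!is.null(x$twa_by_substance))
    for (i in seq_len(nrow(x$twa_by_substance)))
      cat(sprintf("    %s: TWA GM %.3f, TWA P95 %.3f mg/m^3\n",
                  x$twa_by_substance$substance[i],
                  x$twa_by_substance$twa_gm[i],
                  x$twa_by_substance$twa_p95[i]))
  invisible(x)
}

#' @rdname summarize_scenario
#' @param x a `scenario_summary`.
#' @param ... unused.
#' @export
as.data.frame.scenario_summary <- function(x, ...) {
  data.frame(scenario = if (is.null(x$scenario)) NA else x$scenario,
             n_iterations = x$n_iterations, gm = x$gm, gsd = x$gsd,
             p5 = x$p5, p95 = x$p95, p99 = x$p99,
             normalized_gm = x$normalized_gm,
             twa_gm = x$twa_gm, twa_p95 = x$twa_p95)
}
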