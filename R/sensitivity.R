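#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to relate each
#' exposure determinant (or task) to the simulated concentration level.
#' Returns `NA` when either vector is constant (undefined ranks spread).
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`, or `NA_real_` for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Job sensitivity: per-task contribution to shift exposure
#'
#' Decomposes the 8-h TWA shift concentration across tasks. The share of
#' the average is each task's mean TWA contribution
#' `mean(avg_task_k * dur_task_k)` normalized over tasks. The share of
#' variability is the covariance decomposition
#' `Cov(X_k, S) / Var(S)` with `X_k` the task's TWA contribution and
#' `S = sum_j X_j`; the shares sum to 100% exactly by construction
#' (covariances between tasks are attributed proportionally).
#'
#' @param results data frame from [run_monte_carlo()].
#' @return Data frame with `task`, `percent_of_average`,
#'   `percent_of_variability`.
#' @export
job_sensitivity <- function(results) {
  n_tasks <- .n_tasks(results)
  if (nrow(results) < 2)
    stop("variability decomposition needs at least 2 iterations",
         call. = FALSE)
  X <- sapply(seq_len(n_tasks), function(k)
    results[[paste0("avg_task", k)]] * results[[paste0("dur_task", k)]] / 480)
  S <- rowSums(X)
  pa <- 100 * colMeans(X) / sum(colMeans(X))
  pv <- 100 * apply(X, 2, function(x) stats::cov(x, S)) / stats::var(S)
  data.frame(task = seq_len(n_tasks), percent_of_average = pa,
             percent_of_variability = pv)
}

#' Task sensitivity: determinant correlations with task concentration
#'
#' For one task, computes the Spearman correlation between each sampled
#' determinant (per-iteration task-level mean of its draws) and the
#' task's time-average NF concentration, plus each determinant's share
#' of variability as the normalized squared correlation
#' `rho^2 / sum(rho^2) * 100` over the varying determinants.
#' Determinants held constant in the scenario are excluded (flagged in
#' the output) and the shares renormalize over the rest.
#'
#' @param results data frame from [run_monte_carlo()].
#' @param task task index.
#' @param determinants determinant names to assess; any of `"V_room"`,
#'   `"AER"`, `"V_NF"`, `"beta"`, `"G"`, `"t_G"`, `"t_pouring"`.
#' @return Data frame with `determinant`, `spearman_rho`,
#'   `percent_of_variability`, `excluded`.
#' @export
task_sensitivity <- function(results, task,
                             determinants = c("V_room", "AER", "V_NF",
                                              "beta", "G", "t_G",
                                              "t_pouring")) {
  n_tasks <- .n_tasks(results)
  if (!is.numeric(task) || task < 1 || task > n_tasks)
    stop("'task' must be a task index between 1 and ", n_tasks,
         call. = FALSE)
  y <- results[[paste0("avg_task", task)]]
  col_for <- function(d) {
    if (d %in% c("V_room", "AER", "V_NF")) d
    else paste0(d, "_task", task)
  }
  rho <- vapply(determinants, function(d) {
    x <- results[[col_for(d)]]
    if (is.null(x))
      stop("determinant '", d, "' not found in results", call. = FALSE)
    spearman_rho(x, y)
  }, numeric(1))
  excluded <- is.na(rho)
  if (any(excluded))
    message("constant determinant(s) excluded from variability shares: ",
            paste(determinants[excluded], collapse = ", "))
  share <- rep(NA_real_, length(rho))
  tot <- sum(rho[!excluded]^2)
  if (tot > 0) share[!excluded] <- 100 * rho[!excluded]^2 / tot
  data.frame(determinant = determinants, spearman_rho = unname(rho),
             percent_of_variability = share, excluded = excluded,
             row.names = NULL)
}
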