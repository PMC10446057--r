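#' Task specification
#'
#' One work task: a number of repetitions (e.g. bags poured), each with a
#' pouring duration `t_pouring`, an emission time `t_G <= t_pouring` and a
#' constant emission rate `G` while emitting. If a realized `t_G` exceeds
#' the realized `t_pouring` it is truncated (with a warning) rather than
#' rejected.
#'
#' @param name task label.
#' @param n_repetitions integer >= 1.
#' @param t_pouring distribution of the pouring duration per repetition,
#'   min.
#' @param t_G distribution of the emission duration per repetition, min.
#' @param G distribution of the emission rate, mg/min.
#' @param substance substance label used for per-substance 8-h TWA
#'   attribution (e.g. `"TiO2"`, `"MicroMica"`).
#' @return A `task_spec`.
#' @export
task_spec <- function(name, n_repetitions, t_pouring, t_G, G,
                      substance = "none") {
  if (!is.character(name) || length(name) != 1)
    stop("'name' must be a single string", call. = FALSE)
  if (!is.numeric(n_repetitions) || n_repetitions < 1 ||
      n_repetitions != round(n_repetitions))
    stop("task '", name, "': 'n_repetitions' must be an integer >= 1",
         call. = FALSE)
  structure(list(
    name = name,
    n_repetitions = as.integer(n_repetitions),
    t_pouring = as_dist_spec(t_pouring, paste0(name, ".t_pouring")),
    t_G = as_dist_spec(t_G, paste0(name, ".t_G")),
    G = as_dist_spec(G, paste0(name, ".G")),
    substance = substance), class = "task_spec")
}

.default_scopes <- function() {
  list(V_room = "per_shift", AER = "per_shift", V_NF = "per_shift",
       beta = "per_repetition", G = "per_repetition",
       t_G = "per_repetition", t_pouring = "per_repetition")
}

#' Shift specification
#'
#' The full scenario definition: environment distributions, an optional
#' local exhaust flow, the ordered task list and the sampling scopes that
#' state how often each determinant is redrawn (`"per_shift"`,
#' `"per_task"` or `"per_repetition"`).
#'
#' Default scopes follow the convention that the building-scale
#' determinants (`V_room`, `AER`, `V_NF`) are drawn once per shift while
#' the process-scale determinants (`beta`, `G`, `t_G`, `t_pouring`) are
#' redrawn for every repetition, i.e. every individual bag pour is an
#' independent realization of the local process conditions.
#'
#' @param name scenario label.
#' @param V_room,AER,V_NF,beta environment distributions (m^3, 1/h, m^3,
#'   m^3/min); scalars are treated as point values.
#' @param tasks list of [task_spec()]s (at least one).
#' @param Q_lev local exhaust flow from the NF, m^3/min (default 0).
#' @param gap zero-emission time inserted between consecutive tasks, min.
#' @param oelvs named list of occupational exposure limit values
#'   (mg/m^3 as 8-h TWA) keyed by substance label.
#' @param scopes named list overriding the default sampling scopes.
#' @param N_iterations default Monte-Carlo iteration count.
#' @param seed default random seed.
#' @param description free-text description.
#' @return A `shift_spec`.
#' @export
shift_spec <- function(name, V_room, AER, V_NF, beta, tasks,
                       Q_lev = 0, gap = 0, oelvs = list(),
                       scopes = list(), N_iterations = 10000L,
                       seed = NULL, description = "") {
  if (length(tasks) < 1) stop("at least one task is required", call. = FALSE)
  if (!all(vapply(tasks, inherits, logical(1), "task_spec")))
    stop("'tasks' must be a list of task_spec objects", call. = FALSE)
  .check_num(Q_lev, "Q_lev"); .check_num(gap, "gap")
  if (Q_lev < 0) stop("'Q_lev' must be >= 0", call. = FALSE)
  if (gap < 0) stop("'gap' must be >= 0", call. = FALSE)
  if (N_iterations < 1) stop("'N_iterations' must be >= 1", call. = FALSE)
  sc <- .default_scopes()
  for (nm in names(scopes)) {
    if (!nm %in% names(sc))
      stop("unknown scope parameter '", nm, "'", call. = FALSE)
    if (!scopes[[nm]] %in% c("per_shift", "per_task", "per_repetition"))
      stop("scope for '", nm, "' must be per_shift, per_task or ",
           "per_repetition", call. = FALSE)
    sc[[nm]] <- scopes[[nm]]
  }
  structure(list(
    name = name, description = description,
    V_room = as_dist_spec(V_room, "V_room"),
    AER = as_dist_spec(AER, "AER"),
    V_NF = as_dist_spec(V_NF, "V_NF"),
    beta = as_dist_spec(beta, "beta"),
    Q_lev = Q_lev, gap = gap, tasks = tasks,
    oelvs = oelvs, scopes = sc,
    N_iterations = as.integer(N_iterations), seed = seed),
    class = "shift_spec")
}

#' @export
print.shift_spec <- function(x, ...) {
  cat("Two-zone shift scenario:", x$name, "\n")
  cat("  V_room:", format(x$V_room), " AER:", format(x$AER),
      " V_NF:", format(x$V_NF), "\n")
  cat("  beta:", format(x$beta), " Q_lev:", x$Q_lev, "m^3/min\n")
  for (tk in x$tasks)
    cat(sprintf("  task '%s' (%s): %d reps, t_pouring %s, t_G %s, G %s\n",
                tk$name, tk$substance, tk$n_repetitions,
                format(tk$t_pouring), format(tk$t_G), format(tk$G)))
  invisible(x)
}

#' Load a scenario configuration from a YAML file
#'
#' The configuration mirrors [shift_spec()]: an `environment` block with
#' `V_room`, `AER`, `V_NF`, `beta` (each a number or a
#' `{kind: ..., ...}` mapping), optional `Q_lev` (default 0), `gap`,
#' `scopes`, `oelvs`, and a `tasks` sequence with `name`, `substance`,
#' `n_repetitions`, `t_pouring`, `t_G` and `G`. Validation errors name
#' the offending key.
#'
#' @param path path to a YAML file, or a pre-parsed list.
#' @return A [shift_spec()].
#' @export
load_scenario <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("scenario config must be a mapping", call. = FALSE)
  env <- cfg$environment
  if (is.null(env)) stop("missing 'environment' block", call. = FALSE)
  for (key in c("V_room", "AER", "V_NF", "beta"))
    if (is.null(env[[key]]))
      stop("missing environment parameter '", key, "'", call. = FALSE)
  if (is.null(cfg$tasks) || length(cfg$tasks) == 0)
    stop("missing 'tasks' block", call. = FALSE)
  tasks <- lapply(cfg$tasks, function(tk) {
    for (key in c("name", "n_repetitions", "t_pouring", "t_G", "G"))
      if (is.null(tk[[key]]))
        stop("task block missing field '", key, "'", call. = FALSE)
    task_spec(tk$name, tk$n_repetitions, tk$t_pouring, tk$t_G, tk$G,
              substance = if (is.null(tk$substance)) "none" else tk$substance)
  })
  shift_spec(
    name = if (is.null(cfg$name)) "scenario" else cfg$name,
    description = if (is.null(cfg$description)) "" else cfg$description,
    V_room = env$V_room, AER = env$AER, V_NF = env$V_NF, beta = env$beta,
    tasks = tasks,
    Q_lev = if (is.null(cfg$Q_lev)) 0 else cfg$Q_lev,
    gap = if (is.null(cfg$gap)) 0 else cfg$gap,
    oelvs = if (is.null(cfg$oelvs)) list() else cfg$oelvs,
    scopes = if (is.null(cfg$scopes)) list() else cfg$scopes,
    N_iterations = if (is.null(cfg$N_iterations)) 10000L else cfg$N_iterations,
    seed = cfg$seed)
}

#' Rescale an emission rate to a different emission-time resolution
#'
#' When the emission time is re-expressed on a coarser or finer time
#' base, the rate is adjusted so the released mass `G * t` is unchanged:
#' `G' = G * t_source / t_target`.
#'
#' @param G emission rate on the source time base, mg/min.
#' @param t_emit_source,t_emit_target emission durations, min (> 0).
#' @return Adjusted emission rate, mg/min.
#' @examples
#' rescale_emission(1.74, 0.5, 1.0)  # 0.87
#' @export
rescale_emission <- function(G, t_emit_source, t_emit_target) {
  .check_num(G, "G")
  .check_num(t_emit_source, "t_emit_source")
  .check_num(t_emit_target, "t_emit_target")
  if (t_emit_source <= 0 || t_emit_target <= 0)
    stop("emission times must be > 0", call. = FALSE)
  G * t_emit_source / t_emit_target
}

# Draw one iteration's determinants according to the sampling scopes.
# Environment parameters are returned per (task, repetition) so any scope
# is representable; uses the current RNG state.
sample_determinants <- function(shift) {
  stopifnot(inherits(shift, "shift_spec"))
  n_tasks <- length(shift$tasks)
  nrep <- vapply(shift$tasks, function(t) t$n_repetitions, integer(1))
  env_draw <- function(dist, scope) {
    if (scope == "per_shift") {
      rep(list(rep.int(draw_dist(dist, 1), max(nrep))), n_tasks)
    } else if (scope == "per_task") {
      lapply(nrep, function(n) rep.int(draw_dist(dist, 1), n))
    } else {
      lapply(nrep, function(n) draw_dist(dist, n))
    }
  }
  task_draw <- function(dists, scope) {
    if (scope == "per_shift") {
      # a single shared quantile across tasks would tie different
      # distributions together; per_shift here means one draw per task
      # distribution held fixed across its repetitions, as for per_task
      scope <- "per_task"
    }
    if (scope == "per_task") {
      mapply(function(d, n) rep.int(draw_dist(d, 1), n), dists, nrep,
             SIMPLIFY = FALSE)
    } else {
      mapply(function(d, n) draw_dist(d, n), dists, nrep, SIMPLIFY = FALSE)
    }
  }
  sc <- shift$scopes
  list(
    V_room = env_draw(shift$V_room, sc$V_room),
    AER = env_draw(shift$AER, sc$AER),
    V_NF = env_draw(shift$V_NF, sc$V_NF),
    beta = env_draw(shift$beta, sc$beta),
    G = task_draw(lapply(shift$tasks, `[[`, "G"), sc$G),
    t_G = task_draw(lapply(shift$tasks, `[[`, "t_G"), sc$t_G),
    t_pouring = task_draw(lapply(shift$tasks, `[[`, "t_pouring"),
                          sc$t_pouring))
}

#' Realize a sampled shift into an ordered emission schedule
#'
#' Expands one iteration's sampled determinant values into the ordered
#' list of constant-emission segments the two-zone solver consumes. Each
#' repetition contributes an emitting segment of length `t_G` at rate `G`
#' followed, when `t_pouring > t_G`, by a zero-emission segment for the
#' remainder of the repetition. Task windows are half-open intervals
#' `[start, end)` in shift minutes; configured inter-task gaps appear as
#' zero-emission segments assigned to no task (`task = NA`).
#'
#' @param shift a [shift_spec()].
#' @param draws determinant draws as produced by the internal sampler;
#'   when `NULL`, a fresh draw is taken from the current RNG state.
#' @return A data frame with one row per segment: `task`, `rep`,
#'   `duration`, `G`, `beta`, `V_room`, `AER`, `V_NF`, `emitting`.
#'   Attribute `windows` holds the task start/end times.
#' @export
realize_schedule <- function(shift, draws = NULL) {
  stopifnot(inherits(shift, "shift_spec"))
  if (is.null(draws)) draws <- sample_determinants(shift)
  n_tasks <- length(shift$tasks)
  rows <- list()
  nr <- 0
  add <- function(row) {
    nr <<- nr + 1
    rows[[nr]] <<- row
  }
  truncated <- FALSE
  t_now <- 0
  windows <- data.frame(task = seq_len(n_tasks), start = NA_real_,
                        end = NA_real_)
  for (k in seq_len(n_tasks)) {
    tk <- shift$tasks[[k]]
    if (k > 1 && shift$gap > 0) {
      add(list(task = NA_integer_, rep = NA_integer_, duration = shift$gap,
               G = 0, beta = draws$beta[[k]][1], V_room = draws$V_room[[k]][1],
               AER = draws$AER[[k]][1], V_NF = draws$V_NF[[k]][1],
               emitting = FALSE))
      t_now <- t_now + shift$gap
    }
    windows$start[k] <- t_now
    for (r in seq_len(tk$n_repetitions)) {
      tp <- draws$t_pouring[[k]][r]
      tG <- draws$t_G[[k]][r]
      if (tG > tp) { tG <- tp; truncated <- TRUE }
      G <- draws$G[[k]][r]
      env <- c(beta = draws$beta[[k]][r], V_room = draws$V_room[[k]][r],
               AER = draws$AER[[k]][r], V_NF = draws$V_NF[[k]][r])
      if (tG > 0)
        add(c(list(task = k, rep = r, duration = tG, G = G), as.list(env),
              list(emitting = TRUE)))
      if (tp - tG > 1e-12)
        add(c(list(task = k, rep = r, duration = tp - tG, G = 0),
              as.list(env), list(emitting = FALSE)))
      t_now <- t_now + tp
    }
    windows$end[k] <- t_now
  }
  if (truncated)
    warning("realized t_G exceeded t_pouring in at least one repetition; ",
            "emission time truncated to the pouring time", call. = FALSE)
  sched <- do.call(rbind, lapply(rows[seq_len(nr)], as.data.frame))
  attr(sched, "windows") <- windows
  sched
}
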