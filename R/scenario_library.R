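#' Packaged exposure-scenario library
#'
#' Eight ready-made powder-pouring scenarios: the observed paint-factory
#' shift and seven Conditions-of-Use variants (precautionary emission
#' rates, halved inter-zonal airflow, reduced general ventilation, a
#' 100 m^3 and a 10,000 m^3 room, a local exhaust at 9.6 m^3/min, and a
#' worst case combining the precautionary settings). The YAML sources
#' live in `system.file("extdata/scenarios", package = "twozone")`.
#'
#' @param name scenario name (see [scenario_names()]); for
#'   `scenario_library()` omit to load all eight.
#' @return `observed_scenario()` and `get_scenario()` return a
#'   [shift_spec()]; `scenario_library()` a named list of them.
#' @examples
#' observed_scenario()
#' scenario_names()
#' @export
scenario_library <- function() {
  dir <- system.file("extdata", "scenarios", package = "twozone")
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  specs <- lapply(files, load_scenario)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname scenario_library
#' @export
scenario_names <- function() {
  c("observed", "g_widened", "beta_halved", "aer_reduced", "small_room",
    "lev", "large_room", "worst_case")
}

#' @rdname scenario_library
#' @export
get_scenario <- function(name) {
  name <- match.arg(name, scenario_names())
  idx <- match(name, scenario_names())
  dir <- system.file("extdata", "scenarios", package = "twozone")
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  load_scenario(files[idx])
}

#' @rdname scenario_library
#' @export
observed_scenario <- function() {
  get_scenario("observed")
}
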