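#' Model-based risk characterization against an OELV
#'
#' In a probabilistic assessment the exposure risk is considered
#' well-controlled when the 95th percentile of the modelled exposure
#' distribution lies strictly below 10% of the occupational exposure
#' limit value; otherwise the scenario must be verified with personal
#' measurements.
#'
#' @param p95_twa 95th percentile of the 8-h TWA exposure distribution,
#'   mg/m^3 (> 0).
#' @param oelv occupational exposure limit value, mg/m^3 as 8-h TWA
#'   (> 0).
#' @return A `compliance_verdict` list: `ratio` (= p95/OELV),
#'   `well_controlled`, `verdict`, `action`.
#' @examples
#' model_risk_verdict(0.59, 5)  # ratio 0.118 -> measurements required
#' @export
model_risk_verdict <- function(p95_twa, oelv) {
  .check_num(p95_twa, "p95_twa"); .check_num(oelv, "oelv")
  if (p95_twa <= 0 || oelv <= 0)
    stop("'p95_twa' and 'oelv' must be > 0", call. = FALSE)
  ratio <- p95_twa / oelv
  ok <- ratio < 0.1  # strict: exactly 10% of the OELV is not controlled
  structure(list(
    ratio = ratio, well_controlled = ok,
    verdict = if (ok) "well_controlled" else "verify_with_measurements",
    action = if (ok)
      "Exposure is well-controlled (P95 below 10% of the OELV)."
    else
      "P95 is at or above 10% of the OELV; verify with personal measurements."),
    class = "compliance_verdict")
}

#' EN 689 periodic re-measurement interval
#'
#' Once compliance is concluded, measurements are repeated at an interval
#' set by the GM exposure relative to the OELV: below 0.1 OELV every 36
#' months, then 24, 18 and 12 months for the 0.1-0.25, 0.25-0.5 and
#' above-0.5 brackets. Bracket boundaries are resolved left-closed (a
#' ratio of exactly 0.1 falls in the 24-month bracket).
#'
#' @param gm_twa GM of the 8-h TWA exposure, mg/m^3 (> 0).
#' @param oelv limit value, mg/m^3 (> 0).
#' @return Re-measurement interval in months (36, 24, 18 or 12).
#' @export
en689_retest_interval <- function(gm_twa, oelv) {
  .check_num(gm_twa, "gm_twa"); .check_num(oelv, "oelv")
  if (gm_twa <= 0 || oelv <= 0)
    stop("'gm_twa' and 'oelv' must be > 0", call. = FALSE)
  r <- gm_twa / oelv
  if (r < 0.1) 36L else if (r < 0.25) 24L else if (r < 0.5) 18L else 12L
}

#' EN 689 preliminary (3-5 measurement) compliance test
#'
#' The screening test on a small set of personal measurements from one
#' similar exposure group: compliance is concluded when every value is at
#' or below 0.1, 0.15 or 0.2 of the OELV for sets of three, four or five
#' measurements respectively; otherwise the result is inconclusive and
#' more measurements are required.
#'
#' @param measurements 3 to 5 personal exposure values, mg/m^3.
#' @param oelv limit value, mg/m^3 (> 0).
#' @return List with `n`, `fraction` (the n-specific OELV fraction),
#'   `limit`, `compliant`, `verdict`.
#' @export
en689_preliminary_test <- function(measurements, oelv) {
  .check_num(oelv, "oelv")
  if (oelv <= 0) stop("'oelv' must be > 0", call. = FALSE)
  n <- length(measurements)
  if (n < 3 || n > 5)
    stop("the preliminary test requires 3 to 5 measurements; for 6 or ",
         "more use ucl70_p95_lognormal()", call. = FALSE)
  if (any(measurements < 0)) stop("measurements must be >= 0", call. = FALSE)
  fraction <- c(`3` = 0.1, `4` = 0.15, `5` = 0.2)[[as.character(n)]]
  limit <- fraction * oelv
  ok <- all(measurements <= limit)
  list(n = n, fraction = fraction, limit = limit, compliant = ok,
       verdict = if (ok) "compliant" else "inconclusive",
       action = if (ok) "OELV respected under the preliminary test."
       else "Inconclusive; additional measurements required.")
}

#' EN 689 statistical test: 70% UCL of the lognormal 95th percentile
#'
#' For at least six measurements, compliance is tested by comparing the
#' OELV with the 70% upper confidence limit of the 95th percentile of a
#' fitted lognormal distribution:
#' `UCL70 = exp(mean(log x) + k * sd(log x))` with the tolerance-limit
#' factor `k = t'_{0.70, n-1}(delta = z_0.95 * sqrt(n)) / sqrt(n)` from
#' the noncentral-t construction. Compliance is concluded when
#' `UCL70 < OELV`.
#'
#' @param measurements at least six positive exposure values, mg/m^3.
#' @param oelv limit value, mg/m^3 (optional; without it only the UCL is
#'   returned).
#' @return List with `ucl`, `k`, `gm`, `gsd`, `p95_estimate`, and (when
#'   `oelv` is given) `compliant` plus a `verdict`.
#' @export
ucl70_p95_lognormal <- function(measurements, oelv = NULL) {
  n <- length(measurements)
  if (n < 6)
    stop("the UCL70 test requires at least 6 measurements; use ",
         "en689_preliminary_test() for 3 to 5", call. = FALSE)
  if (any(!is.finite(measurements) | measurements <= 0))
    stop("all measurements must be positive", call. = FALSE)
  ly <- log(measurements)
  ybar <- mean(ly)
  s <- stats::sd(ly)
  z95 <- stats::qnorm(0.95)
  k <- stats::qt(0.70, df = n - 1, ncp = z95 * sqrt(n)) / sqrt(n)
  ucl <- exp(ybar + k * s)
  out <- list(ucl = ucl, k = k, gm = exp(ybar), gsd = exp(s),
              p95_estimate = exp(ybar + z95 * s))
  if (!is.null(oelv)) {
    .check_num(oelv, "oelv")
    if (oelv <= 0) stop("'oelv' must be > 0", call. = FALSE)
    out$compliant <- ucl < oelv
    out$verdict <- if (out$compliant) "compliant" else "non_compliant"
  }
  out
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("ratio to OELV: %.3f -> %s\n%s\n", x$ratio, x$verdict,
              x$action))
  invisible(x)
}
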