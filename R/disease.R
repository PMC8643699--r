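#' Area under the disease progress curve (AUDPC)
#'
#' Trapezoidal integral of disease severity (% canopy area diseased, 0-100)
#' over assessment days: `sum_i ((y_i + y_{i+1})/2) * (t_{i+1} - t_i)`,
#' in percent-days. The absolute AUDPC is returned by default; the relative
#' form divides by the maximum attainable value
#' `100 * (t_last - t_first)`.
#'
#' @param days assessment days (DAP), strictly increasing, length >= 2
#' @param severities per-day severities in `[0, 100]`, same length
#' @param relative return relative AUDPC in `[0, 1]` (default `FALSE`)
#' @return AUDPC in percent-days (or a unitless fraction if `relative`)
#' @examples
#' audpc(c(71, 86, 97), c(10, 20, 30))  # 500
#' @export
audpc <- function(days, severities, relative = FALSE) {
  check_num(days, "days"); check_num(severities, "severities")
  if (length(days) != length(severities)) stop_bad("severities", "length mismatch")
  if (length(days) < 2) stop_bad("days", "need at least 2 time points")
  if (any(diff(days) <= 0)) stop_bad("days", "must be strictly increasing")
  if (any(severities < 0 | severities > 100)) {
    stop_bad("severities", "must lie in [0, 100]")
  }
  n <- length(days)
  a <- sum((severities[-n] + severities[-1]) / 2 * diff(days))
  if (relative) a / (100 * (days[n] - days[1])) else a
}
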