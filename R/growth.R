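#' Smooth a height time series and extract growth rates
#'
#' Fits a cubic smoothing spline to weekly plant-height measurements and
#' reports the maximum growth rate (cm d^-1), the day it occurs, and the mean
#' growth rate `(last - first height) / elapsed days`. The derivative is
#' evaluated on a regular grid (default 50 points) spanning the observed
#' days and the maximum taken over the grid. Optionally the maximum is
#' restricted to the log-linear part of the curve, defined as days where a
#' 3-point rolling regression of log height on day has R^2 > 0.95.
#'
#' @param days days after planting, strictly increasing
#' @param heights plant heights, cm (>= 0), same length as `days`
#' @param spar smoothing parameter passed to [stats::smooth.spline()]
#'   (default 0.35); ignored when `df` is given
#' @param df optional target effective degrees of freedom instead of `spar`
#' @param ngrid number of derivative-grid points (default 50)
#' @param loglinear_only restrict the rate maximum to the log-linear window
#'   (default `FALSE`)
#' @return an object of class `growth_fit`: list with `max_rate`,
#'   `day_of_max`, `mean_rate`, `grid` (data.frame day/height/rate), the
#'   spline object `fit`, and `method` (`"spline"` or `"linear"` fallback for
#'   short series)
#' @examples
#' d <- seq(7, 70, by = 7)
#' h <- 160 / (1 + exp(-0.1 * (d - 43)))
#' fit_growth(d, h)$max_rate
#' @export
fit_growth <- function(days, heights, spar = 0.35, df = NULL, ngrid = 50,
                       loglinear_only = FALSE) {
  check_num(days, "days"); check_num(heights, "heights", nonneg = TRUE)
  if (length(days) != length(heights)) stop_bad("heights", "length mismatch")
  if (any(diff(days) <= 0)) stop_bad("days", "must be strictly increasing")
  n <- length(days)
  mean_rate <- (heights[n] - heights[1]) / (days[n] - days[1])

  if (n < 4) {
    warning("fewer than 4 points: piecewise-linear slopes used instead of a spline")
    slopes <- diff(heights) / diff(days)
    i <- which.max(slopes)
    return(structure(list(max_rate = slopes[i],
                          day_of_max = mean(days[i + 0:1]),
                          mean_rate = mean_rate,
                          grid = data.frame(day = days, height = heights,
                                            rate = c(slopes, slopes[n - 1])),
                          fit = NULL, method = "linear"),
                     class = "growth_fit"))
  }

  fit <- if (is.null(df)) stats::smooth.spline(days, heights, spar = spar)
         else stats::smooth.spline(days, heights, df = df)
  grid_days <- seq(min(days), max(days), length.out = ngrid)
  gh <- stats::predict(fit, grid_days)$y
  gr <- stats::predict(fit, grid_days, deriv = 1)$y

  keep <- rep(TRUE, ngrid)
  if (loglinear_only) {
    win <- loglinear_window(days, heights)
    if (any(win)) keep <- grid_days >= min(days[win]) & grid_days <= max(days[win])
  }
  i <- which(keep)[which.max(gr[keep])]
  structure(list(max_rate = gr[i], day_of_max = grid_days[i],
                 mean_rate = mean_rate,
                 grid = data.frame(day = grid_days, height = gh, rate = gr),
                 fit = fit, method = "spline"),
            class = "growth_fit")
}

# days where a centred 3-point fit of log(height) on day has R^2 > 0.95
loglinear_window <- function(days, heights, r2_min = 0.95) {
  n <- length(days)
  ok <- rep(FALSE, n)
  lh <- log(pmax(heights, .Machine$double.eps))
  for (i in 2:(n - 1)) {
    idx <- (i - 1):(i + 1)
    f <- stats::lm.fit(cbind(1, days[idx]), lh[idx])
    tss <- sum((lh[idx] - mean(lh[idx]))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(f$residuals^2) / tss
    if (r2 > r2_min) ok[idx] <- TRUE
  }
  ok
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth fit (%s): max rate %.2f cm/d at %.1f DAP; mean rate %.2f cm/d\n",
              x$method, x$max_rate, x$day_of_max, x$mean_rate))
  invisible(x)
}

#' Classify flowering phenology
#'
#' Maps pre-terminal flowering day (DAP) to one of three classes:
#' early (< 50 DAP), mid (50-70 DAP, closed interval), late (> 70 DAP).
#'
#' @param pre_terminal_day days after planting at pre-terminal flowering;
#'   vectorised, must be >= 0
#' @return factor with levels `early`, `mid`, `late`
#' @export
flowering_class <- function(pre_terminal_day) {
  check_num(pre_terminal_day, "pre_terminal_day", nonneg = TRUE)
  cut(pre_terminal_day, breaks = c(-Inf, 50, 70, Inf),
      labels = c("early", "mid", "late"), right = FALSE) ->
    cl
  # [50, 70] closed on both ends: move exactly-70 back to mid
  cl[pre_terminal_day == 70] <- "mid"
  factor(cl, levels = c("early", "mid", "late"))
}

#' Per-family flowering segregation summary
#'
#' Counts early/mid/late flowering classes within each family and reports
#' the closest simple segregation pattern among all-early, all-late, 1:1,
#' 2:1 and 3:1 (early:late, mid plants counted with late) by chi-square
#' distance. This is descriptive reporting, not a significance test.
#'
#' @param classes factor from [flowering_class()]
#' @param family_ids family identifiers, same length
#' @return data.frame with per-family counts, `n`, and `closest_ratio`
#' @export
segregation_counts <- function(classes, family_ids) {
  if (length(classes) != length(family_ids)) stop_bad("family_ids", "length mismatch")
  fam <- split(as.character(classes), family_ids)
  pats <- list("all-early" = 1, "all-late" = 0, "1:1" = 0.5,
               "2:1" = 2 / 3, "3:1" = 3 / 4)
  rows <- lapply(names(fam), function(f) {
    cl <- fam[[f]]
    n_early <- sum(cl == "early"); n_mid <- sum(cl == "mid"); n_late <- sum(cl == "late")
    n <- length(cl)
    n_lateish <- n - n_early
    # chi-square distance to each candidate early fraction
    d <- vapply(pats, function(p) {
      e_early <- p * n; e_late <- (1 - p) * n
      sum(c((n_early - e_early)^2 / max(e_early, 0.5),
            (n_lateish - e_late)^2 / max(e_late, 0.5)))
    }, numeric(1))
    data.frame(family = f, n = n, n_early = n_early, n_mid = n_mid,
               n_late = n_late, closest_ratio = names(pats)[which.min(d)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
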