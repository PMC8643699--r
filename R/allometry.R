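#' Model-II (and OLS) bivariate regression
#'
#' Fits a straight line to bivariate data by one of four methods commonly
#' used in allometry, all passing through the centroid:
#' \describe{
#'   \item{OLS}{ordinary least squares of y on x.}
#'   \item{MA}{major axis: first eigenvector of the covariance matrix
#'     (minimises perpendicular distances).}
#'   \item{SMA}{standardized major axis: `sign(r) * sd(y)/sd(x)`.}
#'   \item{RMA}{ranged major axis: both variables are standardized by their
#'     (min-max) ranges, an MA fit is performed in the standardized space,
#'     and the slope is back-transformed by `range(y)/range(x)`.}
#' }
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite
#' @param method one of `"OLS"`, `"MA"`, `"SMA"`, `"RMA"`
#' @return an object of class `model2_fit`: list with `method`, `slope`,
#'   `intercept`, `r_squared` (squared Pearson correlation), `n`,
#'   `slope_ci` (approximate 95\% interval from the SMA standard error
#'   formulation, reported for all methods).
#' @examples
#' x <- c(0, 1, 2); y <- 2 * x + 1
#' model2_regress(x, y, "RMA")$slope
#' @export
model2_regress <- function(x, y, method = c("RMA", "OLS", "MA", "SMA")) {
  method <- match.arg(toupper(method[1]), c("RMA", "OLS", "MA", "SMA"))
  check_num(x, "x"); check_num(y, "y")
  if (length(x) != length(y)) stop_bad("y", "x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_bad("x", "need n >= 3")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0) stop_bad("x", "zero variance")
  if (sy == 0) stop_bad("y", "zero variance")
  r <- stats::cor(x, y)

  slope <- switch(method,
    OLS = stats::cov(x, y) / sx^2,
    MA  = ma_slope(x, y),
    SMA = sign_or_pos(r) * sy / sx,
    RMA = {
      rx <- diff(range(x)); ry <- diff(range(y))
      if (rx == 0 || ry == 0) stop_bad("x", "zero range")
      ma_slope((x - min(x)) / rx, (y - min(y)) / ry) * ry / rx
    }
  )
  intercept <- mean(y) - slope * mean(x)

  # 95% CI via the SMA slope-variance formulation (Jolicoeur-style),
  # adequate for all line-fitting methods at the sample sizes used here
  se_factor <- sqrt((1 - r^2) / max(n - 2, 1))
  tcrit <- stats::qt(0.975, df = max(n - 2, 1))
  B <- tcrit * se_factor
  ci <- abs(slope) * c(sqrt(B^2 + 1) - B, sqrt(B^2 + 1) + B) * sign_or_pos(slope)
  structure(list(method = method, slope = slope, intercept = intercept,
                 r_squared = r^2, n = n, slope_ci = sort(ci)),
            class = "model2_fit")
}

sign_or_pos <- function(r) if (r < 0) -1 else 1

# MA slope from the leading eigenvector of the 2x2 covariance matrix
ma_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) return(0)
  d <- syy - sxx
  lambda <- (sxx + syy + sqrt(d^2 + 4 * sxy^2)) / 2
  (lambda - sxx) / sxy
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("%s fit (n=%d): slope %.4f [%.4f, %.4f], intercept %.4f, R^2 %.3f\n",
              x$method, x$n, x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$r_squared))
  invisible(x)
}

#' Log-log allometric fit
#'
#' Applies [model2_regress()] to `log10(x)` and `log10(y)`. The slope is the
#' allometric scaling exponent (base-invariant); the intercept is reported in
#' base-10 log units.
#'
#' @inheritParams model2_regress
#' @return a `model2_fit` on the log10 scale
#' @export
fit_loglog <- function(x, y, method = "RMA") {
  bad <- which(!(is.finite(x) & is.finite(y) & x > 0 & y > 0))
  if (length(bad)) {
    stop_bad("x/y", paste("nonpositive or non-finite values at indices:",
                          paste(utils::head(bad, 10), collapse = ", ")))
  }
  model2_regress(log10(x), log10(y), method)
}

#' Leafing intensity
#'
#' Number of leaves per unit primary stem volume (count cm^-3).
#'
#' @param leaf_count whole-plant leaf count (>= 0)
#' @param stem_volume_cm3 primary stem volume, cm^3 (> 0)
#' @export
leafing_intensity <- function(leaf_count, stem_volume_cm3) {
  check_num(leaf_count, "leaf_count", nonneg = TRUE)
  check_num(stem_volume_cm3, "stem_volume_cm3", positive = TRUE)
  leaf_count / stem_volume_cm3
}

#' Primary stem volume
#'
#' Conical volume from basal stem diameter and plant height:
#' `(1/3) * pi * (dia/2)^2 * ht`, cm^3. The cone (tapering stem) rather than
#' a cylinder is used; see the methods vignette.
#'
#' @param dia_cm basal stem diameter, cm (> 0)
#' @param ht_cm plant height, cm (> 0)
#' @param shape `"cone"` (default) or `"cylinder"`
#' @export
stem_volume <- function(dia_cm, ht_cm, shape = c("cone", "cylinder")) {
  shape <- match.arg(shape)
  check_num(dia_cm, "dia_cm", positive = TRUE)
  check_num(ht_cm, "ht_cm", positive = TRUE)
  v <- pi * (dia_cm / 2)^2 * ht_cm
  if (shape == "cone") v / 3 else v
}

#' Specific leaf / petiole area
#'
#' Area per unit dry mass, cm^2 g^-1 (SLA when applied to leaves, SPA to
#' petioles).
#'
#' @param area_cm2 area, cm^2 (>= 0)
#' @param dry_weight_g dry weight, g (> 0)
#' @export
specific_area <- function(area_cm2, dry_weight_g) {
  check_num(area_cm2, "area_cm2", nonneg = TRUE)
  check_num(dry_weight_g, "dry_weight_g", positive = TRUE)
  area_cm2 / dry_weight_g
}

#' Pointed-oval leaflet area
#'
#' Area of the middle leaflet modelled as a pointed oval (parabolic lens):
#' `(2/3) * length * width`. The constant is configurable; 2/3 is the
#' parabolic-lens value.
#'
#' @param length_cm leaflet length, cm (>= 0)
#' @param width_cm maximum leaflet width, cm (>= 0)
#' @param constant area constant, default `2/3`
#' @export
pointed_oval_area <- function(length_cm, width_cm, constant = 2 / 3) {
  check_num(length_cm, "length_cm", nonneg = TRUE)
  check_num(width_cm, "width_cm", nonneg = TRUE)
  constant * length_cm * width_cm
}

#' Green leaf index of a masked RGB image
#'
#' Mean over masked (foreground) pixels of the per-pixel green leaf index
#' `(2G - R - B) / (2G + R + B)`. Pixels with a zero denominator are
#' excluded from the mean and counted.
#'
#' @param rgb numeric array `h x w x 3` (any common channel scale)
#' @param mask logical matrix `h x w`; `TRUE` = foreground
#' @return list with `gli` (mean index), `n_pixels` (used) and
#'   `n_zero_denom` (excluded)
#' @export
green_leaf_index <- function(rgb, mask) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) stop_bad("rgb", "must be an h x w x 3 array")
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop_bad("mask", "empty mask")
  r <- rgb[, , 1][mask]; g <- rgb[, , 2][mask]; b <- rgb[, , 3][mask]
  den <- 2 * g + r + b
  zero <- den == 0
  vals <- (2 * g - r - b)[!zero] / den[!zero]
  if (!length(vals)) stop_bad("mask", "all masked pixels have zero denominator")
  list(gli = mean(vals), n_pixels = sum(!zero), n_zero_denom = sum(zero))
}
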