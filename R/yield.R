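#' Reference wet-to-dry biomass calibration
#'
#' The packaged reference calibration relating whole-plant wet biomass (WBM,
#' kg) to whole-plant dry biomass (DBM) and dry stripped floral biomass
#' (DSBM), estimated from 34 representative harvested individuals:
#' `DBM = -0.13322 + 0.31174 * WBM` (residual sd 0.1446) and
#' `DSBM = 0.113884 + 0.156749 * WBM` (residual sd 0.1031).
#'
#' @return object of class `biomass_calibration`
#' @export
reference_biomass_calibration <- function() {
  structure(list(
    dbm = list(intercept = -0.13322, slope = 0.31174, residual_sd = 0.1446),
    dsbm = list(intercept = 0.113884, slope = 0.156749, residual_sd = 0.1031),
    n_calibration = 34L, source = "reference"
  ), class = "biomass_calibration")
}

#' Fit a wet-to-dry biomass calibration
#'
#' OLS fits of dry biomass and dry stripped floral biomass on wet biomass,
#' with residual standard deviations, for use with [predict_biomass()].
#'
#' @param wbm wet biomass, kg
#' @param dbm whole-plant dry biomass, kg (same length)
#' @param dsbm optional dry stripped floral biomass, kg
#' @return a `biomass_calibration`
#' @export
fit_biomass_calibration <- function(wbm, dbm, dsbm = NULL) {
  check_num(wbm, "wbm"); check_num(dbm, "dbm")
  if (length(wbm) < 3) stop_bad("wbm", "need n >= 3")
  if (stats::sd(wbm) == 0) stop_bad("wbm", "zero variance")
  fit1 <- function(y) {
    f <- stats::lm(y ~ wbm)
    list(intercept = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2]),
         residual_sd = stats::sigma(f))
  }
  structure(list(dbm = fit1(dbm),
                 dsbm = if (is.null(dsbm)) NULL else fit1(dsbm),
                 n_calibration = length(wbm), source = "fitted"),
            class = "biomass_calibration")
}

#' @export
print.biomass_calibration <- function(x, ...) {
  cat(sprintf("biomass calibration (%s, n=%d)\n", x$source, x$n_calibration))
  cat(sprintf("  DBM  = %.5f + %.5f * WBM  (sd %.4f)\n",
              x$dbm$intercept, x$dbm$slope, x$dbm$residual_sd))
  if (!is.null(x$dsbm)) {
    cat(sprintf("  DSBM = %.5f + %.5f * WBM  (sd %.4f)\n",
                x$dsbm$intercept, x$dsbm$slope, x$dsbm$residual_sd))
  }
  invisible(x)
}

#' Predict dry and stripped biomass from wet biomass
#'
#' Linear prediction from a [fit_biomass_calibration()] or the packaged
#' [reference_biomass_calibration()], clamped below at zero.
#'
#' @param wbm wet biomass, kg (>= 0); vectorised
#' @param cal a `biomass_calibration` (default: the reference calibration)
#' @return data.frame with columns `wbm`, `dbm` and (if calibrated) `dsbm`
#' @examples
#' predict_biomass(6.31)  # dbm ~ 1.83, dsbm ~ 1.10
#' @export
predict_biomass <- function(wbm, cal = reference_biomass_calibration()) {
  stopifnot(inherits(cal, "biomass_calibration"))
  check_num(wbm, "wbm", nonneg = TRUE)
  out <- data.frame(wbm = wbm,
                    dbm = pmax(0, cal$dbm$intercept + cal$dbm$slope * wbm))
  if (!is.null(cal$dsbm)) {
    out$dsbm <- pmax(0, cal$dsbm$intercept + cal$dsbm$slope * wbm)
  }
  out
}

#' Total potential cannabinoid percentage
#'
#' Combines neutral and acid forms of a cannabinoid into the total potential
#' percentage, scaling the acid form by the molar-mass decarboxylation
#' factor: `total = neutral + f * acid`. Defaults: 0.877 for pentyl
#' cannabinoids (THC, CBD, CBC, CBG, CBL) and 0.867 for the propyl (varin)
#' series (THCV, CBDV).
#'
#' @param neutral_pct neutral-form percentage (>= 0); vectorised
#' @param acid_pct acid-form percentage (>= 0)
#' @param compound compound code used to pick the default factor
#' @param f override decarboxylation factor (set 1 for a simple sum)
#' @return total potential percentage
#' @export
total_potential <- function(neutral_pct, acid_pct,
                            compound = c("THC", "CBD", "CBC", "CBG", "CBL",
                                         "THCV", "CBDV"),
                            f = NULL) {
  compound <- match.arg(compound)
  check_num(neutral_pct, "neutral_pct", nonneg = TRUE)
  check_num(acid_pct, "acid_pct", nonneg = TRUE)
  if (is.null(f)) f <- if (compound %in% c("THCV", "CBDV")) 0.867 else 0.877
  neutral_pct + f * acid_pct
}

#' Cannabinoid yield per plant
#'
#' Grams of cannabinoid per plant: summed total-potential percentages times
#' dry stripped floral biomass, `(sum(totals)/100) * dsbm_kg * 1000`.
#'
#' @param total_pcts vector of total-potential percentages (summed)
#' @param dsbm_kg dry stripped floral biomass, kg (>= 0)
#' @return grams
#' @export
cannabinoid_yield <- function(total_pcts, dsbm_kg) {
  check_num(total_pcts, "total_pcts", nonneg = TRUE)
  check_num(dsbm_kg, "dsbm_kg", nonneg = TRUE)
  sum(total_pcts) / 100 * dsbm_kg * 1000
}

#' Stepwise AIC predictor selection
#'
#' Bidirectional stepwise search over an OLS model by AIC, starting from the
#' full model (criterion `n*log(RSS/n) + 2*edf`, as used by
#' [stats::step()]). Aliased (perfectly collinear) columns are dropped with
#' a warning before the search.
#'
#' @param y response vector
#' @param X data.frame or matrix of candidate predictors
#' @return list with `selected` (character vector of kept predictors),
#'   `fit` (the final `lm`), `aic`
#' @export
stepwise_aic <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n <= ncol(X) + 2) stop_bad("X", "need n > p + 2")
  dat <- cbind(data.frame(.y = y), X)
  full <- stats::lm(.y ~ ., data = dat)
  alias <- names(which(is.na(stats::coef(full))))
  if (length(alias)) {
    warning(sprintf("dropping aliased predictor(s): %s", paste(alias, collapse = ", ")))
    X <- X[, setdiff(names(X), alias), drop = FALSE]
    dat <- cbind(data.frame(.y = y), X)
    full <- stats::lm(.y ~ ., data = dat)
  }
  sel <- stats::step(full, scope = list(lower = .y ~ 1, upper = stats::formula(full)),
                     direction = "both", trace = 0)
  list(selected = attr(stats::terms(sel), "term.labels"),
       fit = sel,
       aic = stats::extractAIC(sel)[2])
}

#' LMG relative-importance decomposition of R-squared
#'
#' Decomposes the R-squared of the multiple regression of `y` on the columns
#' of `X` into nonnegative per-predictor shares by the LMG method: the share
#' of predictor j is its sequential increase in R-squared averaged over all
#' orderings of the predictors. Computed exactly by enumerating subsets with
#' combinatorial weights (the average over p! orderings collapses to a
#' weighted sum over the 2^(p-1) subsets not containing j). Shares sum to
#' the full-model R-squared. Optional case-resampling bootstrap percentile
#' CIs at a Bonferroni-adjusted level `1 - alpha/p`.
#'
#' @param y response
#' @param X data.frame/matrix of predictors; `ncol(X) <= 12` for exact
#'   enumeration
#' @param n_boot bootstrap replicates (0 = no CIs; default 0)
#' @param alpha family-wise error rate for the Bonferroni CIs (default 0.05)
#' @param seed RNG seed for the bootstrap
#' @return list with `shares` (named vector), `r_squared` (full model),
#'   `ci` (matrix or NULL), `n_boot`, `seed`
#' @export
lmg <- function(y, X, n_boot = 0, alpha = 0.05, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) stop_bad("X", "need at least one predictor")
  if (p > 12) stop_bad("X", "exact LMG enumeration limited to p <= 12")
  if (qr(cbind(1, X))$rank < p + 1) stop_bad("X", "singular design")
  shares <- lmg_shares(y, X)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(y)
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(lmg_shares(y[idx], X[idx, , drop = FALSE]),
               error = function(e) rep(NA_real_, p))
    })
    lev <- alpha / p   # Bonferroni across predictors
    ci <- t(apply(boots, 1, stats::quantile,
                  probs = c(lev / 2, 1 - lev / 2), na.rm = TRUE))
    rownames(ci) <- colnames(X)
  }
  list(shares = shares, r_squared = sum(shares), ci = ci,
       n_boot = n_boot, seed = seed)
}

# R^2 of y on the columns of X indexed by `idx` (empty set -> 0)
subset_r2 <- function(y, X, idx) {
  if (!length(idx)) return(0)
  f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

lmg_shares <- function(y, X) {
  p <- ncol(X)
  cols <- colnames(X) %||% paste0("x", seq_len(p))
  # precompute R^2 for all subsets, keyed by bitmask
  r2 <- numeric(2^p)
  for (m in 1:(2^p - 1)) {
    r2[m + 1] <- subset_r2(y, X, which(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0))
  }
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1, j - 1)
    acc <- 0
    for (m in 0:(2^p - 1)) {
      if (bitwAnd(m, bit) > 0) next
      s <- sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0)
      wt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      acc <- acc + wt * (r2[bitwOr(m, bit) + 1] - r2[m + 1])
    }
    shares[j] <- acc
  }
  names(shares) <- cols
  shares
}
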