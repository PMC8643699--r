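test_that("biomass calibration is exact on proportional data and recovers printed slopes", {
  w <- seq(1, 10, length.out = 20)
  cal <- fit_biomass_calibration(w, 0.3 * w)
  expect_equal(cal$dbm$slope, 0.3, tolerance = 1e-10)
  expect_equal(cal$dbm$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$dbm$residual_sd, 0, tolerance = 1e-8)

  # regenerate from the packaged model at its stated noise and sample size
  set.seed(12)
  ref <- reference_biomass_calibration()
  w34 <- runif(34, 1.2, 13)
  d34 <- ref$dbm$intercept + ref$dbm$slope * w34 + rnorm(34, 0, ref$dbm$residual_sd)
  fit <- fit_biomass_calibration(w34, d34)
  se <- ref$dbm$residual_sd / (sd(w34) * sqrt(33))
  expect_lt(abs(fit$dbm$slope - ref$dbm$slope), 2.1 * se)

  expect_error(fit_biomass_calibration(rep(2, 5), 1:5), "zero variance")
  expect_error(fit_biomass_calibration(1:2, 1:2), "n >= 3")
})

test_that("the reference calibration reproduces the population-mean biomass values", {
  p <- predict_biomass(6.31)
  expect_equal(p$dbm, 1.84, tolerance = 0.01)
  expect_equal(p$dsbm, 1.11, tolerance = 0.01)
  expect_equal(predict_biomass(0)$dbm, 0)      # raw -0.13322 clamped
  expect_error(predict_biomass(-1), "wbm")
})

test_that("biomass predictions are monotone and cross as the printed lines do", {
  w <- seq(0, 14, by = 0.25)
  p <- predict_biomass(w)
  expect_true(all(diff(p$dbm) >= 0))
  expect_true(all(diff(p$dsbm) >= 0))
  crossing <- (0.113884 - (-0.13322)) / (0.31174 - 0.156749)
  above <- w > crossing + 0.26     # clear of the clamp region
  expect_true(all(p$dsbm[above] < p$dbm[above]))
})

test_that("total potential cannabinoid combines acid and neutral forms", {
  expect_equal(total_potential(0.5, 10, "CBD"), 0.5 + 0.877 * 10)
  expect_equal(total_potential(3, 0, "THC"), 3)
  expect_equal(total_potential(1, 2, "CBDV"), 1 + 0.867 * 2)
  expect_equal(total_potential(1, 2, "THC", f = 1), 3)
  expect_equal(total_potential(0, 0, "CBC"), 0)
  expect_error(total_potential(-1, 2, "THC"), "neutral")
  # linear in both arguments
  expect_equal(total_potential(2, 4, "CBD"), 2 * total_potential(1, 2, "CBD"))
})

test_that("cannabinoid yield arithmetic matches the population means", {
  totals <- c(1.19, 8.73, 0.52, 0.27, 0.03, 0.16, 0.04)
  y <- cannabinoid_yield(totals, 1.11)
  expect_equal(y, 120, tolerance = 0.025)
  expect_equal(cannabinoid_yield(totals, 0), 0)
  expect_equal(cannabinoid_yield(10, 1), 100)
})

test_that("stepwise AIC keeps the informative predictor and drops noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("x", 1:6)
    y <- 3 * X$x1 + rnorm(n)
    sel <- stepwise_aic(y, X)$selected
    "x1" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # pure noise: the intercept-only model is the modal outcome
  set.seed(123)
  sizes <- replicate(300, {
    X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
    y <- rnorm(200)
    length(stepwise_aic(y, X)$selected)
  })
  tab <- table(sizes)
  expect_equal(names(tab)[which.max(tab)], "0")

  # single informative predictor: identical to the full model
  set.seed(5)
  X1 <- data.frame(x1 = rnorm(100))
  y1 <- 2 * X1$x1 + rnorm(100, 0, 0.1)
  expect_equal(stepwise_aic(y1, X1)$selected, "x1")
})

test_that("aliased columns are dropped with a warning before the search", {
  set.seed(8)
  X <- data.frame(a = rnorm(100))
  X$b <- 2 * X$a
  y <- X$a + rnorm(100)
  expect_warning(sw <- stepwise_aic(y, X), "aliased")
  expect_true("a" %in% sw$selected || "b" %in% sw$selected)
})

test_that("LMG shares for orthogonal predictors split R2 equally", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  y <- x1 + x2          # noiseless, orthogonal, equal marginal R2
  l <- lmg(y, cbind(x1, x2))
  expect_equal(unname(l$shares), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(l$r_squared, 1, tolerance = 1e-10)
})

test_that("LMG for two correlated predictors matches the two-ordering closed form", {
  set.seed(19)
  x1 <- rnorm(120)
  x2 <- 0.6 * x1 + rnorm(120, 0, 0.8)
  y <- x1 + 0.5 * x2 + rnorm(120)
  X <- cbind(x1, x2)
  l <- lmg(y, X)
  r2 <- function(idx) summary(lm(y ~ X[, idx, drop = FALSE]))$r.squared
  expect_equal(unname(l$shares[1]),
               0.5 * r2(1) + 0.5 * (r2(1:2) - r2(2)), tolerance = 1e-10)
})

test_that("LMG subset-weight formula equals brute-force ordering average at p = 4", {
  set.seed(9)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("x", 1:4)
  y <- as.numeric(X %*% c(1, 0.5, 0, 0.2) + rnorm(n))
  l <- lmg(y, X)
  expect_equal(unname(l$shares), lmg_bruteforce(y, X), tolerance = 1e-10)
  expect_true(all(l$shares >= -1e-12))
  expect_equal(sum(l$shares), summary(lm(y ~ X))$r.squared, tolerance = 1e-9)
})

test_that("LMG bootstrap CIs cover the point estimates and errors on bad input", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2)
  colnames(X) <- c("a", "b")
  y <- X[, 1] + rnorm(100)
  l <- lmg(y, X, n_boot = 100, seed = 5)
  expect_equal(dim(l$ci), c(2L, 2L))
  expect_true(all(l$shares >= l$ci[, 1] - 1e-9 & l$shares <= l$ci[, 2] + 1e-9))
  Xs <- cbind(X, X[, 1])
  expect_error(lmg(y, Xs), "singular")
})
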