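test_that("square kite reproduces the analytic benchmark values", {
  k <- build_kite(ht = 100, mcd = 100, mcdh = 50, trkl = 0)
  expect_equal(k$a, 50)
  expect_equal(k$b, 50)
  expect_equal(k$w, 50)
  expect_equal(k$area_m2, 0.5)
  expect_equal(k$hyp_ratio, 1)
  expect_equal(k$branch_angle_deg, 45)
  expect_equal(k$circularity, pi / 4)
  expect_equal(kite_volume(k), (pi / 3) * 0.25 * 1.0, tolerance = 1e-12)
})

test_that("kite traits at the population-mean measurements match hand arithmetic", {
  k <- build_kite(ht = 157.7, mcd = 125.9, mcdh = 85.9, trkl = 12.2)
  expect_equal(k$area_m2, 0.916, tolerance = 1e-3)
  expect_equal(k$branch_angle_deg, 40.5, tolerance = 1e-2)
  expect_equal(k$hyp_ratio, 0.985, tolerance = 1e-3)
  expect_equal(k$circularity, 0.777, tolerance = 1e-3)
})

test_that("degenerate kites are rejected naming the offending field", {
  expect_error(build_kite(100, 100, 100, 0), "mcdh")
  expect_error(build_kite(100, 100, 10, 10), "mcdh")
  expect_error(build_kite(100, 100, 5, 10), "mcdh")
  expect_error(build_kite(-1, 100, 50, 0), "ht")
  expect_error(build_kite(100, 0, 50, 0), "mcd")
})

test_that("branch angle covers isoceles, hand-computed, and columnar cases", {
  expect_equal(kite_branch_angle_45 <- build_kite(100, 100, 50, 0)$branch_angle_deg, 45)
  expect_equal(atan(62.95 / 73.7) * 180 / pi, 40.5, tolerance = 0.01)
  # columnar limit: narrow canopy, angle tends to zero
  narrow <- build_kite(100, 0.2, 50, 0)
  expect_lt(narrow$branch_angle_deg, 0.2)
})

test_that("derived per-plant quantities are simple exact ratios", {
  k <- build_kite(100, 100, 50, 0)
  expect_equal(canopy_density(0, k), 0)
  expect_equal(canopy_density(1, k), 1 / 0.2617994, tolerance = 1e-6)
  k2 <- build_kite(200, 200, 100, 0)  # volume x8
  expect_equal(canopy_density(1, k2), canopy_density(1, k) / 8, tolerance = 1e-12)

  expect_equal(specific_kite_area(k, 1), 0.5)
  km <- build_kite(157.7, 125.9, 85.9, 12.2)
  expect_equal(specific_kite_area(km, 1.84), 0.498, tolerance = 1e-3)
  expect_error(specific_kite_area(k, 0), "biomass")

  expect_equal(floral_biomass_per_area(1.11, 125.9), 0.700, tolerance = 1e-3)
  expect_equal(floral_biomass_per_area(0, 50), 0)
  expect_equal(floral_biomass_per_area(2.5, 100), 2.5)
  expect_error(floral_biomass_per_area(1, 0), "mcd")

  expect_equal(internode_length(10), 5)
  expect_equal(internode_length(7.45), 6.71, tolerance = 1e-3)
  expect_equal(internode_length(4), 12.5)
  expect_error(internode_length(0.5), "bpair")
})

test_that("circularity is bounded by pi/4 with equality only at the square kite", {
  set.seed(11)
  for (i in 1:200) {
    ht <- runif(1, 50, 300)
    mcdh <- runif(1, 0.1, 0.9) * ht
    trkl <- runif(1, 0, 0.9) * mcdh
    mcd <- runif(1, 10, 300)
    k <- build_kite(ht, mcd, mcdh, trkl)
    expect_lte(k$circularity, pi / 4 + 1e-12)
  }
  # equality iff a = b = w
  sq <- build_kite(100, 100, 50, 0)
  expect_equal(sq$circularity, pi / 4)
  off <- build_kite(100, 99, 50, 0)
  expect_lt(off$circularity, pi / 4)
})

test_that("circularity of symmetric kites is unimodal with maximum at 45 degrees", {
  angles <- seq(0.5, 89.5, by = 0.01)
  circ <- vapply(angles, function(th) {
    a <- 50
    w <- a * tan(th * pi / 180)
    k <- build_kite(ht = 2 * a, mcd = 2 * w, mcdh = a, trkl = 0)
    k$circularity
  }, numeric(1))
  expect_equal(angles[which.max(circ)], 45, tolerance = 0.1)
  expect_equal(max(circ), pi / 4, tolerance = 1e-6)
  # unimodality: increasing then decreasing
  d <- diff(circ)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
})

test_that("shape traits are scale invariant and size traits scale by degree", {
  k1 <- build_kite(157.7, 125.9, 85.9, 12.2)
  k2 <- build_kite(3 * 157.7, 3 * 125.9, 3 * 85.9, 3 * 12.2)
  expect_equal(k2$circularity, k1$circularity, tolerance = 1e-12)
  expect_equal(k2$hyp_ratio, k1$hyp_ratio, tolerance = 1e-12)
  expect_equal(k2$branch_angle_deg, k1$branch_angle_deg, tolerance = 1e-12)
  expect_equal(k2$area_m2, 9 * k1$area_m2, tolerance = 1e-12)
  expect_equal(k2$volume_m3, 27 * k1$volume_m3, tolerance = 1e-12)
  # doubling canopy width quadruples the bicone volume at fixed heights
  kw <- build_kite(157.7, 2 * 125.9, 85.9, 12.2)
  expect_equal(kw$volume_m3, 4 * k1$volume_m3, tolerance = 1e-12)
})

test_that("kite area equals the shoelace area of the four vertices", {
  set.seed(5)
  for (i in 1:50) {
    ht <- runif(1, 60, 250)
    mcdh <- runif(1, 0.2, 0.8) * ht
    trkl <- runif(1, 0, 0.8) * mcdh
    mcd <- runif(1, 30, 250)
    k <- build_kite(ht, mcd, mcdh, trkl)
    xs <- c(0, mcd / 2, 0, -mcd / 2)
    ys <- c(trkl, mcdh, ht, mcdh)
    expect_equal(k$area_m2 * 1e4, shoelace_area(xs, ys), tolerance = 1e-9)
  }
})

test_that("derive_kite_traits appends trait columns and NA-flags bad rows", {
  tab <- data.frame(HT = c(100, 100), MCD = c(100, 100),
                    MCDH = c(50, 100), TRKL = c(0, 0), BPAIR = c(10, 5))
  expect_warning(out <- derive_kite_traits(tab), "1 row")
  expect_equal(out$KITE[1], 0.5)
  expect_true(is.na(out$KITE[2]))
  expect_equal(out$INL, c(5, 10))
  expect_error(derive_kite_traits(data.frame(HT = 1)), "missing columns")
})
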