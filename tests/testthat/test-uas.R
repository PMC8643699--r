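test_that("excess green is the per-pixel 2G - R - B", {
  rgb <- array(0, c(1, 3, 3))
  rgb[1, 1, ] <- c(0, 1, 0)
  rgb[1, 2, ] <- c(0.3, 0.3, 0.3)
  rgb[1, 3, ] <- c(0.2, 0.5, 0.1)
  e <- excess_green(rgb)
  expect_equal(as.numeric(e), c(2, 0, 0.7))
  expect_error(excess_green(array(0, c(2, 2, 4))), "3")
})

test_that("Otsu threshold equals the exhaustive between-class-variance argmax", {
  # two-level map 60/40
  v1 <- c(rep(0, 60), rep(200, 40))
  t1 <- otsu_threshold(v1)
  expect_gt(t1, 0); expect_lt(t1, 200)
  expect_equal(t1, otsu_bruteforce(v1), tolerance = 1e-9)

  # overlapping symmetric bimodal Gaussians: threshold near the midpoint
  set.seed(10)
  v2 <- c(rnorm(4000, 0.3, 0.1), rnorm(4000, 0.7, 0.1))
  t2 <- otsu_threshold(v2)
  expect_lt(abs(t2 - 0.5), 0.05)
  expect_equal(t2, otsu_bruteforce(v2), tolerance = 1e-9)

  # random histograms
  for (s in 1:5) {
    set.seed(s)
    v <- c(runif(200, 0, 0.4), runif(100, 0.6, 1))
    expect_equal(otsu_threshold(v), otsu_bruteforce(v), tolerance = 1e-9)
  }

  # one foreground pixel still yields a separating finite threshold
  v3 <- c(rep(0.1, 99), 0.9)
  t3 <- otsu_threshold(v3)
  expect_true(is.finite(t3) && t3 > 0.1 && t3 < 0.9)

  expect_error(otsu_threshold(rep(1, 10)), "constant")
})

test_that("connected components locate blob centroids in ground coordinates", {
  gt <- geotransform(0, 0, 0.1)
  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE                     # centroid at row/col 9.5
  p <- locate_plants(m, gt, min_blob_px = 10)
  expect_equal(nrow(p), 1)
  expect_equal(p$x, (9.5 - 0.5) * 0.1, tolerance = 1e-9)
  expect_equal(p$y, (9.5 - 0.5) * 0.1, tolerance = 1e-9)

  m[30:35, 25:30] <- TRUE
  p2 <- locate_plants(m, gt, min_blob_px = 10)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$n_px, c(100L, 36L))       # sorted by y

  # touching blobs merge into one component (documented limitation)
  mt <- matrix(FALSE, 20, 20)
  mt[5:10, 5:10] <- TRUE
  mt[10:15, 10:15] <- TRUE                  # diagonal touch, 8-connected
  expect_equal(nrow(locate_plants(mt, gt, min_blob_px = 10)), 1)

  # blobs below the minimum size are dropped with a warning
  ms <- matrix(FALSE, 10, 10); ms[1:2, 1:2] <- TRUE
  expect_warning(p0 <- locate_plants(ms, gt, min_blob_px = 50), "minimum blob")
  expect_equal(nrow(p0), 0)
})

test_that("RANSAC recovers an exact plane and separates synthetic canopy points", {
  set.seed(1)
  flat <- data.frame(x = runif(200), y = runif(200), z = 0)
  pl <- ransac_ground_plane(flat, seed = 2)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$n_canopy, 0)

  ground <- data.frame(x = runif(1000, 0, 5), y = runif(1000, 0, 5),
                       z = rnorm(1000, 0, 0.005))
  plant <- data.frame(x = runif(300, 2, 3), y = runif(300, 2, 3),
                      z = runif(300, 0.2, 1.5))
  pl2 <- ransac_ground_plane(rbind(ground, plant), seed = 3)
  tilt <- acos(pl2$normal[3]) * 180 / pi
  expect_lt(tilt, 1)
  canopy_flags <- !pl2$inlier[1001:1300]
  expect_gte(mean(canopy_flags), 0.99)

  line <- data.frame(x = 1:50, y = 2 * (1:50), z = 3 * (1:50))
  expect_error(ransac_ground_plane(line), "collinear")
})

test_that("canopy metrics approximate analytic solids on dense samples", {
  set.seed(5)
  plane <- list(normal = c(0, 0, 1), offset = 0)
  # 1 m cube of points
  cube <- data.frame(x = runif(20000, -0.5, 0.5), y = runif(20000, -0.5, 0.5),
                     z = runif(20000, 0, 1))
  m <- canopy_metrics(cube, plane, c(0, 0), box_x = 1.83, box_y = 1.22,
                      grid_res = 0.025)
  expect_equal(m$height, 1, tolerance = 0.05)
  expect_equal(m$projected_area, 1, tolerance = 0.07)
  expect_equal(m$volume, 1, tolerance = 0.07)

  # cone of height 1, radius 0.5 (volume pi r^2 h / 3)
  u <- runif(40000); z <- 1 - u^(1/3)
  rad <- 0.5 * (1 - z) * sqrt(runif(40000))
  th <- runif(40000, 0, 2 * pi)
  cone <- data.frame(x = rad * cos(th), y = rad * sin(th), z = z)
  mc <- canopy_metrics(cone, plane, c(0, 0), grid_res = 0.02)
  expect_equal(mc$volume, pi * 0.25 / 3, tolerance = 0.1)

  # empty ROI
  e <- canopy_metrics(cube, plane, c(50, 50))
  expect_true(e$empty)
  expect_equal(e$height + e$projected_area + e$volume, 0)
})

test_that("vegetation indices match hand arithmetic on uniform rasters", {
  gt <- geotransform(0, 0, 0.05)
  msp <- array(0, c(30, 30, 5))
  msp[, , 1] <- 0.1; msp[, , 2] <- 0.4; msp[, , 3] <- 0.2
  msp[, , 4] <- 0.5; msp[, , 5] <- 0.8
  v <- vegetation_indices(msp, gt, center = c(0.75, 0.75), radius = 0.28)$indices
  expect_equal(unname(v["NDVI"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(v["OSAVI"]), 0.6 / 1.16, tolerance = 1e-10)
  expect_equal(unname(v["MSAVI2"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(v["GCI"]), 1.0, tolerance = 1e-10)
  expect_equal(unname(v["GNDVI"]), 1 / 3, tolerance = 1e-10)
  expect_equal(unname(v["EVI"]), 2.5 * 0.6 / (0.8 + 1.2 - 0.75 + 1), tolerance = 1e-10)
  expect_equal(unname(v["MNLI"]), 1.5 * (0.64 - 0.2) / (0.64 + 0.2 + 0.5), tolerance = 1e-10)

  # NIR = R gives NDVI 0
  msp0 <- msp; msp0[, , 5] <- 0.2
  v0 <- vegetation_indices(msp0, gt, c(0.75, 0.75))$indices
  expect_equal(unname(v0["NDVI"]), 0, tolerance = 1e-12)

  expect_error(vegetation_indices(msp, gt, c(0.1, 0.1)), "outside")
})

test_that("pure ratio indices are invariant to uniform band scaling", {
  gt <- geotransform(0, 0, 0.05)
  set.seed(7)
  msp <- array(runif(30 * 30 * 5, 0.05, 0.9), c(30, 30, 5))
  v1 <- vegetation_indices(msp, gt, c(0.75, 0.75))$indices
  v2 <- vegetation_indices(msp * 3, gt, c(0.75, 0.75))$indices
  for (nm in c("NDVI", "GNDVI", "GCI")) {
    expect_equal(unname(v1[nm]), unname(v2[nm]), tolerance = 1e-10, label = nm)
  }
  # the soil-adjusted and nonlinear indices carry additive constants: scale-dependent
  expect_gt(abs(v1["OSAVI"] - v2["OSAVI"]), 1e-6)
  expect_gt(abs(v1["MSAVI2"] - v2["MSAVI2"]), 1e-6)
})
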