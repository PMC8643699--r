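test_that("the generator is a pure function of config and seed", {
  cfg <- trial_config()
  a <- simulate_trial(cfg, seed = 42)
  b <- simulate_trial(cfg, seed = 42)
  expect_identical(a$traits, b$traits)
  c2 <- simulate_trial(cfg, seed = 43)
  expect_false(identical(a$traits$DIA, c2$traits$DIA))

  g1 <- simulate_growth(a, seed = 2)
  g2 <- simulate_growth(a, seed = 2)
  expect_identical(g1$series, g2$series)

  s1 <- simulate_scene(2, 3, seed = 9)
  s2 <- simulate_scene(2, 3, seed = 9)
  expect_identical(s1$cloud, s2$cloud)
  expect_identical(s1$rgb, s2$rgb)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(trial_config(n_families = 1L,
                            patterns = c(all_early = 1L, all_late = 0L,
                                         seg_1to1 = 0L, seg_2to1 = 0L)), "n_families")
  expect_error(trial_config(patterns = c(all_early = 1L, all_late = 1L,
                                         seg_1to1 = 1L, seg_2to1 = 1L)), "sum")
  expect_error(trial_config(dia = list(mean = 4.44, cv = 0.23, h2 = 1.4)), "h2")
  expect_error(trial_config(bogus = 1), "unknown")
})

test_that("population means land inside the plausibility envelope of the trial", {
  cfg <- trial_config()
  m <- rowMeans(vapply(1:5, function(s) {
    tr <- simulate_trial(cfg, seed = s)$traits
    c(HT = mean(tr$HT), MCD = mean(tr$MCD), DIA = mean(tr$DIA), WBM = mean(tr$WBM))
  }, numeric(4)))
  expect_equal(unname(m["HT"]), 157.7, tolerance = 0.15)
  expect_equal(unname(m["MCD"]), 125.9, tolerance = 0.15)
  expect_equal(unname(m["DIA"]), 4.44, tolerance = 0.15)
  expect_equal(unname(m["WBM"]), 6.31, tolerance = 0.15)
})

test_that("flowering follows the configured family segregation patterns", {
  tr <- simulate_trial(trial_config(), seed = 8)
  cl <- flowering_class(tr$traits$PTFD)
  pat <- tr$truth$pattern_by_family
  seg <- segregation_counts(cl, tr$traits$family)
  all_early_fams <- names(pat)[pat == "all_early"]
  expect_true(all(seg$n_early[seg$family %in% all_early_fams] == 15))
  all_late_fams <- names(pat)[pat == "all_late"]
  expect_true(all(seg$n_early[seg$family %in% all_late_fams] == 0))
  # the population mean pre-terminal flowering day is near the configured mix
  expect_equal(mean(tr$traits$PTFD), 59.3, tolerance = 59.3 * 0.06)
})

test_that("leaflet number tracks the flowering class means", {
  cfg <- trial_config()
  tr <- do.call(rbind, lapply(1:5, function(s) simulate_trial(cfg, s)$traits))
  cl <- flowering_class(tr$PTFD)
  m <- tapply(tr$LFLTN, cl, mean)
  expect_equal(unname(m["early"]), 3.9, tolerance = 0.2)
  expect_equal(unname(m["mid"]), 5.3, tolerance = 0.25)
  expect_equal(unname(m["late"]), 6.3, tolerance = 0.2)
})

test_that("disease progress is inversely coupled to flowering day", {
  cfg <- trial_config()
  r <- vapply(1:10, function(s) {
    tr <- simulate_trial(cfg, s)$traits
    a <- vapply(seq_len(nrow(tr)), function(i)
      audpc(cfg$disease$days, c(tr$PM71[i], tr$PM86[i], tr$PM97[i])), numeric(1))
    cor(a, tr$PTFD)
  }, numeric(1))
  expect_equal(mean(r), -0.54, tolerance = 0.08)
})

test_that("noise-free growth curves recover the analytic logistic maximum", {
  cfg <- trial_config(n_families = 2L, n_progeny = 3L,
                      patterns = c(all_early = 1L, all_late = 1L,
                                   seg_1to1 = 0L, seg_2to1 = 0L))
  tr <- simulate_trial(cfg, seed = 3)
  g <- simulate_growth(tr, seed = 4, days = seq(4, 70, by = 2), noise_sd = 0)
  for (p in unique(g$series$plant)[1:3] ) {
    s <- g$series[g$series$plant == p, ]
    f <- fit_growth(s$dap, s$height_cm, spar = 0.2)
    truth <- g$truth[g$truth$plant == p, ]
    expect_equal(f$max_rate, truth$max_rate, tolerance = truth$max_rate * 0.1)
  }
})

test_that("day of maximum growth correlates positively with flowering day", {
  cfg <- trial_config()
  r <- vapply(1:5, function(s) {
    tr <- simulate_trial(cfg, s)
    g <- simulate_growth(tr, seed = s)
    cor(g$truth$t0, tr$traits$PTFD)
  }, numeric(1))
  expect_true(all(r > 0.2))
  # late-flowering plants carry the larger growth asymptote on average
  tr <- simulate_trial(cfg, 6)
  g <- simulate_growth(tr, 6)
  late <- tr$traits$PTFD > 70
  expect_gt(mean(g$truth$K[late]), mean(g$truth$K[!late]))
})

test_that("scene ground truth is recovered by the extraction pipeline", {
  sc <- simulate_scene(n_rows = 4, n_cols = 6, seed = 11)
  ex <- extract_scene_traits(sc)
  tru <- sc$truth
  expect_equal(nrow(ex$centers), nrow(tru))
  d <- vapply(seq_len(nrow(tru)), function(i)
    min(sqrt((ex$centers$x - tru$x[i])^2 + (ex$centers$y - tru$y[i])^2)),
    numeric(1))
  expect_gte(mean(d < 0.10), 0.95)
  m <- ex$metrics
  idx <- vapply(seq_len(nrow(m)), function(i)
    which.min((tru$x - m$x[i])^2 + (tru$y - m$y[i])^2), integer(1))
  expect_gt(cor(m$height, tru$height[idx]), 0.95)
  # vegetation pixels carry a strong NIR signal
  expect_true(all(m$NDVI > 0.5, na.rm = TRUE))
})

test_that("an empty layout yields a bare-ground scene", {
  sc <- simulate_scene(n_rows = 0, n_cols = 0, seed = 2)
  expect_equal(nrow(sc$truth), 0)
  pl <- ransac_ground_plane(sc$cloud, seed = 1)
  expect_lt(pl$n_canopy / nrow(sc$cloud), 0.01)
})

test_that("trait tables and point clouds round-trip through their text formats", {
  tr <- simulate_trial(trial_config(n_families = 2L, n_progeny = 2L,
                                    patterns = c(all_early = 1L, all_late = 1L,
                                                 seg_1to1 = 0L, seg_2to1 = 0L)),
                       seed = 1)$traits
  f <- tempfile(fileext = ".csv")
  write_trait_table(tr, f)
  back <- read_trait_table(f)
  expect_equal(back$DIA, tr$DIA, tolerance = 1e-12)
  expect_equal(back$family, tr$family)

  cl <- data.frame(x = runif(10), y = runif(10), z = runif(10))
  fx <- tempfile(fileext = ".xyz")
  write_xyz(cl, fx)
  expect_equal(read_xyz(fx)$z, cl$z, tolerance = 1e-12)
})
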