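# Synthetic hemp hybrid trial generator. Emulates the statistical structure
# of a 23-family x 15-progeny common-parent trial: a major-gene flowering
# segregation, a log-log allometric cascade rooted in basal stem diameter,
# configured half-sib heritabilities, phenology-coupled powdery mildew
# progress, the reference wet-to-dry biomass calibration, and CBD-dominant
# cannabinoid profiles. All generators are pure functions of (config, seed).

#' Default configuration of the synthetic trial
#'
#' Returns the trial configuration as a nested list. Defaults encode the
#' study conditions: 23 families of 15 progeny; flowering drawn by
#' major-locus genotype class (early ~ N(42, 3^2), late ~ N(75, 6^2) DAP)
#' with family segregation patterns (all-early, all-late, ~1:1, ~2:1) mixed
#' so the population mean pre-terminal flowering day is ~59 DAP; basal stem
#' diameter (DIA) as the lognormal root latent (mean 4.44 cm, CV 0.23,
#' h^2 0.85); height scaling as DIA^0.65 and wet biomass as DIA^1.7 with
#' symmetric proportional log-scale noise calibrated to R^2 = 0.78; the
#' leafing-intensity cascade (leaf mass ~ LI^-0.71 at R^2 0.66, specific
#' petiole area ~ LI^2.08 at R^2 0.55); the reference biomass calibration
#' with residual sd 0.1446 / 0.1031; disease severity coupled to flowering
#' day targeting r ~ -0.54 with AUDPC; and CBD-dominant cannabinoid totals.
#'
#' @param ... named overrides of top-level entries
#' @return a `trial_config` list
#' @export
trial_config <- function(...) {
  cfg <- list(
    n_families = 23L,
    n_progeny = 15L,
    # counts of family segregation patterns (sum = n_families); p_early per
    # pattern: all_early 1, all_late 0, seg_1to1 1/2, seg_2to1 2/3
    patterns = c(all_early = 5L, all_late = 8L, seg_1to1 = 6L, seg_2to1 = 4L),
    flowering = list(early_mean = 42, early_sd = 3, late_mean = 75, late_sd = 6,
                     range = c(28, 92), terminal_lag = 9.6, terminal_lag_sd = 2),
    leaflet = list(means = c(early = 3.9, mid = 5.3, late = 6.3), sd = 0.6,
                   range = c(3, 7)),
    dia = list(mean = 4.44, cv = 0.23, h2 = 0.85),
    allometry = list(
      ht = list(exponent = 0.65, mean = 157.7, r2 = 0.78),
      wbm = list(exponent = 1.7, mean = 6.31, r2 = 0.78)
    ),
    foliar = list(
      li_mean = 0.56, li_size_cor = -0.82, li_size_slope = 1.2,
      lfdw = list(exponent = -0.71, mean = 0.25, r2 = 0.66),
      spa = list(exponent = 2.08, mean = 34.8, r2 = 0.55),
      sla = list(mean = 167.2, cv = 0.10),
      ptdw = list(mean = 0.03, cv = 0.54),
      lfl = list(mean = 14.3, cv = 0.11),
      mlfw = list(mean = 1.70, cv = 0.21),
      lfp = list(mean = 102.1, spa_slope = -1.46, extra_sd = 0.15)
    ),
    canopy = list(mcd_ht = c(mean = 0.798, sd = 0.07, lo = 0.45, hi = 1.05),
                  mcdh_ht = c(mean = 0.545, sd = 0.08, lo = 0.30, hi = 0.85),
                  trkl = c(mean = 12.2, cv = 0.70),
                  bpair = c(mean = 7.45, sdlog = 0.25, lo = 4, hi = 16)),
    physiology = list(cci = c(mean = 51.2, cv = 0.15),
                      gli = c(mean = 0.12, sd = 0.017, lo = 0.05, hi = 0.25)),
    disease = list(days = c(71, 86, 97), final_mean = 37.8, flow_mean = 59.3,
                   flow_slope = -0.54, noise_sd = 15, range = c(1, 95),
                   rel86 = 0.96, rel71 = 0.88, rel_sd = c(0.05, 0.08)),
    biomass = list(calibration = reference_biomass_calibration(), floor = 0.05),
    cannabinoids = list(
      # total-potential means (% dry mass) and lognormal CVs
      means = c(THC = 1.19, CBD = 8.73, CBC = 0.52, CBG = 0.27,
                THCV = 0.03, CBDV = 0.16, CBL = 0.04),
      cvs = c(THC = 1.0, CBD = 0.32, CBC = 0.57, CBG = 0.41,
              THCV = 1.5, CBDV = 1.5, CBL = 0.70),
      acid_fraction = 0.95, decarb = c(pentyl = 0.877, propyl = 0.867)
    ),
    growth = list(days = seq(7, 70, by = 7), rate = 0.1, rate_sd = 0.01,
                  t0_intercept = 22, t0_flow_slope = 0.35, t0_sd = 10,
                  noise_sd = 2),
    field = list(row_spacing = 1.8, col_spacing = 1.2,
                 box = c(1.83, 1.22), roi_radius = 0.28)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop_bad("config", paste("unknown entries:", paste(bad, collapse = ", ")))
    cfg[names(ov)] <- ov
  }
  validate_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_config <- function(cfg) {
  if (cfg$n_families < 2) stop_bad("n_families", "need >= 2")
  if (cfg$n_progeny < 2) stop_bad("n_progeny", "need >= 2")
  if (sum(cfg$patterns) != cfg$n_families) {
    stop_bad("patterns", "pattern counts must sum to n_families")
  }
  if (cfg$dia$h2 < 0 || cfg$dia$h2 > 1) stop_bad("dia$h2", "must lie in [0, 1]")
  if (cfg$dia$cv <= 0) stop_bad("dia$cv", "must be > 0")
  for (tr in names(cfg$allometry)) {
    a <- cfg$allometry[[tr]]
    if (!is.finite(a$exponent)) stop_bad(tr, "exponent must be finite")
    if (a$r2 <= 0 || a$r2 > 1) stop_bad(tr, "r2 must lie in (0, 1]")
  }
  invisible(cfg)
}

# noise-to-signal variance ratio giving the target R^2 under symmetric
# proportional noise on both log axes: R^2 = 1/(1+lambda^2)^2
lambda2_for_r2 <- function(r2) 1 / sqrt(r2) - 1

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

rlnorm_mean <- function(n, mean, cv) {
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, log(mean) - s^2 / 2, s)
}

#' Simulate a complete trial trait table
#'
#' Generates one virtual trial under a [trial_config()]: per-plant flowering
#' phenology by family segregation pattern, the allometric trait cascade
#' rooted in basal stem diameter, canopy architecture measurements, foliar
#' traits, disease severities, biomass (via the configured calibration with
#' its residual noise) and cannabinoid acid/neutral percentages.
#' Deterministic under a fixed seed.
#'
#' @param cfg a `trial_config`
#' @param seed integer master seed
#' @return list with `traits` (data.frame, one row per plant, standard trait-abbreviation
#'   columns) and `truth` (the generating latents and parameters used by
#'   recovery tests)
#' @export
simulate_trial <- function(cfg = trial_config(), seed = 1L) {
  validate_config(cfg)
  set.seed(derive_seed(seed, 11L))
  k <- cfg$n_families; np <- cfg$n_progeny
  n <- k * np
  family <- rep(sprintf("fam%02d", seq_len(k)), each = np)
  plant <- paste0(family, "-", rep(seq_len(np), k))

  # --- flowering by family segregation pattern -------------------------
  pattern <- rep(rep(names(cfg$patterns), cfg$patterns), each = np)
  p_early <- c(all_early = 1, all_late = 0, seg_1to1 = 0.5, seg_2to1 = 2 / 3)[pattern]
  early <- stats::rbinom(n, 1, p_early) == 1
  fl <- cfg$flowering
  ptfd <- ifelse(early, stats::rnorm(n, fl$early_mean, fl$early_sd),
                 stats::rnorm(n, fl$late_mean, fl$late_sd))
  ptfd <- pmin(pmax(round(ptfd), fl$range[1]), fl$range[2])
  tfd <- pmin(round(ptfd + fl$terminal_lag + stats::rnorm(n, 0, fl$terminal_lag_sd)),
              fl$range[2] + 7)

  cls <- flowering_class(ptfd)
  lf <- cfg$leaflet
  lfltn <- round(stats::rnorm(n, lf$means[as.character(cls)], lf$sd))
  lfltn <- pmin(pmax(lfltn, lf$range[1]), lf$range[2])

  # --- root latent: basal stem diameter --------------------------------
  v_tot <- cv_to_sdlog(cfg$dia$cv)^2           # ln-scale phenotypic variance
  lam2 <- lambda2_for_r2(cfg$allometry$wbm$r2)  # shared measurement-noise ratio
  v_fam <- (cfg$dia$h2 / 4) * v_tot
  v_lat <- v_tot / (1 + lam2)                  # latent (shared) variance
  if (v_fam > v_lat) stop_bad("dia$h2", "family variance exceeds the latent variance; lower h2 or r2 noise")
  v_g <- v_lat - v_fam
  v_meas <- v_tot - v_lat
  m_dia <- log(cfg$dia$mean) - v_tot / 2
  fam_eff <- stats::rnorm(k, 0, sqrt(v_fam))[rep(seq_len(k), each = np)]
  xi <- m_dia + fam_eff + stats::rnorm(n, 0, sqrt(v_g))
  ln_dia <- xi + stats::rnorm(n, 0, sqrt(v_meas))
  dia <- exp(ln_dia)

  # --- allometric cascade ----------------------------------------------
  gen_allo <- function(law) {
    b <- law$exponent
    v_y <- b^2 * v_tot
    alpha <- log(law$mean) - b * m_dia - v_y / 2
    exp(alpha + b * xi + stats::rnorm(n, 0, sqrt(b^2 * lam2 * v_lat)))
  }
  ht <- gen_allo(cfg$allometry$ht)
  wbm <- gen_allo(cfg$allometry$wbm)

  # --- canopy architecture ---------------------------------------------
  cn <- cfg$canopy
  r1 <- pmin(pmax(stats::rnorm(n, cn$mcd_ht["mean"], cn$mcd_ht["sd"]),
                  cn$mcd_ht["lo"]), cn$mcd_ht["hi"])
  r2 <- pmin(pmax(stats::rnorm(n, cn$mcdh_ht["mean"], cn$mcdh_ht["sd"]),
                  cn$mcdh_ht["lo"]), cn$mcdh_ht["hi"])
  mcd <- ht * r1
  mcdh <- ht * r2
  trkl <- pmin(rlnorm_mean(n, cn$trkl["mean"], cn$trkl["cv"]), 0.7 * mcdh)
  bpair <- round(pmin(pmax(stats::rlnorm(n, log(cn$bpair["mean"]) -
                                           cn$bpair["sdlog"]^2 / 2,
                                         cn$bpair["sdlog"]),
                           cn$bpair["lo"]), cn$bpair["hi"]))

  # --- foliar cascade on the leafing-intensity latent ------------------
  fo <- cfg$foliar
  lam2_f <- lambda2_for_r2(fo$lfdw$r2)
  g_li <- fo$li_size_slope
  sd_li_signal <- g_li * sqrt(v_lat)
  sd_li_noise <- sd_li_signal * sqrt(1 / fo$li_size_cor^2 - 1)
  v_eta <- sd_li_signal^2 + sd_li_noise^2
  mu_eta <- log(fo$li_mean) - v_eta * (1 + lam2_f) / 2
  eta <- mu_eta - g_li * (xi - m_dia) + stats::rnorm(n, 0, sd_li_noise)
  ln_li <- eta + stats::rnorm(n, 0, sqrt(lam2_f * v_eta))

  vol <- stem_volume(dia, ht)
  lfn <- pmax(1, round(exp(ln_li) * vol))

  b_f <- fo$lfdw$exponent
  v_lfdw <- b_f^2 * v_eta * (1 + lam2_f)
  a_f <- log(fo$lfdw$mean) - b_f * mu_eta - v_lfdw / 2
  lfdw <- exp(a_f + b_f * eta + stats::rnorm(n, 0, sqrt(b_f^2 * lam2_f * v_eta)))

  b_s <- fo$spa$exponent
  # extra y-noise sized so the observed-LI regression has the target R^2
  v_spa_sig <- b_s^2 * v_eta
  v_spa_noise <- v_spa_sig * ((1 / (fo$spa$r2 * (1 + lam2_f))) - 1)
  a_s <- log(fo$spa$mean) - b_s * mu_eta - (v_spa_sig + v_spa_noise) / 2
  spa <- exp(a_s + b_s * eta + stats::rnorm(n, 0, sqrt(v_spa_noise)))

  sla <- rlnorm_mean(n, fo$sla$mean, fo$sla$cv)
  ptdw <- rlnorm_mean(n, fo$ptdw$mean, fo$ptdw$cv)
  pta <- spa * ptdw
  lfa <- sla * lfdw
  lfl <- rlnorm_mean(n, fo$lfl$mean, fo$lfl$cv)
  mlfw <- rlnorm_mean(n, fo$mlfw$mean, fo$mlfw$cv)
  mlfa <- pointed_oval_area(lfl, mlfw)
  ln_spa_c <- log(spa) - mean(log(spa))
  v_lfp <- (1 / fo$lfp$spa_slope)^2 * stats::var(ln_spa_c) + fo$lfp$extra_sd^2
  lfp <- exp(log(fo$lfp$mean) - v_lfp / 2 + ln_spa_c / fo$lfp$spa_slope +
             stats::rnorm(n, 0, fo$lfp$extra_sd))

  # --- physiology -------------------------------------------------------
  ph <- cfg$physiology
  cci <- rlnorm_mean(n, ph$cci["mean"], ph$cci["cv"])
  gli <- pmin(pmax(stats::rnorm(n, ph$gli["mean"], ph$gli["sd"]),
                   ph$gli["lo"]), ph$gli["hi"])

  # --- powdery mildew, phenology-coupled -------------------------------
  dz <- cfg$disease
  pm97 <- pmin(pmax(dz$final_mean + dz$flow_slope * (ptfd - dz$flow_mean) +
                      stats::rnorm(n, 0, dz$noise_sd), dz$range[1]), dz$range[2])
  pm86 <- pmin(pmax(pm97 * (dz$rel86 + stats::rnorm(n, 0, dz$rel_sd[1])), 0), 100)
  pm71 <- pmin(pmax(pm97 * (dz$rel71 + stats::rnorm(n, 0, dz$rel_sd[2])), 0), 100)

  # --- biomass through the calibration ---------------------------------
  cal <- cfg$biomass$calibration
  dbm <- pmax(cfg$biomass$floor,
              cal$dbm$intercept + cal$dbm$slope * wbm +
                stats::rnorm(n, 0, cal$dbm$residual_sd))
  dsbm <- pmax(cfg$biomass$floor,
               cal$dsbm$intercept + cal$dsbm$slope * wbm +
                 stats::rnorm(n, 0, cal$dsbm$residual_sd))

  # --- cannabinoids -----------------------------------------------------
  cb <- cfg$cannabinoids
  cb_cols <- list()
  for (cmp in names(cb$means)) {
    tot <- rlnorm_mean(n, cb$means[[cmp]], cb$cvs[[cmp]])
    f <- if (cmp %in% c("THCV", "CBDV")) cb$decarb[["propyl"]] else cb$decarb[["pentyl"]]
    acid <- cb$acid_fraction * tot / f
    cb_cols[[paste0(cmp, "A_pct")]] <- acid
    cb_cols[[paste0(cmp, "_pct")]] <- (1 - cb$acid_fraction) * tot
  }
  chemo_ratio <- (cb_cols[["CBDA_pct"]] * cb$decarb[["pentyl"]] + cb_cols[["CBD_pct"]]) /
    pmax(cb_cols[["THCA_pct"]] * cb$decarb[["pentyl"]] + cb_cols[["THC_pct"]], 1e-9)
  chemotype <- cut(chemo_ratio, c(-Inf, 0.2, 5, Inf),
                   labels = c("THC-dominant", "intermediate", "CBD-dominant"))

  traits <- data.frame(
    family = family, plant = plant, pattern = pattern,
    PTFD = ptfd, TFD = tfd, LFLTN = lfltn,
    HT = ht, MCD = mcd, MCDH = mcdh, TRKL = trkl, DIA = dia, BPAIR = bpair,
    LFN = lfn, LFDW = lfdw, LFA = lfa, LFL = lfl, LFP = lfp, SLA = sla,
    PTDW = ptdw, PTA = pta, SPA = spa, MLFW = mlfw, MLFA = mlfa,
    CCI = cci, GLI = gli,
    PM71 = pm71, PM86 = pm86, PM97 = pm97,
    WBM = wbm, DBM = dbm, DSBM = dsbm,
    chemotype = as.character(chemotype),
    stringsAsFactors = FALSE
  )
  traits <- cbind(traits, as.data.frame(cb_cols))

  truth <- list(config = cfg, seed = seed,
                pattern_by_family = stats::setNames(rep(names(cfg$patterns), cfg$patterns),
                                                    sprintf("fam%02d", seq_len(k))),
                early = early, xi = xi, eta = eta,
                family_effects = fam_eff[seq(1, n, by = np)],
                variances = c(total = v_tot, family = v_fam, latent = v_lat,
                              measurement = v_meas),
                exponents = c(ht = cfg$allometry$ht$exponent,
                              wbm = cfg$allometry$wbm$exponent,
                              lfdw = b_f, spa = b_s),
                h2_dia = cfg$dia$h2)
  list(traits = traits, truth = truth)
}

#' Simulate weekly height growth series
#'
#' Logistic growth curves per plant, with the inflection day linked to the
#' plant's flowering day (inducing a positive correlation of day of maximum
#' growth with days to flower) and the asymptote tied to the plant's final
#' height, plus measurement noise.
#'
#' @param trial result of [simulate_trial()]
#' @param seed integer seed
#' @param days measurement days (default: the config's weekly grid)
#' @param noise_sd measurement noise, cm (default from config)
#' @return list with `series` (long data.frame: plant, family, dap,
#'   height_cm) and `truth` (per-plant t0, rate, K, true max rate rK/4)
#' @export
simulate_growth <- function(trial, seed = 1L, days = NULL, noise_sd = NULL) {
  cfg <- trial$truth$config
  g <- cfg$growth
  days <- days %||% g$days
  noise_sd <- noise_sd %||% g$noise_sd
  set.seed(derive_seed(seed, 21L))
  tr <- trial$traits
  n <- nrow(tr)
  t0 <- pmin(pmax(g$t0_intercept + g$t0_flow_slope * tr$PTFD +
                    stats::rnorm(n, 0, g$t0_sd), 15), 68)
  r <- pmax(0.03, stats::rnorm(n, g$rate, g$rate_sd))
  tmax <- max(days)
  K <- tr$HT * (1 + exp(-r * (tmax - t0)))   # so the curve hits HT at the last day
  series <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- K[i] / (1 + exp(-r[i] * (days - t0[i])))
    data.frame(plant = tr$plant[i], family = tr$family[i], dap = days,
               height_cm = pmax(0, h + stats::rnorm(length(days), 0, noise_sd)),
               stringsAsFactors = FALSE)
  }))
  list(series = series,
       truth = data.frame(plant = tr$plant, t0 = t0, rate = r, K = K,
                          max_rate = r * K / 4, stringsAsFactors = FALSE))
}

#' Simulate a planted aerial scene
#'
#' Builds a co-registered synthetic flight product over a planted grid:
#' an RGB raster (green vegetation disks on brown soil), a 5-band
#' multispectral raster (NIR elevated on vegetation), and a 3-D point cloud
#' (rough ground plane plus tapered canopy point clusters), together with
#' the ground truth (plant centres and heights).
#'
#' @param n_rows,n_cols planting grid size
#' @param heights plant heights in m (recycled; default lognormal around
#'   1.58 m)
#' @param seed integer seed
#' @param row_spacing,col_spacing grid spacing, m (defaults 1.8 between
#'   rows, 1.2 within row)
#' @param gsd raster ground sampling distance, m (default 0.04)
#' @param margin bare-ground margin, m (default 1.5)
#' @param ground_noise ground roughness sd, m (default 0.005)
#' @param plant_points canopy points per plant (default 400)
#' @param ground_density ground points per m^2 (default 60)
#' @return a `scene`: list with `rgb`, `msp`, `cloud`, `gt` (geotransform),
#'   `truth` (data.frame plant, x, y, height, radius)
#' @export
simulate_scene <- function(n_rows = 4, n_cols = 6, heights = NULL, seed = 1L,
                           row_spacing = 1.8, col_spacing = 1.2, gsd = 0.04,
                           margin = 1.5, ground_noise = 0.005,
                           plant_points = 400, ground_density = 60) {
  if (row_spacing <= 0 || col_spacing <= 0) stop_bad("spacing", "must be > 0")
  set.seed(derive_seed(seed, 31L))
  n <- n_rows * n_cols
  if (n > 0) {
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    cx <- margin + (grid$col - 1) * col_spacing + stats::rnorm(n, 0, 0.04)
    cy <- margin + (grid$row - 1) * row_spacing + stats::rnorm(n, 0, 0.04)
    if (is.null(heights)) heights <- stats::rlnorm(n, log(1.58) - 0.02, 0.2)
    heights <- rep_len(heights, n)
    radius <- pmin(0.45, 0.20 + 0.15 * heights)
  } else {
    cx <- cy <- heights <- radius <- numeric(0)
  }
  W <- 2 * margin + max(0, n_cols - 1) * col_spacing
  H <- 2 * margin + max(0, n_rows - 1) * row_spacing
  gt <- geotransform(0, 0, gsd)
  nc <- ceiling(W / gsd); nr <- ceiling(H / gsd)

  px <- pixel_to_ground(matrix(seq_len(nr), nr, nc),
                        matrix(seq_len(nc), nr, nc, byrow = TRUE), gt)
  veg <- matrix(FALSE, nr, nc)
  for (i in seq_len(n)) {
    veg <- veg | ((px$x - cx[i])^2 + (px$y - cy[i])^2 <= radius[i]^2)
  }
  band <- function(soil, plant, noise) {
    m <- matrix(stats::rnorm(nr * nc, soil, noise), nr, nc)
    m[veg] <- stats::rnorm(sum(veg), plant, noise)
    m
  }
  rgb <- array(0, c(nr, nc, 3))
  rgb[, , 1] <- band(0.45, 0.18, 0.03)
  rgb[, , 2] <- band(0.35, 0.42, 0.03)
  rgb[, , 3] <- band(0.25, 0.15, 0.03)
  msp <- array(0, c(nr, nc, 5))
  soil5 <- c(0.08, 0.12, 0.18, 0.22, 0.25)
  veg5 <- c(0.04, 0.10, 0.06, 0.35, 0.55)
  for (b in 1:5) msp[, , b] <- band(soil5[b], veg5[b], 0.01)

  n_ground <- max(100, round(ground_density * W * H))
  gx <- stats::runif(n_ground, 0, W); gy <- stats::runif(n_ground, 0, H)
  ground <- data.frame(x = gx, y = gy, z = stats::rnorm(n_ground, 0, ground_noise))
  plant_pts <- lapply(seq_len(n), function(i) {
    z <- stats::runif(plant_points, 0.05 * heights[i], heights[i])
    rad <- radius[i] * (1 - 0.6 * z / heights[i]) * sqrt(stats::runif(plant_points))
    th <- stats::runif(plant_points, 0, 2 * pi)
    data.frame(x = cx[i] + rad * cos(th), y = cy[i] + rad * sin(th), z = z)
  })
  cloud <- do.call(rbind, c(list(ground), plant_pts))

  structure(list(rgb = rgb, msp = msp, cloud = cloud, gt = gt,
                 truth = data.frame(plant = seq_len(n), x = cx, y = cy,
                                    height = heights, radius = radius)),
            class = "scene")
}

#' Write / read a point cloud as XYZ text
#'
#' @param cloud data.frame with `x`, `y`, `z`
#' @param path file path
#' @export
write_xyz <- function(cloud, path) {
  utils::write.table(cloud[, c("x", "y", "z")], path, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  out <- utils::read.table(path, col.names = c("x", "y", "z"))
  out
}
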