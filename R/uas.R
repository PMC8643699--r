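# Per-plant trait extraction from reconstructed aerial products: rasters are
# numeric matrices/arrays indexed [row, col(, band)]; a geotransform maps
# pixel centres to ground metres: x = x0 + (col - 0.5) * gsd,
# y = y0 + (row - 0.5) * gsd. Point clouds are data.frames with x, y, z (m).

#' Make a raster geotransform
#'
#' @param x0,y0 ground coordinates (m) of the raster's top-left corner
#' @param gsd ground sampling distance, m per pixel
#' @export
geotransform <- function(x0 = 0, y0 = 0, gsd = 0.05) {
  list(x0 = x0, y0 = y0, gsd = gsd)
}

pixel_to_ground <- function(row, col, gt) {
  list(x = gt$x0 + (col - 0.5) * gt$gsd, y = gt$y0 + (row - 0.5) * gt$gsd)
}

#' Excess green index map
#'
#' Per-pixel `2G - R - B` from a 3-band RGB raster.
#'
#' @param rgb numeric array h x w x 3
#' @return numeric matrix h x w
#' @export
excess_green <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) stop_bad("rgb", "must be h x w x 3")
  2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
}

#' Otsu threshold of an index map
#'
#' Builds a histogram (default 256 bins over the observed range) and returns
#' the cut level maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; on ties the smallest level is returned. Pixels
#' `> threshold` are foreground.
#'
#' @param map numeric matrix or vector with at least two distinct values
#' @param nbins histogram bins (default 256)
#' @return threshold on the data scale
#' @export
otsu_threshold <- function(map, nbins = 256) {
  v <- as.numeric(map)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop_bad("map", "constant map has no threshold")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), nbins), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(w)
  mu0 <- cumsum(w * mids)
  mu_t <- mu0[nbins]
  # between-class variance for a cut after each bin t = 1..nbins-1
  t <- seq_len(nbins - 1)
  w1 <- 1 - w0[t]
  valid <- w0[t] > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mu_t * w0[t][valid] - mu0[t][valid])^2 / (w0[t][valid] * w1[valid])
  best <- which.max(bcv)  # first maximum = smallest level on ties
  breaks[best + 1]
}

#' Locate plants from a binary vegetation map
#'
#' Labels 8-connected foreground components, discards blobs smaller than
#' `min_blob_px`, and returns component centroids mapped to ground
#' coordinates, sorted row-major by field position (y, then x).
#'
#' @param binary logical (or 0/1) matrix; `TRUE` = vegetation
#' @param gt geotransform from [geotransform()]
#' @param min_blob_px minimum component size in pixels (default 50)
#' @return data.frame with `plant`, `x`, `y` (m), `n_px`; zero rows (with a
#'   warning) when no components survive
#' @export
locate_plants <- function(binary, gt, min_blob_px = 50) {
  if (!is.matrix(binary)) stop_bad("binary", "must be a matrix")
  lab <- label_components(binary > 0)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- ids[sizes[ids] >= min_blob_px]
  if (!length(keep)) {
    warning("no components above the minimum blob size")
    return(data.frame(plant = integer(0), x = numeric(0), y = numeric(0),
                      n_px = integer(0)))
  }
  rows <- lapply(keep, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    g <- pixel_to_ground(mean(w[, 1]), mean(w[, 2]), gt)
    data.frame(x = g$x, y = g$y, n_px = nrow(w))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$y, out$x), , drop = FALSE]
  data.frame(plant = seq_len(nrow(out)), out, row.names = NULL)
}

# 8-connected component labelling by iterative label propagation: every
# foreground pixel starts with its own index; neighbours exchange maxima
# until a fixed point. Iteration count is bounded by the blob diameter.
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- matrix(0L, nr, nc)
      r_src <- seq_len(nr) - s[1]; c_src <- seq_len(nc) - s[2]
      ok_r <- r_src >= 1 & r_src <= nr; ok_c <- c_src >= 1 & c_src <= nc
      sh[ok_r, ok_c] <- lab[r_src[ok_r], c_src[ok_c]]
      sh[!fg] <- 0L
      new <- pmax(new, sh)
    }
    new[!fg] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..n_components
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids)) lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' RANSAC ground-plane fit for a plant point cloud
#'
#' Fits the dominant plane by random sample consensus: seeded random
#' 3-point samples propose planes, the plane with the largest inlier count
#' (absolute signed distance `<= dist_thresh`) wins, and the final plane is
#' refit by total least squares on its inliers. Points are partitioned into
#' `ground` (inliers) and `canopy` (the rest).
#'
#' @param cloud data.frame with columns `x`, `y`, `z` (m)
#' @param dist_thresh inlier distance, m (default 0.05)
#' @param iters RANSAC iterations (default 500)
#' @param seed RNG seed (default 1)
#' @return list with `normal` (unit vector, oriented +z), `offset` (plane is
#'   `normal . p + offset = 0`), `inlier` (logical vector), `n_ground`,
#'   `n_canopy`
#' @export
ransac_ground_plane <- function(cloud, dist_thresh = 0.05, iters = 500, seed = 1L) {
  P <- as.matrix(cloud[, c("x", "y", "z")])
  n <- nrow(P)
  if (n < 3) stop_bad("cloud", "need at least 3 points")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) stop_bad("cloud", "points are collinear")

  set.seed(seed)
  best_in <- -1L
  best <- NULL
  for (i in seq_len(iters)) {
    idx <- sample.int(n, 3)
    v1 <- P[idx[2], ] - P[idx[1], ]
    v2 <- P[idx[3], ] - P[idx[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    d <- abs(as.vector(P %*% nrm) - sum(nrm * P[idx[1], ]))
    n_in <- sum(d <= dist_thresh)
    if (n_in > best_in) {
      best_in <- n_in
      best <- list(normal = nrm, point = P[idx[1], ])
    }
  }
  d <- abs(as.vector(P %*% best$normal) - sum(best$normal * best$point))
  inlier <- d <= dist_thresh
  # refit by total least squares (smallest principal axis) on the inliers
  Q <- P[inlier, , drop = FALSE]
  ctr <- colMeans(Q)
  nrm <- svd(sweep(Q, 2, ctr), nu = 0)$v[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  offset <- -sum(nrm * ctr)
  d2 <- as.vector(P %*% nrm) + offset
  inlier <- abs(d2) <= dist_thresh
  list(normal = nrm, offset = offset, inlier = inlier,
       n_ground = sum(inlier), n_canopy = sum(!inlier))
}

#' Height of points above a fitted plane
#'
#' @param cloud data.frame with `x`, `y`, `z`
#' @param plane fit from [ransac_ground_plane()]
#' @return signed heights, m
#' @export
plane_height <- function(cloud, plane) {
  as.vector(as.matrix(cloud[, c("x", "y", "z")]) %*% plane$normal) + plane$offset
}

#' Canopy morphological metrics inside a plant ROI
#'
#' Crops canopy points to the plant's bounding box (default 1.83 m across
#' row by 1.22 m within row, centred on the plant), measures heights above
#' the ground plane, and reports: canopy height (99th percentile of point
#' heights), projected area (occupied cells of a `grid_res` grid times cell
#' area), and volume (sum over occupied cells of cell-max height times cell
#' area).
#'
#' @param cloud data.frame of canopy points with `x`, `y`, `z`
#' @param plane ground plane from [ransac_ground_plane()]
#' @param center c(x, y) plant centre, m
#' @param box_x,box_y bounding-box dimensions, m (defaults 1.83, 1.22)
#' @param grid_res occupancy-grid resolution, m (default 0.05)
#' @param height_q quantile for canopy height (default 0.99)
#' @return list with `height`, `projected_area`, `volume`, `n_canopy_points`,
#'   `empty` (flag)
#' @export
canopy_metrics <- function(cloud, plane, center, box_x = 1.83, box_y = 1.22,
                           grid_res = 0.05, height_q = 0.99) {
  inbox <- abs(cloud$x - center[1]) <= box_x / 2 &
           abs(cloud$y - center[2]) <= box_y / 2
  pts <- cloud[inbox, , drop = FALSE]
  if (!nrow(pts)) {
    return(list(height = 0, projected_area = 0, volume = 0,
                n_canopy_points = 0L, empty = TRUE))
  }
  h <- plane_height(pts, plane)
  h <- pmax(h, 0)
  cx <- floor((pts$x - (center[1] - box_x / 2)) / grid_res)
  cy <- floor((pts$y - (center[2] - box_y / 2)) / grid_res)
  cell <- paste(cx, cy)
  cell_max <- tapply(h, cell, max)
  list(height = unname(stats::quantile(h, height_q)),
       projected_area = length(cell_max) * grid_res^2,
       volume = sum(cell_max) * grid_res^2,
       n_canopy_points = nrow(pts), empty = FALSE)
}

#' Vegetation indices within a circular plant region
#'
#' Means over the pixels of a circular region (default radius 0.28 m at the
#' plant centre) of seven per-pixel indices computed from a 5-band
#' multispectral raster (bands ordered B, G, R, RedEdge, NIR):
#' NDVI `(NIR-R)/(NIR+R)`, GNDVI `(NIR-G)/(NIR+G)`, GCI `NIR/G - 1`,
#' EVI `2.5 (NIR-R)/(NIR + 6R - 7.5B + 1)`, OSAVI `(NIR-R)/(NIR+R+0.16)`,
#' MSAVI2 `(2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR-R)))/2`, and
#' MNLI `1.5 (NIR^2 - R)/(NIR^2 + R + 0.5)`. Pixels with a zero denominator
#' (or a negative MSAVI2 discriminant) are excluded per index and counted.
#'
#' @param msp numeric array h x w x 5
#' @param gt geotransform
#' @param center c(x, y) plant centre, m
#' @param radius circle radius, m (default 0.28)
#' @return list with `indices` (named numeric vector of 7 means),
#'   `n_pixels`, `n_excluded` (named)
#' @export
vegetation_indices <- function(msp, gt, center, radius = 0.28) {
  if (length(dim(msp)) != 3 || dim(msp)[3] != 5) stop_bad("msp", "must be h x w x 5")
  nr <- dim(msp)[1]; nc <- dim(msp)[2]
  px <- pixel_to_ground(matrix(seq_len(nr), nr, nc),
                        matrix(seq_len(nc), nr, nc, byrow = TRUE), gt)
  if (center[1] - radius < gt$x0 || center[2] - radius < gt$y0 ||
      center[1] + radius > gt$x0 + nc * gt$gsd ||
      center[2] + radius > gt$y0 + nr * gt$gsd) {
    stop_bad("center", "circle extends outside the raster")
  }
  inside <- (px$x - center[1])^2 + (px$y - center[2])^2 <= radius^2
  B <- msp[, , 1][inside]; G <- msp[, , 2][inside]; R <- msp[, , 3][inside]
  NIR <- msp[, , 5][inside]

  safe_mean <- function(num, den) {
    ok <- is.finite(num) & is.finite(den) & den != 0
    list(mean = if (any(ok)) mean(num[ok] / den[ok]) else NA_real_,
         excluded = sum(!ok))
  }
  ndvi <- safe_mean(NIR - R, NIR + R)
  gndvi <- safe_mean(NIR - G, NIR + G)
  gci <- safe_mean(NIR, G)
  evi <- safe_mean(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1)
  osavi <- safe_mean(NIR - R, NIR + R + 0.16)
  disc <- (2 * NIR + 1)^2 - 8 * (NIR - R)
  ok_m <- disc >= 0
  msavi2 <- list(mean = if (any(ok_m)) mean((2 * NIR[ok_m] + 1 - sqrt(disc[ok_m])) / 2)
                        else NA_real_,
                 excluded = sum(!ok_m))
  mnli <- safe_mean(1.5 * (NIR^2 - R), NIR^2 + R + 0.5)

  vals <- c(NDVI = ndvi$mean, GNDVI = gndvi$mean, GCI = gci$mean - 1,
            EVI = evi$mean, OSAVI = osavi$mean, MSAVI2 = msavi2$mean,
            MNLI = mnli$mean)
  excl <- c(NDVI = ndvi$excluded, GNDVI = gndvi$excluded, GCI = gci$excluded,
            EVI = evi$excluded, OSAVI = osavi$excluded,
            MSAVI2 = msavi2$excluded, MNLI = mnli$excluded)
  list(indices = vals, n_pixels = sum(inside), n_excluded = excl)
}

#' End-to-end per-plant trait extraction from a scene
#'
#' Runs the aerial pipeline on a scene (as produced by [simulate_scene()]):
#' excess-green + Otsu + connected components to locate plants, RANSAC
#' ground plane on the point cloud, then canopy metrics and vegetation
#' indices per located plant.
#'
#' @param scene a `scene` list with `rgb`, `msp`, `cloud`, `gt`
#' @param min_blob_px minimum blob size for [locate_plants()]
#' @param grid_res grid resolution for [canopy_metrics()]
#' @param dist_thresh RANSAC inlier distance
#' @param seed RANSAC seed
#' @return list with `centers` (from [locate_plants()]), `plane`, and
#'   `metrics` (data.frame: plant, x, y, height, projected_area, volume,
#'   and the seven index means)
#' @export
extract_scene_traits <- function(scene, min_blob_px = 50, grid_res = 0.05,
                                 dist_thresh = 0.05, seed = 1L) {
  exg <- excess_green(scene$rgb)
  thr <- otsu_threshold(exg)
  centers <- locate_plants(exg > thr, scene$gt, min_blob_px)
  plane <- ransac_ground_plane(scene$cloud, dist_thresh = dist_thresh, seed = seed)
  canopy <- scene$cloud[!plane$inlier, , drop = FALSE]
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    ctr <- c(centers$x[i], centers$y[i])
    m <- canopy_metrics(canopy, plane, ctr, grid_res = grid_res)
    vi <- tryCatch(vegetation_indices(scene$msp, scene$gt, ctr)$indices,
                   error = function(e) rep(NA_real_, 7))
    data.frame(plant = centers$plant[i], x = ctr[1], y = ctr[2],
               height = m$height, projected_area = m$projected_area,
               volume = m$volume, t(vi))
  })
  list(centers = centers, plane = plane, metrics = do.call(rbind, rows))
}
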