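#' Build the 2-D kite model of canopy architecture
#'
#' Summarises a plant's canopy as a symmetric kite (a quadrilateral with a
#' vertical axis of symmetry) constructed from four field measurements: plant
#' height (`ht`), maximum canopy diameter (`mcd`), the height at which that
#' diameter occurs (`mcdh`), and trunk length to the first branch (`trkl`),
#' all in cm. The kite's vertices are the first branch point `(0, trkl)`, the
#' shoot apex `(0, ht)` and the two lateral canopy extremes
#' `(+/- mcd/2, mcdh)`; the trunk below the first branch is excluded.
#'
#' Derived scalar traits: kite area (m^2), perimeter (m), circularity
#' `4*pi*A/P^2` (dimensionless, maximal `pi/4` for the square kite),
#' hypotenuse ratio (upper/lower), branch angle (degrees from the vertical
#' stem axis, `atan(w/a)`), and kite volume (m^3) as the bicone of revolution
#' of the kite about the stem axis.
#'
#' @param ht plant height, cm (> 0)
#' @param mcd maximum canopy diameter, cm (> 0)
#' @param mcdh height at maximum canopy diameter, cm; must satisfy
#'   `trkl < mcdh < ht`
#' @param trkl trunk length to first branch, cm (>= 0)
#' @param dia optional basal stem diameter, cm
#' @param bpair optional branching pairs per 50 cm of primary stem
#' @return an object of class `kite_model`: a list with the leg lengths
#'   `a` (lower, `mcdh - trkl`), `b` (upper, `ht - mcdh`), half-width `w`
#'   (`mcd/2`), hypotenuses `h_l`, `h_u` (cm), and the traits `area_m2`,
#'   `perimeter_m`, `circularity`, `hyp_ratio`, `branch_angle_deg`,
#'   `volume_m3`.
#' @examples
#' k <- build_kite(ht = 157.7, mcd = 125.9, mcdh = 85.9, trkl = 12.2)
#' k$area_m2
#' k$branch_angle_deg
#' @export
build_kite <- function(ht, mcd, mcdh, trkl = 0, dia = NA_real_, bpair = NA_real_) {
  check_num(ht, "ht", positive = TRUE)
  check_num(mcd, "mcd", positive = TRUE)
  check_num(mcdh, "mcdh", positive = TRUE)
  check_num(trkl, "trkl", nonneg = TRUE)
  if (mcdh <= trkl) stop_bad("mcdh", "must exceed trkl (degenerate lower kite triangle)")
  if (mcdh >= ht) stop_bad("mcdh", "must be below ht (degenerate upper kite triangle)")

  a <- mcdh - trkl
  b <- ht - mcdh
  w <- mcd / 2
  h_l <- sqrt(w^2 + a^2)
  h_u <- sqrt(w^2 + b^2)
  area_cm2 <- (a + b) * w          # 1/2 * (a+b) * 2w
  per_cm <- 2 * (h_l + h_u)
  circ <- 4 * pi * area_cm2 / per_cm^2
  vol_cm3 <- (pi / 3) * w^2 * (a + b)

  structure(list(
    ht = ht, mcd = mcd, mcdh = mcdh, trkl = trkl, dia = dia, bpair = bpair,
    a = a, b = b, w = w, h_l = h_l, h_u = h_u,
    area_m2 = area_cm2 / 1e4,
    perimeter_m = per_cm / 100,
    circularity = circ,
    hyp_ratio = h_u / h_l,
    branch_angle_deg = kite_branch_angle_wa(w, a),
    volume_m3 = vol_cm3 / 1e6
  ), class = "kite_model")
}

#' @export
print.kite_model <- function(x, ...) {
  cat("2-D canopy kite model\n")
  cat(sprintf("  legs a=%.1f b=%.1f cm, half-width w=%.1f cm\n", x$a, x$b, x$w))
  cat(sprintf("  area %.3f m^2 | perimeter %.3f m | circularity %.3f\n",
              x$area_m2, x$perimeter_m, x$circularity))
  cat(sprintf("  hyp ratio %.3f | branch angle %.1f deg | volume %.4f m^3\n",
              x$hyp_ratio, x$branch_angle_deg, x$volume_m3))
  invisible(x)
}

kite_branch_angle_wa <- function(w, a) {
  if (any(a <= 0)) stop_bad("a", "lower kite leg must be > 0 (degenerate lower triangle)")
  atan(w / a) * 180 / pi
}

#' Kite branch angle
#'
#' Angle between the primary stem axis and the lower kite hypotenuse,
#' `atan(w/a)` in degrees, from the lower kite triangle (half-width `w`,
#' lower leg `a = mcdh - trkl`). 45 degrees for the square kite; tends to 0
#' in the columnar limit.
#'
#' @param k a `kite_model` from [build_kite()]
#' @return angle in degrees, in (0, 90)
#' @export
kite_branch_angle <- function(k) {
  stopifnot(inherits(k, "kite_model"))
  kite_branch_angle_wa(k$w, k$a)
}

#' Kite (canopy) volume
#'
#' Volume of the solid of revolution of the kite about the vertical stem
#' axis: two cones base-to-base, `V = (pi/3) * w^2 * (a + b)`, reported in
#' m^3.
#'
#' @param k a `kite_model`
#' @return volume in m^3
#' @export
kite_volume <- function(k) {
  stopifnot(inherits(k, "kite_model"))
  k$volume_m3
}

#' Canopy density from wet leaf mass and kite volume
#'
#' @param wet_leaf_mass_kg wet leaf mass, kg (>= 0)
#' @param k a `kite_model` with positive volume
#' @return density, kg m^-3
#' @export
canopy_density <- function(wet_leaf_mass_kg, k) {
  check_num(wet_leaf_mass_kg, "wet_leaf_mass_kg", nonneg = TRUE)
  v <- kite_volume(k)
  if (v <= 0) stop_bad("volume", "kite volume must be > 0")
  wet_leaf_mass_kg / v
}

#' Specific kite area
#'
#' Kite area per unit dry biomass (m^2 kg^-1); low values indicate small
#' plants with a high dry-biomass proportion (dense canopies).
#'
#' @param k a `kite_model`
#' @param dry_biomass_kg whole-plant dry biomass, kg (> 0)
#' @param wet_biomass_kg optional: use wet biomass as the denominator instead
#' @return m^2 kg^-1
#' @export
specific_kite_area <- function(k, dry_biomass_kg, wet_biomass_kg = NULL) {
  stopifnot(inherits(k, "kite_model"))
  denom <- if (is.null(wet_biomass_kg)) dry_biomass_kg else wet_biomass_kg
  check_num(denom, "biomass", positive = TRUE)
  k$area_m2 / denom
}

#' Dry floral biomass per unit canopy footprint
#'
#' Dry stripped floral biomass divided by the square of the maximum canopy
#' diameter (diameter converted to metres), kg m^-2.
#'
#' @param dsbm_kg dry stripped floral biomass, kg (>= 0)
#' @param mcd_cm maximum canopy diameter, cm (> 0)
#' @return kg m^-2
#' @export
floral_biomass_per_area <- function(dsbm_kg, mcd_cm) {
  check_num(dsbm_kg, "dsbm_kg", nonneg = TRUE)
  check_num(mcd_cm, "mcd_cm", positive = TRUE)
  dsbm_kg / (mcd_cm / 100)^2
}

#' Internode length from branching-pair counts
#'
#' Derived as 50 cm divided by the number of branching pairs counted along
#' 50 cm of the primary stem.
#'
#' @param bpair branching pairs per 50 cm (>= 1)
#' @return internode length, cm
#' @export
internode_length <- function(bpair) {
  check_num(bpair, "bpair")
  if (any(bpair < 1)) stop_bad("bpair", "must be >= 1")
  50 / bpair
}

#' Canopy shape ratios for archetypal analysis
#'
#' The two dimensionless ratios used to classify canopy form: maximum canopy
#' diameter to plant height, and height-at-maximum-diameter to plant height.
#' A first ratio above 1 indicates a prostrate habit (canopy wider than
#' tall).
#'
#' @param ht plant height, cm (> 0); vectorised
#' @param mcd maximum canopy diameter, cm
#' @param mcdh height at maximum canopy diameter, cm
#' @return data.frame with columns `mcd_ht`, `mcdh_ht` and logical
#'   `prostrate`
#' @export
shape_ratios <- function(ht, mcd, mcdh) {
  check_num(ht, "ht", positive = TRUE)
  check_num(mcd, "mcd", nonneg = TRUE)
  check_num(mcdh, "mcdh", nonneg = TRUE)
  data.frame(mcd_ht = mcd / ht, mcdh_ht = mcdh / ht,
             prostrate = mcd / ht > 1)
}

#' Derive all kite traits for a trait table
#'
#' Applies [build_kite()] row-wise to a data.frame with columns `HT`, `MCD`,
#' `MCDH`, `TRKL` (standard trait abbreviations) and appends the derived
#' columns `KITE` (area, m^2), `KPER` (perimeter, m), `KC` (circularity),
#' `KHR` (hypotenuse ratio), `KBA` (branch angle, deg), `KVOL` (m^3), and
#' `INL` (internode length, cm, if `BPAIR` present). Rows violating the kite
#' preconditions get `NA`s and a warning.
#'
#' @param traits data.frame of per-plant measurements
#' @return the input with kite trait columns appended
#' @export
derive_kite_traits <- function(traits) {
  need <- c("HT", "MCD", "MCDH", "TRKL")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop_bad("traits", paste("missing columns:", paste(miss, collapse = ", ")))
  n <- nrow(traits)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("KITE", "KPER", "KC", "KHR", "KBA", "KVOL")))
  bad <- 0L
  for (i in seq_len(n)) {
    k <- tryCatch(build_kite(traits$HT[i], traits$MCD[i], traits$MCDH[i], traits$TRKL[i]),
                  error = function(e) NULL)
    if (is.null(k)) { bad <- bad + 1L; next }
    out[i, ] <- c(k$area_m2, k$perimeter_m, k$circularity, k$hyp_ratio,
                  k$branch_angle_deg, k$volume_m3)
  }
  if (bad > 0L) warning(sprintf("%d row(s) failed kite validation; set to NA", bad))
  res <- cbind(traits, as.data.frame(out))
  if ("BPAIR" %in% names(traits)) {
    res$INL <- ifelse(!is.na(traits$BPAIR) & traits$BPAIR >= 1, 50 / traits$BPAIR, NA_real_)
  }
  res
}
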