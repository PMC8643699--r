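#' One-way variance components across families
#'
#' Decomposes a trait's variance into among-family and residual components
#' for a one-way random-effects (common-parent family) design. The primary
#' estimator is closed-form method of moments via expected mean squares with
#' the unbalanced-design coefficient `n0 = (N - sum(n_i^2)/N) / (k - 1)`:
#' `sigma2_residual = MSW`, `sigma2_family = max(0, (MSB - MSW)/n0)`
#' (negative estimates clamped to zero and flagged). `estimator = "REML"`
#' fits the same model with `lme4::lmer` when lme4 is available.
#'
#' @param values numeric trait values
#' @param family_ids family identifiers, same length
#' @param estimator `"MoM"` (default) or `"REML"`
#' @return object of class `variance_components`: list with `sigma2_family`,
#'   `sigma2_residual`, `n_families`, `n_total`, `n0`, `estimator`,
#'   `clamped` (logical)
#' @export
variance_components <- function(values, family_ids, estimator = c("MoM", "REML")) {
  estimator <- match.arg(estimator)
  check_num(values, "values")
  if (length(values) != length(family_ids)) stop_bad("family_ids", "length mismatch")
  fam <- factor(family_ids)
  k <- nlevels(fam)
  if (k < 2) stop_bad("family_ids", "need at least 2 families")
  N <- length(values)
  ni <- as.numeric(table(fam))

  if (estimator == "REML") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop_bad("estimator", "REML requires the lme4 package")
    }
    m <- lme4::lmer(values ~ 1 + (1 | fam),
                    data = data.frame(values = values, fam = fam))
    vc <- as.data.frame(lme4::VarCorr(m))
    s2f <- vc$vcov[vc$grp == "fam"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    return(structure(list(sigma2_family = s2f, sigma2_residual = s2e,
                          n_families = k, n_total = N, n0 = NA_real_,
                          estimator = "REML", clamped = FALSE),
                     class = "variance_components"))
  }

  grand <- mean(values)
  means <- tapply(values, fam, mean)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[fam])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  raw <- (msb - msw) / n0
  structure(list(sigma2_family = max(0, raw), sigma2_residual = msw,
                 n_families = k, n_total = N, n0 = n0,
                 estimator = "MoM", clamped = raw < 0),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (%s, %d families, N=%d): family %.4g, residual %.4g%s\n",
              x$estimator, x$n_families, x$n_total,
              x$sigma2_family, x$sigma2_residual,
              if (isTRUE(x$clamped)) " [family clamped to 0]" else ""))
  invisible(x)
}

#' Half-sib heritability from variance components
#'
#' Narrow-sense heritability under the half-sib (common-parent) assumption:
#' additive variance is four times the among-family variance, so
#' `h^2 = 4 * sigma2_F / (sigma2_F + sigma2_eps)`, capped at 1 (sampling
#' noise can push the multiplier past 1; capping is flagged). A full-sib
#' multiplier of 2 is available for sensitivity analysis.
#'
#' @param vc a `variance_components` object
#' @param multiplier 4 (half-sib, default) or 2 (full-sib)
#' @return list with `h2` (in `[0, 1]`), `h2_uncapped`, `capped` (logical)
#' @export
half_sib_h2 <- function(vc, multiplier = 4) {
  stopifnot(inherits(vc, "variance_components"))
  tot <- vc$sigma2_family + vc$sigma2_residual
  if (tot <= 0) stop_bad("vc", "both variance components are zero; h2 undefined")
  raw <- multiplier * vc$sigma2_family / tot
  list(h2 = min(1, raw), h2_uncapped = raw, capped = raw > 1)
}

#' Per-family and population trait summary
#'
#' Family means, standard errors and CVs plus population-level mean, range
#' and CV (sd/mean) for one trait. The common parent's plants (if labelled)
#' are excluded from the population-level statistics, mirroring standard
#' trial reporting.
#'
#' @param values trait values
#' @param family_ids family identifiers
#' @param common_parent optional family id to exclude from population stats
#' @return list with `family` (data.frame: family, n, mean, se, cv) and
#'   `population` (data.frame: n, mean, min, max, cv; `cv` is `NA` when the
#'   mean is zero)
#' @export
family_summary <- function(values, family_ids, common_parent = NULL) {
  check_num(values, "values")
  fam <- factor(family_ids)
  per <- do.call(rbind, lapply(levels(fam), function(f) {
    v <- values[fam == f]
    m <- mean(v)
    data.frame(family = f, n = length(v), mean = m,
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               cv = if (m != 0 && length(v) > 1) stats::sd(v) / m else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pv <- if (is.null(common_parent)) values else values[fam != common_parent]
  pm <- mean(pv)
  pop <- data.frame(n = length(pv), mean = pm, min = min(pv), max = max(pv),
                    cv = if (pm != 0) stats::sd(pv) / pm else NA_real_)
  list(family = per, population = pop)
}

#' Heritability report for a trait table
#'
#' Runs [variance_components()] + [half_sib_h2()] and [family_summary()] for
#' each named trait column.
#'
#' @param traits data.frame with a `family` column and trait columns
#' @param trait_cols character vector of trait column names
#' @param estimator passed to [variance_components()]
#' @return data.frame: trait, mean, min, max, cv, sigma2_family,
#'   sigma2_residual, h2, capped
#' @export
h2_report <- function(traits, trait_cols, estimator = "MoM") {
  if (!"family" %in% names(traits)) stop_bad("traits", "needs a `family` column")
  rows <- lapply(trait_cols, function(tc) {
    v <- traits[[tc]]
    keep <- is.finite(v)
    vc <- variance_components(v[keep], traits$family[keep], estimator)
    h <- half_sib_h2(vc)
    s <- family_summary(v[keep], traits$family[keep])
    data.frame(trait = tc, mean = s$population$mean, min = s$population$min,
               max = s$population$max, cv = s$population$cv,
               sigma2_family = vc$sigma2_family,
               sigma2_residual = vc$sigma2_residual,
               h2 = h$h2, capped = h$capped, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
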