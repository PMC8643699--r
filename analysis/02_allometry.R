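#!/usr/bin/env Rscript
# Model-II (RMA) log-log allometries of the simulated trial: the
# height/diameter and biomass/diameter power laws and the foliar
# leafing-intensity cascade. Writes results/allometry.csv.

suppressPackageStartupMessages(library(hempkite))
tr <- read_trait_table("results/traits.csv")

pairs <- list(
  ht_dia   = list(x = tr$DIA, y = tr$HT,   label = "log10 HT ~ log10 DIA"),
  wbm_dia  = list(x = tr$DIA, y = tr$WBM,  label = "log10 WBM ~ log10 DIA"),
  vol_wbm  = list(x = tr$VOL, y = tr$WBM,  label = "log10 WBM ~ log10 VOL"),
  lfdw_li  = list(x = tr$LI,  y = tr$LFDW, label = "log10 LFDW ~ log10 LI"),
  spa_li   = list(x = tr$LI,  y = tr$SPA,  label = "log10 SPA ~ log10 LI")
)

rows <- lapply(names(pairs), function(nm) {
  p <- pairs[[nm]]
  f <- fit_loglog(p$x, p$y, "RMA")
  message(sprintf("%-22s slope %+.3f [%.3f, %.3f]  R^2 %.2f",
                  p$label, f$slope, f$slope_ci[1], f$slope_ci[2], f$r_squared))
  data.frame(pair = nm, method = f$method, slope = f$slope,
             ci_lo = f$slope_ci[1], ci_hi = f$slope_ci[2],
             intercept = f$intercept, r_squared = f$r_squared, n = f$n)
})
out <- do.call(rbind, rows)
utils::write.csv(out, "results/allometry.csv", row.names = FALSE)
message("wrote results/allometry.csv")
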