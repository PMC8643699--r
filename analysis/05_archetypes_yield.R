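#!/usr/bin/env Rscript
# Archetypal classification of canopy form on the two shape ratios, the
# biomass/cannabinoid yield report, and the relative-importance
# decomposition of biomass yield. Writes results/archetypes.csv,
# results/yield.csv and results/importance.csv.

suppressPackageStartupMessages(library(hempkite))
tr <- read_trait_table("results/traits.csv")
seed <- 7L

## canopy-form archetypes (k = 4, 5 restarts) on (MCD/HT, MCDH/HT)
X <- as.matrix(shape_ratios(tr$HT, tr$MCD, tr$MCDH)[, c("mcd_ht", "mcdh_ht")])
sol <- archetypal_analysis(X, k = 4, nrep = 5, seed = seed)
asg <- assign_archetype(X, sol)
message(sprintf("archetypes (k=4, rss %.3f):", sol$rss))
print(round(sol$archetypes, 3))
message(sprintf("plants per archetype: %s", paste(table(asg$labels), collapse = ", ")))
utils::write.csv(
  data.frame(plant = tr$plant, mcd_ht = X[, 1], mcdh_ht = X[, 2],
             archetype = asg$labels, asg$weights),
  "results/archetypes.csv", row.names = FALSE)

## yield report: predicted vs simulated biomass, cannabinoid yields
pred <- predict_biomass(tr$WBM)
yield <- data.frame(plant = tr$plant, family = tr$family, wbm = tr$WBM,
                    dbm = tr$DBM, dbm_pred = pred$dbm,
                    dsbm = tr$DSBM, dsbm_pred = pred$dsbm,
                    cb_total_pct = tr$CB_total_pct, cb_yield_g = tr$CB_yield_g,
                    dsbm_per_area = tr$DSBM_area)
utils::write.csv(yield, "results/yield.csv", row.names = FALSE)
message(sprintf("mean DSBM/WBM ratio %.3f; mean cannabinoid yield %.0f g/plant",
                mean(tr$DSBM / tr$WBM), mean(tr$CB_yield_g)))

## predictor selection + LMG decomposition for dry stripped floral biomass
preds <- c("DIA", "KITE", "HT", "MCD", "VOL", "KBA", "PTFD", "SPA")
keep <- complete.cases(tr[, c("DSBM", preds)])
sw <- stepwise_aic(tr$DSBM[keep], tr[keep, preds])
message(sprintf("stepwise-AIC selected: %s", paste(sw$selected, collapse = ", ")))
li <- lmg(tr$DSBM[keep], tr[keep, sw$selected], n_boot = 1000, seed = seed)
imp <- data.frame(predictor = names(li$shares), lmg_share = li$shares,
                  ci_lo = li$ci[, 1], ci_hi = li$ci[, 2])
imp <- imp[order(-imp$lmg_share), ]
utils::write.csv(imp, "results/importance.csv", row.names = FALSE)
message(sprintf("model R^2 %.2f decomposed as:", li$r_squared))
print(imp, digits = 3, row.names = FALSE)
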