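#!/usr/bin/env Rscript
# Powdery-mildew AUDPC, its coupling to phenology, and the per-trait
# population summary with half-sib heritabilities. Writes
# results/trait_summary.csv.

suppressPackageStartupMessages(library(hempkite))
tr <- read_trait_table("results/traits.csv")

message(sprintf("AUDPC: mean %.0f %%*days (max possible 2600); final severity mean %.1f%%",
                mean(tr$AUDPC), mean(tr$PM97)))
message(sprintf("cor(AUDPC, flowering day) = %.2f",
                cor(tr$AUDPC, tr$PTFD)))

cols <- intersect(c("HT", "BPAIR", "INL", "MCD", "MCDH", "TRKL", "KITE", "KHR",
                    "KBA", "KC", "DIA", "VOL", "LFLTN", "MLFW", "MLFA", "LFDW",
                    "LFA", "LFL", "LFP", "SLA", "PTDW", "PTA", "SPA", "PTFD",
                    "TFD", "CCI", "GLI", "PM97", "AUDPC", "WBM", "DBM", "DSBM",
                    "CB_total_pct", "CB_yield_g"), names(tr))
summ <- h2_report(tr, cols)
utils::write.csv(summ, "results/trait_summary.csv", row.names = FALSE)
message("trait summary (first rows):")
print(head(summ[, c("trait", "mean", "min", "max", "cv", "h2")], 8), digits = 3)
message(sprintf("h2(DIA, log scale) = %.2f",
                half_sib_h2(variance_components(log10(tr$DIA), tr$family))$h2))
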