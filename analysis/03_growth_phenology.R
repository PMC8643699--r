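#!/usr/bin/env Rscript
# Growth-rate extraction from the weekly height series (smoothing splines),
# flowering classification, and per-family segregation patterns. Writes
# results/growth_rates.csv and results/segregation.csv.

suppressPackageStartupMessages(library(hempkite))
tr <- read_trait_table("results/traits.csv")
series <- utils::read.csv("results/height_series.csv")

rates <- do.call(rbind, lapply(split(series, series$plant), function(s) {
  s <- s[order(s$dap), ]
  f <- fit_growth(s$dap, s$height_cm)
  data.frame(plant = s$plant[1], family = s$family[1],
             max_rate = f$max_rate, day_of_max = f$day_of_max,
             mean_rate = f$mean_rate)
}))
utils::write.csv(rates, "results/growth_rates.csv", row.names = FALSE)

m <- merge(rates, tr[, c("plant", "PTFD")], by = "plant")
message(sprintf("mean growth rate %.2f cm/d; mean day of max growth %.1f DAP",
                mean(rates$mean_rate), mean(rates$day_of_max)))
message(sprintf("cor(day of max growth, flowering day) = %.2f",
                cor(m$day_of_max, m$PTFD)))

cl <- flowering_class(tr$PTFD)
seg <- segregation_counts(cl, tr$family)
utils::write.csv(seg, "results/segregation.csv", row.names = FALSE)
message(sprintf("segregation patterns: %s",
                paste(names(table(seg$closest_ratio)),
                      table(seg$closest_ratio), sep = "=", collapse = ", ")))
message(sprintf("leaflet number by class: %s",
                paste(levels(cl), round(tapply(tr$LFLTN, cl, mean), 2),
                      sep = "=", collapse = ", ")))
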