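#!/usr/bin/env Rscript
# Stage 3: Mann-Kendall / Sen trend analysis.
#
# Annual mean temperature, annual precipitation totals and the annual mean
# 1-month SPEI, tested per site at alpha = 0.05.

library(wheatmoist)

climate <- read_climate_csv("results/climate.csv")
spei <- utils::read.csv("results/spei.csv")

annual <- function(df, col, fun) {
  a <- stats::aggregate(df[[col]], by = list(site = df$site, year = df$year),
                        FUN = fun)
  names(a)[3] <- "value"
  a
}

trends <- rbind(
  cbind(series = "tmean_annual_c", trend_suite(annual(climate, "tmean_c", mean))),
  cbind(series = "precip_annual_mm", trend_suite(annual(climate, "precip_mm", sum))),
  cbind(series = "spei1_annual_mean",
        trend_suite(annual(spei[spei$scale == 1 & !is.na(spei$spei), ],
                           "spei", mean)))
)
write_table_csv(trends, "results/trends.csv")

for (se in unique(trends$series)) {
  sub <- trends[trends$series == se, ]
  cat(sprintf("%-18s %d/%d sites significant; Sen slopes %.4f to %.4f per yr\n",
              se, sum(sub$significant), nrow(sub),
              min(sub$slope), max(sub$slope)))
}
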