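#!/usr/bin/env Rscript
# Stage 2: multi-scalar SPEI.
#
# Thornthwaite PET -> monthly water balance -> trailing 1/3/6/9-month sums
# -> per-calendar-month log-logistic fit -> standard-normal index, then the
# seven-level moisture classification.

library(wheatmoist)

climate <- read_climate_csv("results/climate.csv")
spei <- compute_spei(climate, scales = c(1, 3, 6, 9))
out <- spei
out$spei <- round(out$spei, 6)
write_table_csv(out, "results/spei.csv")

defined <- spei[!is.na(spei$spei), ]
cat(sprintf("computed %d SPEI values (%d undefined leading months)\n",
            nrow(defined), sum(is.na(spei$spei))))
freq <- table(defined$level[defined$scale == 1])
cat("1-month SPEI moisture-level frequencies:\n")
for (lv in moisture_levels()) {
  cat(sprintf("  %-17s %5.1f%%\n", lv, 100 * freq[[lv]] / sum(freq)))
}
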