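#!/usr/bin/env Rscript
# Stage 1: simulate the study world.
#
# Ten sites spanning 31-35 degrees N with the documented north-dry/south-wet
# gradient, monthly records 1979-2014 (36 years), then winter-wheat yields
# for harvest years 1980-2014 generated from the quadratic fixed-effects
# model with AR(1) errors, driven by the late-growth-stage 3-month SPEI of
# the simulated climate itself.

library(wheatmoist)

seed <- 1L
dir.create("results", showWarnings = FALSE)

sites <- default_sites()
climate <- generate_climate(sites, start_year = 1979, n_years = 36,
                            seed = seed)
write_table_csv(climate, "results/climate.csv")

spei3 <- compute_spei(climate, scales = 3)
cov <- season_covariate(spei3, "S3", 1980:2014, 3)
yields <- generate_yields(cov, default_panel_params(), seed = seed + 1)
write_table_csv(yields, "results/yield.csv")

cat(sprintf("simulated %d climate records for %d sites (1979-2014)\n",
            nrow(climate), length(sites)))
cat(sprintf("simulated %d site-year yields; range %.2f-%.2f t/ha\n",
            nrow(yields), min(yields$yield_t_ha), max(yields$yield_t_ha)))
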