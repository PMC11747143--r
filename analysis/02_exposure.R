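#!/usr/bin/env Rscript
# Turn the daily salinity series into the exposure covariates: for every
# station-year, total days and maximum consecutive days within each salinity
# bin (0-1, 1-3, 3-5, 5-7, 7-9 psu) over the 123-day summer window.

library(oysterthresh)

salinity <- read_salinity_csv("results/salinity.csv")
exposure <- build_exposure_table(salinity)
write_exposure_csv(exposure, "results/exposure.csv")

cat("station-years:", nrow(exposure),
    "| covariate columns:", ncol(exposure) - 3, "\n")
cat("continuous days <1 psu (c.d_su0.1): median",
    median(exposure$c.d_su0.1), ", range",
    paste(range(exposure$c.d_su0.1), collapse = "-"), "\n")
cat("total days in 7-9 psu (s_d_su7.9): median",
    median(exposure$s_d_su7.9), "\n")
cat("wrote results/exposure.csv\n")
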