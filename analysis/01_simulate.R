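#!/usr/bin/env Rscript
# Generate the synthetic monitoring data the analysis runs on: daily salinity
# for 3 basins x 6 stations x 2016-2020 with injected summer low-salinity
# events, and dredge-style abundance records drawn from the hierarchical
# model with a planted slope of -0.6 on continuous summer days below 1 psu.

library(oysterthresh)

seed <- 20260923L %% .Machine$integer.max
dir.create("results", showWarnings = FALSE)

fx <- make_fixture("negative-slope-east", seed = seed)

write_salinity_csv(fx$salinity, "results/salinity.csv")
write_dredge_csv(fx$records, "results/dredge_records.csv")
writeLines(c(
  paste0("scenario: negative-slope-east"),
  paste0("seed: ", seed),
  paste0("gamma.c.d_su0.1: ", fx$truth$gamma[["c.d_su0.1"]]),
  paste0("sigma: ", fx$truth$sigma),
  paste0("sigma_station: ", fx$truth$sigma_station),
  paste0("alpha: ", paste(names(fx$truth$alpha), fx$truth$alpha,
                          sep = "=", collapse = ", "))),
  "results/truth.meta")

cat("stations:", length(unique(fx$salinity$station_id)),
    "| daily rows:", nrow(fx$salinity),
    "| dredge records:", nrow(fx$records), "\n")
cat("salinity range:", paste(round(range(fx$salinity$salinity), 1), collapse = "-"),
    "psu\n")
cat("wrote results/salinity.csv, results/dredge_records.csv, results/truth.meta\n")
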