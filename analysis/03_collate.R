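#!/usr/bin/env Rscript
# Collapse the dredge records to the fall abundance response (mean oysters
# per dredge by station-year-stage) and compute each basin's critical
# abundance: half the five-year mean, the level the Bayesian threshold sweep
# tests against.

library(oysterthresh)

records <- read_dredge_csv("results/dredge_records.csv")
abundance <- collate_season(records, "fall")
write.csv(abundance, "results/abundance_fall.csv", row.names = FALSE)

crit <- do.call(rbind, lapply(unique(abundance$basin_id), function(b) {
  cc <- critical_abundance(abundance, b, "fall", "spat")
  data.frame(basin_id = b, season = cc$season, stage = cc$stage,
             critical = cc$value)
}))
write.csv(crit, "results/critical_abundance.csv", row.names = FALSE)

cat("abundance rows:", nrow(abundance), "\n")
print(crit, row.names = FALSE)
cat("wrote results/abundance_fall.csv, results/critical_abundance.csv\n")
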