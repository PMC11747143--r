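#!/usr/bin/env Rscript
# The random-forest branch: fit abundance on the ten exposure covariates,
# keep the model only if its out-of-bag r-squared clears 0.75, rank variables
# by node purity, select the interpretation variable (lowest bin if the top
# three are tightly grouped), read the partial-dependence changepoint, and
# convert it to a day threshold with the subtract-from-window rule.

library(oysterthresh)

seed <- 20260923L %% .Machine$integer.max
abundance <- read.csv("results/abundance_fall.csv")
exposure <- read_exposure_csv("results/exposure.csv")
d <- merge(abundance, exposure, by = c("station_id", "basin_id", "year"))
cov_cols <- setdiff(names(exposure), c("station_id", "basin_id", "year"))

rf <- fit_rf(d[, cov_cols], d$abundance, rf_settings(seed = seed))
cat(sprintf("oob r-squared: %.3f -> %s\n", rf$oob_r2,
            ifelse(rf$retained, "retained", "NOT retained (<= 0.75)")))
if (!rf$retained) quit(save = "no")

rank <- variable_importance(rf)
print(head(rank, 5), row.names = FALSE)
write.csv(rank, "results/rf_importance.csv", row.names = FALSE)

var <- select_interpretation_variable(rank)
cat("interpretation variable:", var, "\n")
pdp <- partial_dependence(rf, var)
write.csv(pdp, "results/rf_pdp.csv", row.names = FALSE)
cp <- detect_changepoint(pdp)
if (is.na(cp)) {
  cat("partial dependence is flat: no changepoint\n")
  quit(save = "no")
}
cat("changepoint at", cp, "days\n")
p <- oysterthresh:::parse_exposure_column(var)
# a decline inside the lowest bin reads directly; a rise in a safe bin is
# converted by subtraction from the 123-day summer window
direct <- p$lower == 0
th <- rf_interpretation_rule("summer", cp, sprintf("%g-%g", p$lower, p$upper),
                             p$kind, direct = direct)
cat(sprintf("threshold: salinity %s, %d %s summer days (%s)\n",
            th$salinity, th$days, th$exposure,
            ifelse(direct, "direct", "subtracted from 123")))
write.csv(th, "results/rf_thresholds.csv", row.names = FALSE)
cat("wrote results/rf_importance.csv, results/rf_pdp.csv, results/rf_thresholds.csv\n")
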