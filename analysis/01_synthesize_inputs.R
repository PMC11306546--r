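#!/usr/bin/env Rscript
# Step 1: build the synthetic geography input table.
#
# Real runs of this model consume per-geography wage and overhead tables
# assembled from the BLS OEWS survey and commercial overhead surveys; those
# per-area tables are not redistributable here. This step generates a
# synthetic stand-in with the same statistical structure — near-symmetric
# cross-geography wage variation around a $23.51/h CHW mean, right-skewed
# overhead around $43.65 per work-hour with transportation near 65% of the
# total, and longer travel times in non-metropolitan areas — so every later
# step runs end-to-end.

suppressPackageStartupMessages(library(chwpay))

dir.create("results", showWarnings = FALSE)
cfg <- synth_config()  # 52 "states", one metro + one non-metro area each
geos <- generate_geographies(cfg, path = "results/inputs_synthetic.csv")

chw <- sapply(geos, function(g) g$chw_wage$mean)
oh <- sapply(geos, function(g) g$overhead$total)
share <- sapply(geos, function(g) g$overhead$rates[["transportation"]] / g$overhead$total)
tt <- sapply(geos, `[[`, "travel_time_hours")
metro <- sapply(geos, `[[`, "metro")

cat(sprintf("generated %d geographies (%d states) -> results/inputs_synthetic.csv\n",
            length(geos), cfg$n_states))
cat(sprintf("CHW wage:   mean $%.2f/h, range $%.2f-$%.2f\n",
            mean(chw), min(chw), max(chw)))
cat(sprintf("overhead:   mean $%.2f/h, range $%.2f-$%.2f (right-skewed)\n",
            mean(oh), min(oh), max(oh)))
cat(sprintf("transport:  %.1f%% of overhead on average\n", 100 * mean(share)))
cat(sprintf("travel:     %.2f h metro vs %.2f h non-metro per in-person visit\n",
            mean(tt[metro]), mean(tt[!metro])))
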