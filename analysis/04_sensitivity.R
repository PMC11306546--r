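#!/usr/bin/env Rscript
# Step 4: the two prespecified sensitivity analyses. Requires step 01.
#
# (a) Supervisor substitution: replace the RN care manager (1:8) with an
#     MSW supervisor (1:6), reusing the same seed so both scenarios see
#     identical input draws and the contrast is purely structural.
# (b) Panel-size sweep: rescale the national baseline across panels 15-100
#     by the inverse-panel law, draw by draw, so credible intervals rescale
#     by the same factor as the means.

suppressPackageStartupMessages(library(chwpay))

stopifnot(file.exists("results/inputs_synthetic.csv"))
geos <- load_geography_inputs("results/inputs_synthetic.csv")
cfg <- sim_config(n_draws = 10000, seed = 20230)

swap <- supervisor_swap(geos, config = cfg)
cat("supervisor substitution (national):\n")
for (k in names(swap)) {
  cat(sprintf("  %-3s FFS $%.2f (%.2f, %.2f)  PMPM $%.2f (%.2f, %.2f)\n", k,
              swap[[k]]$ffs_rate, swap[[k]]$ffs_ci_low, swap[[k]]$ffs_ci_high,
              swap[[k]]$pmpm_rate, swap[[k]]$pmpm_ci_low, swap[[k]]$pmpm_ci_high))
}
write_results(swap, "results/sensitivity_supervisor.csv")

baseline <- simulate_aggregate(geos, config = cfg)
sweep <- panel_sweep(baseline)
cat("\npanel-size sweep (national):\n")
print(sweep)
df <- as.data.frame(sweep)
df$label <- sprintf("NATIONAL@panel=%g", df$panel_size)
utils::write.csv(
  data.frame(panel_size = df$panel_size,
             ffs = round(df$ffs_rate, 2), ffs_lo = round(df$ffs_ci_low, 2),
             ffs_hi = round(df$ffs_ci_high, 2),
             pmpm = round(df$pmpm_rate, 2), pmpm_lo = round(df$pmpm_ci_low, 2),
             pmpm_hi = round(df$pmpm_ci_high, 2)),
  "results/sensitivity_panel.csv", row.names = FALSE)
cat("\nwrote results/sensitivity_supervisor.csv, results/sensitivity_panel.csv\n")
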