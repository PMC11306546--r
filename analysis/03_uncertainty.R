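#!/usr/bin/env Rscript
# Step 3: Monte Carlo uncertainty propagation over the synthetic table.
#
# For every geography, samples the uncertain inputs (wages and overhead
# components) 10,000 times from normal distributions around their means and
# sds, computes the break-even rates within each draw, and summarizes the
# draw distribution as a mean with a 95% percentile credible interval.
# State, metro/non-metro and national aggregates average the per-draw
# thresholds across geographies within each draw. Requires step 01.

suppressPackageStartupMessages(library(chwpay))

stopifnot(file.exists("results/inputs_synthetic.csv"))
res <- run_pipeline("results/inputs_synthetic.csv", out_dir = "results",
                    config = sim_config(n_draws = 10000, seed = 20230))

nat <- res$aggregates$NATIONAL
cat(sprintf("\nnational FFS : $%.2f (95%% CI %.2f, %.2f) per 30-min visit\n",
            nat$ffs_rate, nat$ffs_ci_low, nat$ffs_ci_high))
cat(sprintf("national PMPM: $%.2f (95%% CI %.2f, %.2f) per member-month\n",
            nat$pmpm_rate, nat$pmpm_ci_low, nat$pmpm_ci_high))
cat(sprintf("metro vs non-metro FFS: $%.2f vs $%.2f\n",
            res$aggregates$METRO$ffs_rate, res$aggregates$NONMETRO$ffs_rate))

writeLines(render_report(res), "results/report.md")
cat("wrote results/thresholds.csv, results/thresholds.json, results/report.md\n")
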