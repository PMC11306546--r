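#!/usr/bin/env Rscript
# Step 2: deterministic worked example at the national mean inputs.
#
# Composes the annual cost of supporting one full-time CHW (2080 paid
# hours): labor at $23.51/h, an RN care-manager supervisor at $39.88/h
# shared across 8 CHWs, and $43.65/h of overhead. Converts the monthly cost
# into the two break-even payment rates given a 65-patient panel and the
# 30-minute visit model with a 1:3 in-person-to-virtual mix.

suppressPackageStartupMessages(library(chwpay))

g <- fixture_national()
plan <- staffing_plan()     # RN, 1:8, 2080 h
svc <- service_model()      # panel 65, 0.5 h visits, 25% in person

cb <- total_cost(g, plan)
print(cb)

visits <- monthly_visit_capacity(svc, g$travel_time_hours, plan)
est <- point_thresholds(g, plan, svc)
cat(sprintf("\nvisit capacity: %.2f visits/month at %.2f h travel per in-person visit\n",
            visits, g$travel_time_hours))
cat(sprintf("break-even FFS : $%.2f per 30-min visit\n", est$ffs_rate))
cat(sprintf("break-even PMPM: $%.2f per member per month (panel %d)\n",
            est$pmpm_rate, svc$panel_size))
cat(sprintf("patients served per CHW-year: %.0f (panel x 12/enrollment months)\n",
            svc$panel_size * 12 / svc$enrollment_months))

dir.create("results", showWarnings = FALSE)
write_results(list(est), "results/baseline_national.csv")
cat("\nwrote results/baseline_national.csv\n")
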