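#!/usr/bin/env Rscript
# Two validation analyses on the included cohort:
#  (a) CD19 vs CD20 as the denominator B cell marker — count agreement and
#      co-expression;
#  (b) conventional age-group percentile references vs the continuous model —
#      boundary discontinuities of the step reference against the bounded
#      per-day movement of the fitted curve, and an overlay table.

suppressPackageStartupMessages(library(refcurveB))

included <- read_cohort("results/included.csv")
age <- cohort_age_years(included)

mk <- compare_markers(included)
print(mk)
utils::write.csv(
  data.frame(n = mk$n,
             median_abs_count_diff = mk$median_abs_count_diff,
             min_abs_count_diff = mk$range_abs_count_diff[1],
             max_abs_count_diff = mk$range_abs_count_diff[2],
             coexpression_pct = mk$coexpression_pct,
             median_naive_pct_diff = mk$median_naive_pct_diff,
             median_switched_pct_diff = mk$median_switched_pct_diff),
  "results/marker_comparison.csv", row.names = FALSE)

refs <- read_reference("results/reference.csv")
cat("\nGrouped (step) references vs the continuous model:\n")
rows <- list()
for (key in c("naive_pct_cd19", "nonswitched_pct_cd19", "memory_pct_cd19")) {
  grp <- grouped_reference(age, included[[key]],
                           subset = strsplit(key, "_")[[1]][1])
  jump <- max(step_discontinuity(grp, 50))
  # the continuous curve cannot move faster than its derivative bound
  fit <- refs[[key]]$fit
  daily <- max_daily_increment(fit)
  cat(sprintf("  %-22s max median jump %6.2f vs max daily curve move %7.4f\n",
              key, jump, daily))
  rows[[key]] <- data.frame(key = key, max_median_jump = jump,
                            max_daily_increment = daily)
}
utils::write.csv(do.call(rbind, rows), "results/step_discontinuity.csv",
                 row.names = FALSE)

grp <- grouped_reference(age, included$nonswitched_pct_cd19,
                         subset = "nonswitched", measure = "pct_cd19")
ov <- overlay_report(grp, refs$nonswitched_pct_cd19)
utils::write.csv(ov, "results/overlay_nonswitched.csv", row.names = FALSE)
cat(sprintf("\nNon-switched overlay: grouped 10th-90th band outside the continuous\n90%% band at %.0f%% of grid ages\n",
            100 * attr(ov, "fraction_outside")))
cat("Wrote results/marker_comparison.csv, results/step_discontinuity.csv, results/overlay_nonswitched.csv\n")
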