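#!/usr/bin/env Rscript
# Fit the three-parameter exponential model to every subset x measure of the
# included cohort, build the 0.90/0.95 residual-quantile reference bands,
# and export the reference table plus a dense age grid of limits (the
# machine-readable reference chart a laboratory system would ingest).

suppressPackageStartupMessages(library(refcurveB))

included <- read_cohort("results/included.csv")
refs <- fit_cohort_references(included)

utils::write.csv(fit_table(refs), "results/fits.csv", row.names = FALSE)
write_reference(refs, "results/reference.csv")

grid <- do.call(rbind, lapply(names(refs), function(key)
  cbind(data.frame(key = key), reference_grid(refs[[key]]))))
utils::write.csv(grid, "results/reference_grid.csv", row.names = FALSE)

cat("Fitted", length(refs), "reference models on n =", nrow(included),
    "included subjects\n\n")
for (key in c("naive_pct_cd19", "memory_pct_cd19", "totalB_abs_cd19")) {
  f <- refs[[key]]$fit
  cat(sprintf("%-18s y = %.2f + %.2f * exp(%.3f * age)   (SSR %.0f)\n",
              key, f$a, f$b, f$c, f$ssr))
}
cat(sprintf("\nPredicted naive fraction: %.1f%% at birth, %.1f%% at 18 y\n",
            predict(refs$naive_pct_cd19$fit, 0),
            predict(refs$naive_pct_cd19$fit, 18)))
cat(sprintf("Predicted total CD19+ count: %.0f cells/ul at birth, %.0f at 18 y\n",
            predict(refs$totalB_abs_cd19$fit, 0),
            predict(refs$totalB_abs_cd19$fit, 18)))
cat("Wrote results/fits.csv, results/reference.csv, results/reference_grid.csv\n")

# optional chart of the naive-fraction reference
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  g <- reference_grid(refs$naive_pct_cd19)
  p <- ggplot(g, aes(age_years)) +
    geom_point(data = data.frame(age = cohort_age_years(included),
                                 y = included$naive_pct_cd19),
               aes(age, y), size = 0.6, alpha = 0.5) +
    geom_line(aes(y = predicted), color = "darkgreen") +
    geom_line(aes(y = lower90), color = "darkgreen", linetype = "dashed") +
    geom_line(aes(y = upper90), color = "darkgreen", linetype = "dashed") +
    geom_line(aes(y = lower95), color = "darkgreen", linetype = "dotted") +
    geom_line(aes(y = upper95), color = "darkgreen", linetype = "dotted") +
    labs(x = "age (years)", y = "naive B cells (% of CD19+)",
         title = "Continuous reference: naive B cell fraction") +
    theme_minimal()
  ggsave("results/naive_reference.png", p, width = 7, height = 4, dpi = 150)
  cat("Wrote results/naive_reference.png\n")
}
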