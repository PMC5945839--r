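#!/usr/bin/env Rscript
# Per-patient use of the continuous references: a 7-month-old with a
# complete lack of switched memory B cells but normal naive, non-switched
# and memory counts — the immunophenotype of CD40 ligand deficiency (absent
# class switching). The calculator flags only the switched compartment.

suppressPackageStartupMessages(library(refcurveB))

refs <- read_reference("results/reference.csv")
age <- 7 / 12

# plausible panel: on-curve values everywhere except switched memory = 0
panel <- c(
  naive_abs_cd19 = round(reference_grid(refs$naive_abs_cd19, age)$predicted),
  nonswitched_abs_cd19 =
    round(reference_grid(refs$nonswitched_abs_cd19, age)$predicted),
  memory_abs_cd19 =
    round(reference_grid(refs$nonswitched_abs_cd19, age)$predicted),
  switched_abs_cd19 = 0)

ev <- evaluate_patient(panel, age, refs)
cols <- c("measure", "observed", "predicted", "lower90", "upper90",
          "flag90", "flag95", "abnormal")
print(ev[, cols], row.names = FALSE, digits = 4)
utils::write.csv(ev, "results/patient_evaluation.csv", row.names = FALSE)

ab <- ev$measure[ev$abnormal]
cat("\nFlagged abnormal:", if (length(ab)) paste(ab, collapse = ", ")
    else "none", "\n")
cat("Wrote results/patient_evaluation.csv\n")
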