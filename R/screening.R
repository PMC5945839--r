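#' Apply study inclusion/exclusion criteria to a cohort manifest
#'
#' Each record is assigned to exactly one category, tested in fixed priority
#' order: abnormal screening (positive CRP / abnormal blood counts, or age
#' at or above 18 years), then missing laboratory parameters, then
#' insufficient material for flow cytometry; everything else is included.
#' Multi-flag records are therefore counted once, matching a mutually
#' exclusive exclusion accounting.
#'
#' @param records a data.frame with columns `subject_id`, `age_days`,
#'   `crp_positive_or_abnormal_counts`, `labs_missing`,
#'   `material_insufficient`. An empty data.frame is allowed.
#' @return Object of class `screening_report`: counts per category, the
#'   included subject ids, and the per-record `category` vector (in input
#'   order).
#' @export
screen_cohort <- function(records) {
  need <- c("subject_id", "age_days", "crp_positive_or_abnormal_counts",
            "labs_missing", "material_insufficient")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("screen_cohort: missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(records$subject_id[duplicated(records$subject_id)])
  if (length(dup))
    stop("screen_cohort: duplicate subject_id: ", paste(dup, collapse = ", "))

  n <- nrow(records)
  category <- character(n)
  if (n) {
    abnormal <- as.logical(records$crp_positive_or_abnormal_counts) |
      records$age_days >= 18 * 365
    labs <- !abnormal & as.logical(records$labs_missing)
    material <- !abnormal & !labs & as.logical(records$material_insufficient)
    category <- ifelse(abnormal, "abnormal",
                ifelse(labs, "missing_labs",
                ifelse(material, "insufficient_material", "included")))
  }
  structure(
    list(n_assessed = n,
         n_excluded_abnormal = sum(category == "abnormal"),
         n_excluded_missing_labs = sum(category == "missing_labs"),
         n_excluded_insufficient_material =
           sum(category == "insufficient_material"),
         n_included = sum(category == "included"),
         included_ids = records$subject_id[category == "included"],
         category = category),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Cohort screening report\n")
  cat("  assessed:                     ", x$n_assessed, "\n")
  cat("  excluded, abnormal counts/CRP:", x$n_excluded_abnormal, "\n")
  cat("  excluded, missing labs:       ", x$n_excluded_missing_labs, "\n")
  cat("  excluded, insufficient material:",
      x$n_excluded_insufficient_material, "\n")
  cat("  included:                     ", x$n_included, "\n")
  invisible(x)
}

#' Keep only the subjects passing screening
#'
#' @param cohort a cohort data.frame.
#' @param report optional precomputed [screen_cohort()] report for the same
#'   records.
#' @return The included rows of `cohort`.
#' @export
filter_included <- function(cohort, report = screen_cohort(cohort)) {
  stopifnot(length(report$category) == nrow(cohort))
  cohort[report$category == "included", , drop = FALSE]
}

#' Screening report as a one-row table
#' @param report a [screen_cohort()] report.
#' @return One-row data.frame of the counts.
#' @export
screening_table <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  data.frame(n_assessed = report$n_assessed,
             n_excluded_abnormal = report$n_excluded_abnormal,
             n_excluded_missing_labs = report$n_excluded_missing_labs,
             n_excluded_insufficient_material =
               report$n_excluded_insufficient_material,
             n_included = report$n_included)
}
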