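#' Evaluate a patient's subset panel against continuous references
#'
#' For every measured value the matching reference gives the age-dependent
#' predicted value and the clamped lower/upper limits at each confidence
#' probability; the observation is flagged `below`, `within` or `above`
#' per band. Intervals are closed: a value exactly on a limit counts as
#' within (clinical convention). A result outside the widest band is
#' marked abnormal, mirroring how such values are highlighted when
#' reference ranges are embedded in a laboratory information system.
#'
#' @param panel named numeric vector or one-row data.frame of observed
#'   values; names are measurement keys such as `"switched_abs_cd19"`.
#' @param age_years patient age in years, in \[0, 18\]. Older patients are
#'   rejected rather than extrapolated: the model is fitted on children.
#' @param references named list of `continuous_reference` objects keyed
#'   like the panel. A panel entry without a matching reference yields a
#'   warning and an NA row; the remaining entries are still evaluated.
#' @return data.frame (class `reference_evaluation`): one row per panel
#'   entry with `measure`, `age_years`, `observed`, `predicted`,
#'   `lower`/`upper` limits and `flag_` column per confidence, and
#'   `abnormal`.
#' @export
evaluate_patient <- function(panel, age_years, references) {
  if (is.data.frame(panel)) {
    stopifnot(nrow(panel) == 1L)
    panel <- unlist(panel[1, , drop = TRUE])
  }
  if (is.null(names(panel)) || !all(nzchar(names(panel))))
    stop("evaluate_patient: panel values must be named by measurement key")
  if (!is.numeric(age_years) || length(age_years) != 1L ||
      age_years < 0 || age_years > 18)
    stop("evaluate_patient: 'age_years' must be a single age in [0, 18]")

  confs <- NULL
  rows <- lapply(names(panel), function(key) {
    obs <- unname(panel[[key]])
    ref <- references[[key]]
    if (is.null(ref)) {
      warning("evaluate_patient: no reference for '", key, "'")
      return(data.frame(measure = key, age_years = age_years, observed = obs,
                        predicted = NA_real_, stringsAsFactors = FALSE))
    }
    g <- reference_grid(ref, age_years)
    row <- data.frame(measure = key, age_years = age_years, observed = obs,
                      predicted = g$predicted, stringsAsFactors = FALSE)
    widest_within <- TRUE
    for (nm in names(ref$bands)) {
      lo <- g[[paste0("lower", nm)]]
      hi <- g[[paste0("upper", nm)]]
      flag <- if (obs < lo) "below" else if (obs > hi) "above" else "within"
      row[[paste0("lower", nm)]] <- lo
      row[[paste0("upper", nm)]] <- hi
      row[[paste0("flag", nm)]] <- flag
      widest_within <- flag == "within"   # bands are sorted; last is widest
    }
    row$abnormal <- !widest_within
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r)))
      r[[nm]] <- if (startsWith(nm, "flag")) NA_character_ else NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reference_evaluation", "data.frame")
  out
}

#' Compare CD19 and CD20 as the denominator B cell marker
#'
#' Summarizes the agreement between CD19- and CD20-based total B cell
#' quantification across a cohort: the median and range of the per-subject
#' absolute count difference, the fraction of CD19+ B cells co-expressing
#' CD20 (per-subject CD20/CD19 count ratio, capped at 1, averaged), and —
#' when CD20-denominated fraction columns are present — the median
#' per-subject difference of the naive and switched-memory fractions under
#' the two denominators (CD19 minus CD20).
#'
#' @param cohort a cohort data.frame carrying `totalB_abs_cd19` and
#'   `totalB_abs_cd20`; optionally `naive_pct_cd19`/`naive_pct_cd20` and
#'   `switched_pct_cd19`/`switched_pct_cd20`.
#' @return Object of class `marker_comparison` (a list): `n`,
#'   `median_abs_count_diff`, `range_abs_count_diff`, `coexpression_pct`,
#'   `median_naive_pct_diff`, `median_switched_pct_diff`.
#' @export
compare_markers <- function(cohort) {
  need <- c("totalB_abs_cd19", "totalB_abs_cd20")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("compare_markers: missing column(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(cohort[, need])
  cd19 <- cohort$totalB_abs_cd19[keep]
  cd20 <- cohort$totalB_abs_cd20[keep]
  if (!length(cd19))
    stop("compare_markers: no complete CD19/CD20 count pairs")
  d <- abs(cd19 - cd20)
  pos <- cd19 > 0                    # co-expression undefined at zero counts
  pct_diff <- function(a, b) {
    if (all(c(a, b) %in% names(cohort))) {
      x <- cohort[[a]] - cohort[[b]]
      stats::median(x, na.rm = TRUE)
    } else NA_real_
  }
  structure(
    list(n = length(cd19),
         median_abs_count_diff = stats::median(d),
         range_abs_count_diff = range(d),
         coexpression_pct = 100 * mean(pmin(cd20[pos] / cd19[pos], 1)),
         median_naive_pct_diff = pct_diff("naive_pct_cd19", "naive_pct_cd20"),
         median_switched_pct_diff = pct_diff("switched_pct_cd19",
                                             "switched_pct_cd20")),
    class = "marker_comparison")
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat("CD19 vs CD20 B cell marker comparison (n =", x$n, ")\n")
  cat(sprintf("  median |CD19 - CD20| count difference: %.1f cells/ul (range %.1f-%.1f)\n",
              x$median_abs_count_diff, x$range_abs_count_diff[1],
              x$range_abs_count_diff[2]))
  cat(sprintf("  CD20 co-expression among CD19+ B cells: %.1f%%\n",
              x$coexpression_pct))
  if (!is.na(x$median_naive_pct_diff))
    cat(sprintf("  median naive fraction difference (CD19 - CD20): %.1f points\n",
                x$median_naive_pct_diff))
  if (!is.na(x$median_switched_pct_diff))
    cat(sprintf("  median switched fraction difference (CD19 - CD20): %.1f points\n",
                x$median_switched_pct_diff))
  invisible(x)
}
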