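# Shared table IO: delimited text, human-auditable, numbers at 12
# significant digits so write -> read -> write is byte-identical.

required_cohort_cols <- c("subject_id", "age_days", "sex",
                          "crp_positive_or_abnormal_counts", "labs_missing",
                          "material_insufficient")

known_measure_cols <- c(
  "lymphocytes_abs",
  "totalB_pct_cd19", "totalB_abs_cd19", "totalB_abs_cd20", "totalB_pct_cd20",
  "naive_pct_cd19", "naive_abs_cd19", "naive_pct_cd20", "naive_abs_cd20",
  "nonswitched_pct_cd19", "nonswitched_abs_cd19",
  "nonswitched_pct_cd20", "nonswitched_abs_cd20",
  "switched_pct_cd19", "switched_abs_cd19",
  "switched_pct_cd20", "switched_abs_cd20",
  "memory_pct_cd19", "memory_abs_cd19", "memory_pct_cd20", "memory_abs_cd20")

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)     # 12 significant digits, no padding
  out[is.na(x)] <- ""
  out
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

write_table_12g <- function(df, path, delim = ",") {
  out <- df
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table
#'
#' Reads a delimited cohort file (comma or tab, sniffed from the header):
#' one row per subject with identifier, age in days, sex, screening flags
#' (encoded 0/1) and measurement columns named
#' `<subset>_<measure>_<denominator>`. Validation failures name the
#' offending column or subject.
#'
#' @param path file path.
#' @param delim field delimiter; default sniffs `","` vs `"\t"`.
#' @return A `cohort` data.frame.
#' @export
read_cohort <- function(path, delim = sniff_delim(path)) {
  if (!file.exists(path)) stop("read_cohort: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(required_cohort_cols, names(df))
  if (length(miss))
    stop("read_cohort: missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(required_cohort_cols, known_measure_cols))
  if (length(extra))
    warning("read_cohort: unknown column(s) preserved: ",
            paste(extra, collapse = ", "))
  for (nm in c("crp_positive_or_abnormal_counts", "labs_missing",
               "material_insufficient")) {
    v <- df[[nm]]
    if (!all(v %in% c(0L, 1L, TRUE, FALSE)))
      stop("read_cohort: column '", nm, "' must be encoded 0/1")
    df[[nm]] <- as.logical(v)
  }
  if (anyNA(df$age_days) || !is.numeric(df$age_days))
    stop("read_cohort: 'age_days' must be numeric and complete")
  bad <- df$age_days < 0
  if (any(bad))
    stop("read_cohort: negative age_days for subject(s): ",
         paste(df$subject_id[bad], collapse = ", "))
  for (nm in intersect(known_measure_cols, names(df))) {
    v <- df[[nm]]
    if (!is.numeric(v))
      stop("read_cohort: column '", nm, "' must be numeric")
    if (any(is.infinite(v) | is.nan(v)))
      stop("read_cohort: non-finite values in column '", nm, "'")
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write a cohort table
#'
#' @param cohort a cohort data.frame.
#' @param path output file path.
#' @param delim field delimiter (`","` or `"\t"`).
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  miss <- setdiff(required_cohort_cols, names(cohort))
  if (length(miss))
    stop("write_cohort: missing required column(s): ",
         paste(miss, collapse = ", "))
  write_table_12g(as.data.frame(cohort), path, delim)
}

reference_key <- function(ref) {
  paste(ref$fit$subset, ref$fit$measure, sep = "_")
}

#' Serialize continuous references to a delimited table
#'
#' One row per reference: subset, measure, denominator, the fitted
#' parameters (a, b, c), n, SSR, the band offsets at each confidence, the
#' clamp policy and the supported age domain — a human-auditable encoding
#' of the full reference model, suitable for laboratory sign-off and
#' re-loading with [read_reference()].
#'
#' @param references named list of `continuous_reference` objects; names
#'   are measurement keys (`<subset>_<measure>_<denominator>`).
#' @param path output file path.
#' @param delim field delimiter.
#' @return The path, invisibly.
#' @export
write_reference <- function(references, path, delim = ",") {
  stopifnot(length(references) > 0)
  rows <- lapply(names(references), function(key) {
    ref <- references[[key]]
    stopifnot(inherits(ref, "continuous_reference"))
    parts <- strsplit(key, "_")[[1]]
    row <- data.frame(
      key = key,
      subset = parts[1],
      measure = if (length(parts) > 1) parts[2] else NA_character_,
      denominator = if (length(parts) > 2) parts[3] else NA_character_,
      measure_kind = ref$measure_kind,
      a = ref$fit$a, b = ref$fit$b, c = ref$fit$c,
      n = ref$fit$n, ssr = ref$fit$ssr,
      stringsAsFactors = FALSE)
    for (nm in names(ref$bands)) {
      row[[paste0("lower", nm)]] <- ref$bands[[nm]]$lower_offset
      row[[paste0("upper", nm)]] <- ref$bands[[nm]]$upper_offset
    }
    row$clamp_low <- ref$clamp_low
    row$clamp_high <- ref$clamp_high
    row$age_min <- ref$fit$age_range[1]
    row$age_max <- ref$fit$age_range[2]
    row
  })
  write_table_12g(do.call(rbind, rows), path, delim)
}

#' Read continuous references back from a table
#'
#' Inverse of [write_reference()]. The reconstructed references carry the
#' fitted parameters, band offsets and clamp policy (not the original
#' residual vectors, which the serialized model no longer needs).
#'
#' @param path file path.
#' @param delim field delimiter; default sniffs the header.
#' @return Named list of `continuous_reference` objects.
#' @export
read_reference <- function(path, delim = sniff_delim(path)) {
  if (!file.exists(path)) stop("read_reference: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, na.strings = "")
  need <- c("key", "measure_kind", "a", "b", "c", "n", "ssr",
            "clamp_low", "clamp_high", "age_min", "age_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_reference: missing column(s): ", paste(miss, collapse = ", "))
  band_cols <- grep("^lower", names(df), value = TRUE)
  confs <- sub("^lower", "", band_cols)
  refs <- lapply(seq_len(nrow(df)), function(i) {
    fit <- structure(
      list(a = df$a[i], b = df$b[i], c = df$c[i],
           fitted = NULL, residuals = NULL, ssr = df$ssr[i], n = df$n[i],
           converged = TRUE, subset = df$subset[i],
           measure = paste(stats::na.omit(c(df$measure[i],
                                            df$denominator[i])),
                           collapse = "_"),
           age_range = c(df$age_min[i], df$age_max[i])),
      class = "exp_fit")
    bands <- lapply(confs, function(cc) {
      structure(list(confidence = as.numeric(cc) / 100,
                     lower_offset = df[[paste0("lower", cc)]][i],
                     upper_offset = df[[paste0("upper", cc)]][i]),
                class = "reference_band")
    })
    names(bands) <- confs
    new_continuous_reference(fit, bands, df$measure_kind[i])
  })
  names(refs) <- df$key
  refs
}

measure_kind_of <- function(key) {
  if (grepl("_pct(_|$)", key)) "fraction_percent" else "absolute_count"
}

#' Fit continuous references for a panel of cohort measurements
#'
#' Fits the three-parameter exponential model and builds 0.90/0.95 bands
#' for each requested measurement column of an (already screened) cohort.
#'
#' @param cohort cohort data.frame of included subjects.
#' @param keys measurement column names to fit; the default covers the
#'   five subsets x two measures on the CD19 denominator plus the CD20
#'   total count.
#' @param confidences band confidence probabilities.
#' @return Named list of `continuous_reference` objects.
#' @export
fit_cohort_references <- function(cohort,
                                  keys = c("totalB_pct_cd19", "totalB_abs_cd19",
                                           "totalB_abs_cd20",
                                           "naive_pct_cd19", "naive_abs_cd19",
                                           "nonswitched_pct_cd19",
                                           "nonswitched_abs_cd19",
                                           "switched_pct_cd19",
                                           "switched_abs_cd19",
                                           "memory_pct_cd19",
                                           "memory_abs_cd19"),
                                  confidences = c(0.90, 0.95)) {
  miss <- setdiff(keys, names(cohort))
  if (length(miss))
    stop("fit_cohort_references: cohort lacks column(s): ",
         paste(miss, collapse = ", "))
  age <- cohort_age_years(cohort)
  refs <- lapply(keys, function(key) {
    keep <- !is.na(cohort[[key]])
    parts <- strsplit(key, "_")[[1]]
    fit <- fit_exponential(age[keep], cohort[[key]][keep],
                           subset = parts[1],
                           measure = paste(parts[-1], collapse = "_"))
    build_reference(fit, measure_kind_of(key), confidences)
  })
  names(refs) <- keys
  refs
}

#' Fit table for a set of references
#' @param references named list of `continuous_reference` objects.
#' @return data.frame with one row per fit: key, a, b, c, ssr, n, converged.
#' @export
fit_table <- function(references) {
  do.call(rbind, lapply(names(references), function(key) {
    f <- references[[key]]$fit
    data.frame(key = key, a = f$a, b = f$b, c = f$c, ssr = f$ssr, n = f$n,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}

#' Run the full reference pipeline
#'
#' simulate -> screen -> fit -> reference bands -> in-sample coverage and
#' marker comparison, writing every intermediate table under `out_dir`
#' (cohort, screening report, included subjects, fit table, reference
#' table, dense age-grid limits, coverage, marker summary). Deterministic
#' given `(config, seed)`; each stage logs its row counts via `message()`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory, created if needed.
#' @param seed optional override of `config$seed`.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the cohort, screening report, references
#'   and file paths.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[refcurveB] ", ...)
  paths <- list()

  cohort <- generate_cohort(config, seed = seed)
  paths$cohort <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, paths$cohort)
  log("simulate: ", nrow(cohort), " subjects -> cohort.csv")

  report <- screen_cohort(cohort)
  included <- filter_included(cohort, report)
  paths$screening <- file.path(out_dir, "screening_report.csv")
  write_table_12g(screening_table(report), paths$screening)
  paths$included <- file.path(out_dir, "included.csv")
  write_cohort(included, paths$included)
  log("screen: ", report$n_assessed, " assessed, ", report$n_included,
      " included -> screening_report.csv, included.csv")

  references <- fit_cohort_references(included)
  paths$fits <- file.path(out_dir, "fits.csv")
  write_table_12g(fit_table(references), paths$fits)
  paths$reference <- file.path(out_dir, "reference.csv")
  write_reference(references, paths$reference)
  log("fit: ", length(references),
      " subset/measure models -> fits.csv, reference.csv")

  grid <- do.call(rbind, lapply(names(references), function(key) {
    g <- reference_grid(references[[key]])
    cbind(data.frame(key = key, stringsAsFactors = FALSE), g)
  }))
  paths$grid <- file.path(out_dir, "reference_grid.csv")
  write_table_12g(grid, paths$grid)

  age <- cohort_age_years(included)
  cov <- do.call(rbind, lapply(names(references), function(key) {
    cv <- empirical_coverage(references[[key]], age[!is.na(included[[key]])],
                             included[[key]][!is.na(included[[key]])])
    data.frame(key = key, band = names(cv), within_rate = unname(cv),
               stringsAsFactors = FALSE)
  }))
  paths$coverage <- file.path(out_dir, "coverage.csv")
  write_table_12g(cov, paths$coverage)
  log("coverage: in-sample within-rates -> coverage.csv")

  mk <- compare_markers(included)
  paths$markers <- file.path(out_dir, "marker_comparison.csv")
  write_table_12g(
    data.frame(n = mk$n,
               median_abs_count_diff = mk$median_abs_count_diff,
               min_abs_count_diff = mk$range_abs_count_diff[1],
               max_abs_count_diff = mk$range_abs_count_diff[2],
               coexpression_pct = mk$coexpression_pct,
               median_naive_pct_diff = mk$median_naive_pct_diff,
               median_switched_pct_diff = mk$median_switched_pct_diff),
    paths$markers)
  log("compare: CD19/CD20 summary -> marker_comparison.csv")

  invisible(list(cohort = cohort, screening = report,
                 references = references, markers = mk, paths = paths))
}
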