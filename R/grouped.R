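#' Conventional age-group percentile reference
#'
#' Builds the classical step reference: subjects are binned into age groups
#' (half-open `[low, high)` intervals, the last group closed on the right)
#' and each group is summarized by its n, mean and the 5th, 10th, 50th,
#' 90th and 95th empirical percentiles, using the same interpolated
#' quantile rule as the continuous reference bands.
#'
#' @param age_years subject ages in years.
#' @param values measured responses, same length.
#' @param group_edges ordered group boundaries in years; defaults to the
#'   groups 0-1, 1-2, 2-5, 5-11 and 11-18 years.
#' @param subset,measure optional provenance labels.
#' @return Object of class `grouped_reference`: `group_edges`, `table`
#'   (one row per group), labels.
#' @export
grouped_reference <- function(age_years, values,
                              group_edges = c(0, 1, 2, 5, 11, 18),
                              subset = NA_character_,
                              measure = NA_character_) {
  if (length(age_years) != length(values))
    stop("grouped_reference: 'age_years' and 'values' lengths differ")
  keep <- !is.na(age_years) & !is.na(values)
  age_years <- age_years[keep]
  values <- values[keep]
  if (length(group_edges) < 2L || is.unsorted(group_edges, strictly = TRUE))
    stop("grouped_reference: 'group_edges' must be >= 2 strictly increasing values")
  if (any(age_years < group_edges[1]) ||
      any(age_years > group_edges[length(group_edges)]))
    stop("grouped_reference: ages outside [",
         group_edges[1], ", ", group_edges[length(group_edges)], "] years")
  k <- length(group_edges) - 1L
  idx <- findInterval(age_years, group_edges, rightmost.closed = TRUE)
  labels <- paste0(group_edges[-length(group_edges)], "-", group_edges[-1], "y")
  rows <- lapply(seq_len(k), function(g) {
    v <- values[idx == g]
    if (!length(v))
      stop("grouped_reference: empty age group ", labels[g])
    q <- stats::quantile(v, c(0.05, 0.10, 0.50, 0.90, 0.95),
                         type = 7, names = FALSE)
    data.frame(group = labels[g], age_low = group_edges[g],
               age_high = group_edges[g + 1L], n = length(v), mean = mean(v),
               p5 = q[1], p10 = q[2], p50 = q[3], p90 = q[4], p95 = q[5],
               stringsAsFactors = FALSE)
  })
  structure(list(group_edges = group_edges, table = do.call(rbind, rows),
                 subset = subset, measure = measure),
            class = "grouped_reference")
}

#' Ingest an externally published grouped percentile table
#'
#' Wraps percentile rows published elsewhere (e.g. age-group reference
#' tables from the literature) as a `grouped_reference` without refitting,
#' so they can be overlaid on a continuous reference. The caller must
#' supply the group boundaries explicitly.
#'
#' @param table data.frame with one row per group and columns `n`, `mean`
#'   (optional, may be NA), `p5`, `p10`, `p50`, `p90`, `p95`.
#' @param group_edges ordered boundaries in years, length `nrow(table) + 1`.
#' @param subset,measure provenance labels.
#' @return A `grouped_reference`.
#' @export
as_grouped_reference <- function(table, group_edges,
                                 subset = NA_character_,
                                 measure = NA_character_) {
  if (length(group_edges) != nrow(table) + 1L)
    stop("as_grouped_reference: need length(group_edges) == nrow(table) + 1")
  if (is.unsorted(group_edges, strictly = TRUE))
    stop("as_grouped_reference: 'group_edges' must be strictly increasing")
  pc <- c("p5", "p10", "p50", "p90", "p95")
  miss <- setdiff(pc, names(table))
  if (length(miss))
    stop("as_grouped_reference: missing percentile column(s): ",
         paste(miss, collapse = ", "))
  bad <- apply(table[, pc], 1, is.unsorted)
  if (any(bad))
    stop("as_grouped_reference: percentiles must be non-decreasing in row(s) ",
         paste(which(bad), collapse = ", "))
  tab <- data.frame(group = paste0(group_edges[-length(group_edges)], "-",
                                   group_edges[-1], "y"),
                    age_low = group_edges[-length(group_edges)],
                    age_high = group_edges[-1],
                    n = if ("n" %in% names(table)) table$n else NA_integer_,
                    mean = if ("mean" %in% names(table)) table$mean else NA_real_,
                    table[, pc], stringsAsFactors = FALSE)
  structure(list(group_edges = group_edges, table = tab,
                 subset = subset, measure = measure),
            class = "grouped_reference")
}

#' @export
print.grouped_reference <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$subset, x$measure)), collapse = " / ")
  cat("Age-group percentile reference",
      if (nzchar(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Jumps of a grouped reference at its internal group boundaries
#'
#' The discontinuities a step reference introduces: at each internal
#' boundary, the absolute difference of the chosen statistic between the
#' adjacent groups, in response units. A continuous reference has no such
#' jumps — its largest per-day increment is bounded by the curve's
#' derivative.
#'
#' @param grouped a `grouped_reference`.
#' @param percentile one of 5, 10, 50, 90, 95, or `"mean"`.
#' @return Named numeric vector of jump sizes, one per internal boundary.
#' @export
step_discontinuity <- function(grouped, percentile = 50) {
  stopifnot(inherits(grouped, "grouped_reference"))
  if (nrow(grouped$table) < 2L)
    stop("step_discontinuity: need at least 2 groups")
  col <- if (identical(percentile, "mean")) "mean"
         else if (is.numeric(percentile) &&
                  percentile %in% c(5, 10, 50, 90, 95))
           paste0("p", percentile)
         else stop("step_discontinuity: unknown percentile '", percentile,
                   "' (use 5, 10, 50, 90, 95 or \"mean\")")
  v <- grouped$table[[col]]
  jumps <- abs(diff(v))
  names(jumps) <- paste0(grouped$table$group[-length(v)], "|",
                         grouped$table$group[-1])
  jumps
}

#' Maximum per-day increment of a continuous reference curve
#'
#' Closed-form bound on how much the predicted curve can change in one day:
#' `|b * c| * exp(max(0, c * age_max)) / 365` for the exponential model on
#' `[0, age_max]` (the derivative's envelope at whichever end of the domain
#' maximizes it).
#'
#' @param fit an `exp_fit`.
#' @param age_max upper end of the age domain, years.
#' @return Bound in response units per day.
#' @export
max_daily_increment <- function(fit, age_max = 18) {
  stopifnot(inherits(fit, "exp_fit"))
  abs(fit$b * fit$c) * exp(max(0, fit$c * age_max)) / 365
}

#' Overlay a grouped reference on a continuous one
#'
#' Reproduces the grouped-versus-continuous comparison: on an age grid, the
#' grouped 10th-90th percentile band of each subject's age group is set
#' against the continuous 90% limits, and ages where the grouped band
#' reaches outside the continuous band are flagged. Labels must agree when
#' both objects carry them.
#'
#' @param grouped a `grouped_reference`.
#' @param continuous a `continuous_reference` for the same subset/measure.
#' @param age_years evaluation grid (default: the grouped age span by 0.1 y).
#' @return data.frame with the grid, grouped `p10`/`p50`/`p90`, continuous
#'   `predicted`/`lower90`/`upper90`, and logical `grouped_outside`; the
#'   fraction of flagged grid points is attached as attribute
#'   `"fraction_outside"`.
#' @export
overlay_report <- function(grouped, continuous, age_years = NULL) {
  stopifnot(inherits(grouped, "grouped_reference"),
            inherits(continuous, "continuous_reference"))
  for (f in c("subset", "measure")) {
    a <- grouped[[f]]
    b <- continuous$fit[[f]]
    if (!is.na(a) && !is.na(b) && a != b)
      stop("overlay_report: ", f, " mismatch ('", a, "' vs '", b, "')")
  }
  if (!"90" %in% names(continuous$bands))
    stop("overlay_report: continuous reference lacks a 0.90 band")
  if (is.null(age_years))
    age_years <- seq(grouped$group_edges[1],
                     grouped$group_edges[length(grouped$group_edges)],
                     by = 0.1)
  idx <- findInterval(age_years, grouped$group_edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- NA
  idx[idx > nrow(grouped$table)] <- NA
  g <- reference_grid(continuous, age_years)
  out <- data.frame(age_years = age_years,
                    group = grouped$table$group[idx],
                    grouped_p10 = grouped$table$p10[idx],
                    grouped_p50 = grouped$table$p50[idx],
                    grouped_p90 = grouped$table$p90[idx],
                    predicted = g$predicted,
                    lower90 = g$lower90,
                    upper90 = g$upper90,
                    stringsAsFactors = FALSE)
  out$grouped_outside <- out$grouped_p10 < out$lower90 |
    out$grouped_p90 > out$upper90
  attr(out, "fraction_outside") <- mean(out$grouped_outside, na.rm = TRUE)
  out
}
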