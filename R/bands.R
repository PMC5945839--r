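#' Distribution-free reference-band offsets from fit residuals
#'
#' The offsets are the empirical `(1 - confidence)/2` and
#' `1 - (1 - confidence)/2` quantiles of the residuals (observed minus
#' predicted), computed with linear interpolation between order statistics
#' (R quantile type 7). No distributional assumption is made; added to the
#' predicted curve they form a reference band expected to contain the
#' stated fraction of healthy values.
#'
#' @param residuals numeric vector of fit residuals; a warning is issued
#'   below 20 values, where empirical tail quantiles are poorly determined.
#' @param confidence confidence probability in (0, 1\]; `1` gives the
#'   residual range (min, max).
#' @return Object of class `reference_band` with `confidence`,
#'   `lower_offset`, `upper_offset`.
#' @examples
#' residual_quantile_offsets(-10:10, 0.90)   # offsets (-9, 9)
#' @export
residual_quantile_offsets <- function(residuals, confidence) {
  if (!length(residuals) || anyNA(residuals))
    stop("residual_quantile_offsets: residuals must be non-empty and complete")
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence > 1)
    stop("residual_quantile_offsets: 'confidence' must be in (0, 1]")
  if (length(residuals) < 20L)
    warning("residual_quantile_offsets: fewer than 20 residuals; ",
            "tail quantiles are poorly determined")
  alpha <- 1 - confidence
  q <- stats::quantile(residuals, c(alpha / 2, 1 - alpha / 2),
                       type = 7, names = FALSE)
  structure(list(confidence = confidence,
                 lower_offset = q[1], upper_offset = q[2]),
            class = "reference_band")
}

new_continuous_reference <- function(fit, bands, measure_kind) {
  clamp_high <- if (measure_kind == "fraction_percent") 100 else Inf
  structure(list(fit = fit, bands = bands, measure_kind = measure_kind,
                 clamp_low = 0, clamp_high = clamp_high),
            class = "continuous_reference")
}

#' Build a continuous age-matched reference
#'
#' Combines a converged exponential fit with residual-quantile bands at the
#' requested confidence probabilities (0.90 and 0.95 by default). Band
#' offsets are age-constant and added to the predicted curve; limits are
#' then clamped to the biologically possible range (fractions to
#' \[0, 100\], counts to \[0, Inf)).
#'
#' @param fit a converged [fit_exponential()] object with residuals.
#' @param measure_kind `"fraction_percent"` or `"absolute_count"`.
#' @param confidences confidence probabilities, each in (0, 1\].
#' @return Object of class `continuous_reference`.
#' @export
build_reference <- function(fit,
                            measure_kind = c("fraction_percent",
                                             "absolute_count"),
                            confidences = c(0.90, 0.95)) {
  stopifnot(inherits(fit, "exp_fit"))
  measure_kind <- match.arg(measure_kind)
  if (!isTRUE(fit$converged))
    stop("build_reference: fit did not converge; refusing to build reference ",
         "bands from an unconverged model")
  if (is.null(fit$residuals) || !length(fit$residuals))
    stop("build_reference: fit carries no residuals")
  if (!length(confidences))
    stop("build_reference: at least one confidence required")
  confidences <- sort(confidences)
  bands <- lapply(confidences, function(p)
    residual_quantile_offsets(fit$residuals, p))
  names(bands) <- format_confidence(confidences)
  new_continuous_reference(fit, bands, measure_kind)
}

# band column suffix: 0.90 -> "90", 0.95 -> "95", 0.999 -> "99.9"
format_confidence <- function(p) sprintf("%g", p * 100)

#' @export
print.continuous_reference <- function(x, digits = 4, ...) {
  cat("Continuous age-matched reference (", x$measure_kind, ")\n", sep = "")
  print(x$fit, digits = digits)
  for (b in x$bands)
    cat(sprintf("  %g band offsets: [%.*g, %.*g]\n",
                b$confidence, digits, b$lower_offset, digits, b$upper_offset))
  invisible(x)
}

#' Reference limits on an age grid
#'
#' Evaluates the predicted curve and the clamped lower/upper limits of every
#' band at the given ages — the machine-readable equivalent of a reference
#' chart, suitable for plotting or laboratory-information-system ingestion.
#'
#' @param reference a `continuous_reference`.
#' @param age_years ages in years (default: 0 to 18 by 0.1).
#' @return data.frame with `age_years`, `predicted`, and `lower<cc>` /
#'   `upper<cc>` columns per confidence (e.g. `lower90`, `upper95`).
#' @export
reference_grid <- function(reference, age_years = seq(0, 18, by = 0.1)) {
  stopifnot(inherits(reference, "continuous_reference"))
  pred <- predict(reference$fit, age_years)
  out <- data.frame(
    age_years = age_years,
    predicted = pmin(pmax(pred, reference$clamp_low), reference$clamp_high))
  for (nm in names(reference$bands)) {
    b <- reference$bands[[nm]]
    out[[paste0("lower", nm)]] <-
      pmin(pmax(pred + b$lower_offset, reference$clamp_low),
           reference$clamp_high)
    out[[paste0("upper", nm)]] <-
      pmin(pmax(pred + b$upper_offset, reference$clamp_low),
           reference$clamp_high)
  }
  out
}

#' Empirical coverage of reference bands on a test set
#'
#' For each band, the fraction of test values lying inside the clamped
#' closed interval `[predicted + lower_offset, predicted + upper_offset]`
#' evaluated at each subject's own age. On a test set drawn independently
#' of the fitting cohort this estimates the band's true coverage, which the
#' construction aims to hold at the nominal confidence probability.
#'
#' @param reference a `continuous_reference`.
#' @param age_years,values test subjects' ages and observed values.
#' @return Named numeric vector of coverage fractions, one per band.
#' @export
empirical_coverage <- function(reference, age_years, values) {
  stopifnot(inherits(reference, "continuous_reference"))
  if (!length(values))
    stop("empirical_coverage: empty test set")
  if (length(age_years) != length(values))
    stop("empirical_coverage: 'age_years' and 'values' lengths differ")
  grid <- reference_grid(reference, age_years)
  out <- vapply(names(reference$bands), function(nm) {
    mean(values >= grid[[paste0("lower", nm)]] &
         values <= grid[[paste0("upper", nm)]])
  }, numeric(1))
  names(out) <- vapply(reference$bands, function(b)
    formatC(b$confidence, format = "g"), character(1))
  out
}
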