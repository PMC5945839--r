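# Exact least-squares solve of the linear subproblem: for fixed rate c the
# model a + b*exp(c*x) is linear in (a, b). Returns the conditional optimum
# and its SSR; collapses to the intercept-only fit when exp(c*x) is
# numerically constant over the observed ages.
profile_solve <- function(age, y, c) {
  e <- exp(c * age)
  me <- mean(e)
  my <- mean(y)
  vee <- sum((e - me)^2)
  # only exact or underflowed degeneracy (e.g. c = 0) falls back to the
  # intercept fit; a tiny but non-zero spread still identifies (a, b)
  if (!is.finite(vee) || vee < 1e-300) {
    r <- y - my
    return(list(a = my, b = 0, ssr = sum(r^2)))
  }
  b <- sum((e - me) * (y - my)) / vee
  a <- my - b * me
  r <- y - a - b * e
  list(a = a, b = b, ssr = sum(r^2))
}

#' Fit the three-parameter exponential reference model
#'
#' Fits `y = a + b * exp(c * age)` by minimizing the sum of squared
#' residuals. The fit is profiled: for any fixed rate `c` the model is
#' linear in `(a, b)` and solved exactly, so only `c` is searched — first on
#' a grid over `c_range`, then by repeated 1-D local refinement around the
#' grid optimum until the profiled SSR improves by less than a relative
#' 1e-10. Ties on the grid are broken toward smaller `|c|` (the smoother
#' curve). This is deterministic and immune to poor 3-D starting values.
#'
#' @param age_years vector of non-negative ages in years.
#' @param response vector of responses (% or cells/ul), same length; at
#'   least 4 points with at least 3 distinct ages, no missing values.
#' @param subset,measure optional provenance labels carried into outputs.
#' @param c_range search bracket for the rate, per year. Rates beyond
#'   +/- 8 / year are indistinguishable from step functions on a 0-18 y
#'   age domain.
#' @param grid_n number of grid points over `c_range`.
#' @return Object of class `exp_fit` with elements `a`, `b`, `c`,
#'   `fitted`, `residuals` (observed - predicted), `ssr`, `n`, `converged`,
#'   `subset`, `measure`, `age_range`.
#' @examples
#' age <- c(0, 0.5, 1, 2, 4, 8, 16)
#' y <- 10 + 88 * exp(-0.5 * age)
#' fit_exponential(age, y)
#' @export
fit_exponential <- function(age_years, response, subset = NA_character_,
                            measure = NA_character_, c_range = c(-8, 8),
                            grid_n = 321L) {
  if (length(age_years) != length(response))
    stop("fit_exponential: 'age_years' and 'response' lengths differ")
  if (anyNA(age_years) || anyNA(response) ||
      !all(is.finite(age_years)) || !all(is.finite(response)))
    stop("fit_exponential: missing or non-finite values")
  if (any(age_years < 0))
    stop("fit_exponential: ages must be non-negative")
  n <- length(response)
  if (n < 4L || length(unique(age_years)) < 3L)
    stop("fit_exponential: insufficient data (need >= 4 points, >= 3 distinct ages)")

  new_fit <- function(a, b, c, converged) {
    fitted <- a + b * exp(c * age_years)
    res <- response - fitted
    structure(list(a = a, b = b, c = c, fitted = fitted, residuals = res,
                   ssr = sum(res^2), n = n, converged = converged,
                   subset = subset, measure = measure, age_range = c(0, 18)),
              class = "exp_fit")
  }

  if (stats::var(response) == 0)                       # degenerate constant
    return(new_fit(response[1], 0, 0, TRUE))

  c_grid <- seq(c_range[1], c_range[2], length.out = grid_n)
  pssr <- function(cc) profile_solve(age_years, response, cc)$ssr
  ssr_grid <- vapply(c_grid, pssr, numeric(1))

  # the profiled SSR can have several shallow basins (very negative rates
  # mimic step functions); refine every local grid minimum, not just the
  # global one, then keep the best refined candidate
  is_local_min <- ssr_grid <= c(Inf, ssr_grid[-grid_n]) &
    ssr_grid <= c(ssr_grid[-1], Inf)
  cand_c <- numeric(0)
  cand_ssr <- numeric(0)
  for (i in which(is_local_min)) {
    opt <- stats::optimize(pssr, c(c_grid[max(i - 1L, 1L)],
                                   c_grid[min(i + 1L, grid_n)]), tol = 1e-12)
    take <- if (opt$objective <= ssr_grid[i]) {
      c(opt$minimum, opt$objective)
    } else c(c_grid[i], ssr_grid[i])
    cand_c <- c(cand_c, take[1])
    cand_ssr <- c(cand_ssr, take[2])
  }
  best <- min(cand_ssr)
  tied <- which(cand_ssr <= best * (1 + 1e-9))
  j <- tied[which.min(abs(cand_c[tied]))]              # tie -> smaller |c|
  c_best <- cand_c[j]
  ssr_best <- cand_ssr[j]

  # local re-refinement until the profiled SSR stops improving
  converged <- FALSE
  w <- (c_range[2] - c_range[1]) / (grid_n - 1)
  for (k in 1:6) {
    opt <- stats::optimize(pssr, c(max(c_best - w, c_range[1]),
                                   min(c_best + w, c_range[2])), tol = 1e-12)
    improve <- (ssr_best - opt$objective) / max(ssr_best, 1e-300)
    if (opt$objective <= ssr_best) {
      c_best <- opt$minimum
      ssr_best <- opt$objective
    }
    if (improve < 1e-10) { converged <- TRUE; break }
    w <- w / 4
  }
  sol <- profile_solve(age_years, response, c_best)
  if (sol$b == 0) c_best <- 0                          # flat profile: report smooth form
  new_fit(sol$a, sol$b, c_best, converged)
}

#' @export
print.exp_fit <- function(x, digits = 4, ...) {
  lab <- paste(stats::na.omit(c(x$subset, x$measure)), collapse = " / ")
  cat("Three-parameter exponential fit",
      if (nzchar(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  cat(sprintf("  y = %.*g + %.*g * exp(%.*g * age)\n",
              digits, x$a, digits, x$b, digits, x$c))
  cat(sprintf("  n = %d, SSR = %.*g, converged: %s\n",
              x$n, digits, x$ssr, x$converged))
  invisible(x)
}

#' Predict from a fitted exponential model
#'
#' @param object an `exp_fit`.
#' @param age_years ages in years; must lie in the supported domain
#'   (0-18 years) unless `extrapolate = TRUE`.
#' @param extrapolate allow ages outside the supported domain.
#' @param ... ignored.
#' @return Predicted responses, one per age.
#' @export
predict.exp_fit <- function(object, age_years, extrapolate = FALSE, ...) {
  if (!is.numeric(age_years) || anyNA(age_years))
    stop("predict.exp_fit: 'age_years' must be numeric and complete")
  if (!extrapolate &&
      (any(age_years < object$age_range[1]) ||
       any(age_years > object$age_range[2])))
    stop("predict.exp_fit: age outside the supported range [",
         object$age_range[1], ", ", object$age_range[2],
         "] years (set extrapolate = TRUE to override)")
  object$a + object$b * exp(object$c * age_years)
}

#' @export
residuals.exp_fit <- function(object, ...) object$residuals
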