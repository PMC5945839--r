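#' Specify an age trajectory for a simulated B cell measure
#'
#' A trajectory describes the expected value of one measurement (a subset
#' frequency in % of B cells, or an absolute count in cells/ul) as a function
#' of age, plus the noise process around it. The `exponential` kind is the
#' monotone three-parameter curve `a + b * exp(c * age)`; the `biexponential`
#' kind adds a second component `b2 * exp(c2 * age)` and can produce the
#' peaked absolute-count trajectories seen for memory subsets in early
#' childhood. Only the generator uses trajectories; the fitted model is
#' always the three-parameter exponential.
#'
#' @param kind `"exponential"` or `"biexponential"`.
#' @param a asymptote, in response units (% or cells/ul).
#' @param b amplitude, in response units; `a + b` is the value at age 0
#'   (plus `b2` for the biexponential).
#' @param c rate per year; negative values decay toward the asymptote.
#' @param b2,c2 second-component amplitude and rate (biexponential only).
#' @param unit `"percent"` (responses clamped to \[0, 100\]) or `"count"`
#'   (clamped to \[0, Inf)).
#' @param noise_kind `"skewed"` (shifted, rescaled gamma; mean 0) or
#'   `"gaussian"`.
#' @param noise_scale baseline noise standard deviation, response units.
#' @param noise_skew skewness of the skewed noise (sign gives the direction
#'   of the long tail); ignored for gaussian noise.
#' @param noise_prop proportional noise component: the noise sd at age t is
#'   `noise_scale + noise_prop * |mu(t)|`, giving heteroscedastic spread.
#' @return An object of class `trajectory_spec`.
#' @examples
#' tr <- trajectory_spec("exponential", a = 10, b = 88, c = -0.5)
#' evaluate_trajectory(tr, c(0, 2, 18))
#' @export
trajectory_spec <- function(kind = c("exponential", "biexponential"),
                            a, b, c, b2 = NA_real_, c2 = NA_real_,
                            unit = c("percent", "count"),
                            noise_kind = c("skewed", "gaussian"),
                            noise_scale = 0, noise_skew = 1,
                            noise_prop = 0) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  noise_kind <- match.arg(noise_kind)
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("trajectory_spec: '", nm, "' must be a single finite number")
  }
  if (kind == "exponential") {
    if (!is.na(b2) || !is.na(c2))
      stop("trajectory_spec: 'b2'/'c2' must be unset for kind = 'exponential'")
  } else {
    if (is.na(b2) || is.na(c2))
      stop("trajectory_spec: kind = 'biexponential' requires 'b2' and 'c2'")
  }
  if (noise_scale < 0) stop("trajectory_spec: 'noise_scale' must be >= 0")
  if (noise_prop < 0) stop("trajectory_spec: 'noise_prop' must be >= 0")
  if (noise_kind == "skewed" && noise_skew == 0)
    stop("trajectory_spec: 'noise_skew' must be non-zero for skewed noise")
  structure(
    list(kind = kind, a = a, b = b, c = c, b2 = b2, c2 = c2, unit = unit,
         noise_kind = noise_kind, noise_scale = noise_scale,
         noise_skew = noise_skew, noise_prop = noise_prop),
    class = "trajectory_spec"
  )
}

clamp_unit <- function(x, unit) {
  if (unit == "percent") pmin(pmax(x, 0), 100) else pmax(x, 0)
}

trajectory_mean <- function(spec, age_years) {
  mu <- spec$a + spec$b * exp(spec$c * age_years)
  if (spec$kind == "biexponential")
    mu <- mu + spec$b2 * exp(spec$c2 * age_years)
  mu
}

#' Evaluate a trajectory's expected value at given ages
#'
#' Returns `a + b*exp(c*age)` (plus the second component for biexponential
#' specs), clamped to the trajectory's unit range.
#'
#' @param spec a [trajectory_spec()].
#' @param age_years vector of non-negative ages in years.
#' @return Numeric vector of expected responses, one per age.
#' @export
evaluate_trajectory <- function(spec, age_years) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (!is.numeric(age_years) || anyNA(age_years) || any(age_years < 0))
    stop("evaluate_trajectory: 'age_years' must be non-negative")
  clamp_unit(trajectory_mean(spec, age_years), spec$unit)
}

# Mean-zero noise draw; skewed noise is a shifted gamma standardised to unit
# sd, so its support is bounded on the short-tail side at 2/|skew| sds.
draw_noise <- function(n, sd, kind, skew) {
  if (n == 0L) return(numeric(0))
  if (kind == "gaussian") return(stats::rnorm(n, 0, sd))
  shape <- (2 / abs(skew))^2
  z <- (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape)
  if (skew < 0) z <- -z
  sd * z
}

#' Simulate noisy measurements along a trajectory
#'
#' Draws one observation per age: the trajectory mean plus mean-zero noise
#' (gaussian or skewed, optionally heteroscedastic), clamped to the unit
#' range after the noise is added so the result matches what a laboratory
#' could observe.
#'
#' @inheritParams evaluate_trajectory
#' @return Numeric vector of simulated responses.
#' @export
simulate_measure <- function(spec, age_years) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (!is.numeric(age_years) || anyNA(age_years) || any(age_years < 0))
    stop("simulate_measure: 'age_years' must be non-negative")
  mu <- trajectory_mean(spec, age_years)
  sd <- spec$noise_scale + spec$noise_prop * abs(mu)
  clamp_unit(mu + draw_noise(length(mu), sd, spec$noise_kind, spec$noise_skew),
             spec$unit)
}

#' Sample subject ages
#'
#' @param n number of subjects.
#' @param age_min_days,age_max_days age bounds in days.
#' @param distribution `"log_uniform"` (over-represents infancy, as pediatric
#'   enrollment typically does) or `"uniform"`.
#' @return Integer vector of ages in days.
#' @export
sample_ages <- function(n, age_min_days = 2L, age_max_days = 6570L,
                        distribution = c("log_uniform", "uniform")) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 0, age_min_days >= 0, age_min_days < age_max_days)
  d <- if (distribution == "uniform") {
    stats::runif(n, age_min_days, age_max_days)
  } else {
    exp(stats::runif(n, log(pmax(age_min_days, 1)), log(age_max_days)))
  }
  pmin(pmax(as.integer(round(d)), age_min_days), age_max_days)
}
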