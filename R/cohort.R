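#' Default generative trajectories for the synthetic pediatric cohort
#'
#' One [trajectory_spec()] per generated measurement column. The curves
#' emulate the developmental pattern of B cell subpopulations in childhood:
#' at birth essentially all B cells are naive (~98% of CD19+ B cells, total
#' count ~1800 cells/ul), the naive fraction declines over the first decade,
#' memory fractions rise over the first five years and then plateau, and
#' absolute memory counts peak around age 2 as the product of a falling
#' total count and a rising memory fraction. Noise is skewed and, for
#' counts and memory fractions, heteroscedastic.
#'
#' Subset absolute counts are not given trajectories of their own: they are
#' derived as `total count x fraction / 100` so each record is internally
#' consistent.
#'
#' @return Named list of `trajectory_spec` objects; names are measurement
#'   column names (`<subset>_<measure>_<denominator>`).
#' @export
default_trajectories <- function() {
  list(
    totalB_pct_cd19 = trajectory_spec("exponential", a = 10, b = 10, c = -0.25,
                                      unit = "percent", noise_kind = "skewed",
                                      noise_scale = 2, noise_skew = 1,
                                      noise_prop = 0.08),
    totalB_abs_cd19 = trajectory_spec("exponential", a = 250, b = 1550, c = -0.5,
                                      unit = "count", noise_kind = "skewed",
                                      noise_scale = 120, noise_skew = 1,
                                      noise_prop = 0.15),
    naive_pct_cd19 = trajectory_spec("exponential", a = 77, b = 21, c = -0.45,
                                     unit = "percent", noise_kind = "skewed",
                                     noise_scale = 3.5, noise_skew = -1),
    nonswitched_pct_cd19 = trajectory_spec("exponential", a = 7, b = -6.8, c = -0.6,
                                           unit = "percent", noise_kind = "skewed",
                                           noise_scale = 0.3, noise_skew = 1,
                                           noise_prop = 0.25),
    switched_pct_cd19 = trajectory_spec("exponential", a = 8, b = -7.8, c = -0.6,
                                        unit = "percent", noise_kind = "skewed",
                                        noise_scale = 0.3, noise_skew = 1,
                                        noise_prop = 0.25)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the reference study population: 184 children aged 2 days
#' to 18 years, log-uniform age sampling (over-representing infancy),
#' screening-failure rates matching the published exclusion accounting
#' (16 abnormal counts/CRP, 21 missing labs, 6 insufficient material out of
#' 227 assessed), ~99% CD20 co-expression among CD19+ B cells, and fixed
#' +2/-2 percentage-point shifts for the naive/switched fractions when CD20
#' is used as the denominator marker.
#'
#' @param n_subjects number of subjects to generate.
#' @param age_min_days,age_max_days age range in days (defaults 2 and
#'   6570 = 18 years).
#' @param age_distribution `"log_uniform"` or `"uniform"`.
#' @param seed integer seed; identical `(config, seed)` yields an identical
#'   cohort.
#' @param trajectories named list of [trajectory_spec()] objects, see
#'   [default_trajectories()].
#' @param cd20_coexpression_rate expected fraction of CD19+ B cells that
#'   co-express CD20, in \[0, 1\].
#' @param cd20_concentration concentration of the per-subject beta draw of
#'   the co-expression ratio; larger is tighter. `Inf` (or a rate of 1)
#'   makes CD20 counts exactly proportional (identical when rate = 1).
#' @param marker_shift_naive,marker_shift_switched percentage-point offsets
#'   added to the CD19-denominated naive/switched fractions to form their
#'   CD20-denominated counterparts.
#' @param screening_fail_rates named probabilities for the exclusion reasons
#'   `abnormal`, `missing_labs`, `insufficient_material`; the remainder is
#'   the inclusion probability.
#' @param p_female probability a subject is female (study ratio 64:110).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 184L,
                          age_min_days = 2L,
                          age_max_days = 6570L,
                          age_distribution = c("log_uniform", "uniform"),
                          seed = 1L,
                          trajectories = default_trajectories(),
                          cd20_coexpression_rate = 0.99,
                          cd20_concentration = 300,
                          marker_shift_naive = 2,
                          marker_shift_switched = -2,
                          screening_fail_rates = c(
                            abnormal = 16 / 227,
                            missing_labs = 21 / 227,
                            insufficient_material = 6 / 227),
                          p_female = 64 / 174) {
  age_distribution <- match.arg(age_distribution)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("cohort_config: 'n_subjects' must be a positive integer")
  if (age_min_days < 0 || age_min_days >= age_max_days)
    stop("cohort_config: need 0 <= age_min_days < age_max_days")
  if (cd20_coexpression_rate < 0 || cd20_coexpression_rate > 1)
    stop("cohort_config: 'cd20_coexpression_rate' must be in [0, 1]")
  need <- c("abnormal", "missing_labs", "insufficient_material")
  if (!all(need %in% names(screening_fail_rates)))
    stop("cohort_config: 'screening_fail_rates' must name ",
         paste(need, collapse = ", "))
  screening_fail_rates <- screening_fail_rates[need]
  if (any(screening_fail_rates < 0) || sum(screening_fail_rates) > 1)
    stop("cohort_config: 'screening_fail_rates' must be probabilities summing to <= 1")
  if (p_female < 0 || p_female > 1)
    stop("cohort_config: 'p_female' must be in [0, 1]")
  core <- c("totalB_pct_cd19", "totalB_abs_cd19", "naive_pct_cd19",
            "nonswitched_pct_cd19", "switched_pct_cd19")
  if (!all(core %in% names(trajectories)))
    stop("cohort_config: 'trajectories' must include ",
         paste(setdiff(core, names(trajectories)), collapse = ", "))
  ok <- vapply(trajectories, inherits, logical(1), what = "trajectory_spec")
  if (!all(ok))
    stop("cohort_config: 'trajectories' entries must be trajectory_spec objects: ",
         paste(names(trajectories)[!ok], collapse = ", "))
  structure(
    list(n_subjects = as.integer(n_subjects),
         age_min_days = as.integer(age_min_days),
         age_max_days = as.integer(age_max_days),
         age_distribution = age_distribution,
         seed = as.integer(seed),
         trajectories = trajectories,
         cd20_coexpression_rate = cd20_coexpression_rate,
         cd20_concentration = cd20_concentration,
         marker_shift_naive = marker_shift_naive,
         marker_shift_switched = marker_shift_switched,
         screening_fail_rates = screening_fail_rates,
         p_female = p_female),
    class = "cohort_config")
}

#' Generate a synthetic pediatric cohort
#'
#' Produces one row per subject with screening flags and the full subset
#' panel. Internal consistency is enforced: subset absolute counts equal
#' `total B count x fraction / 100`, `memory = non-switched + switched`,
#' and naive + memory fractions never exceed 100 (the memory fractions are
#' rescaled in the rare draws where noise would push the sum over).
#' Subjects flagged `material_insufficient` carry no panel (NA columns),
#' as no flow cytometry could have been run for them.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return A `data.frame` (class `cohort`) with identifier, age, sex,
#'   screening flags, lymphocyte count and measurement columns.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_subjects
  tr <- config$trajectories

  age_days <- sample_ages(n, config$age_min_days, config$age_max_days,
                          config$age_distribution)
  age_years <- age_days / 365
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")

  p <- config$screening_fail_rates
  category <- sample(c("abnormal", "missing_labs", "insufficient_material",
                       "included"),
                     n, replace = TRUE,
                     prob = c(p, included = 1 - sum(p)))

  totalB_pct <- simulate_measure(tr$totalB_pct_cd19, age_years)
  totalB_abs <- simulate_measure(tr$totalB_abs_cd19, age_years)
  naive_pct <- simulate_measure(tr$naive_pct_cd19, age_years)
  ns_pct <- simulate_measure(tr$nonswitched_pct_cd19, age_years)
  sw_pct <- simulate_measure(tr$switched_pct_cd19, age_years)

  # keep naive + non-switched + switched <= 100: shrink the memory parts,
  # which are tiny whenever the naive fraction is near its ceiling
  mem <- ns_pct + sw_pct
  over <- naive_pct + mem > 100 & mem > 0
  if (any(over)) {
    f <- (100 - naive_pct[over]) / mem[over]
    ns_pct[over] <- ns_pct[over] * f
    sw_pct[over] <- sw_pct[over] * f
  }
  memory_pct <- ns_pct + sw_pct

  # CD20 co-expression: per-subject beta ratio around the configured rate
  rate <- config$cd20_coexpression_rate
  conc <- config$cd20_concentration
  ratio <- if (rate >= 1 || rate <= 0 || !is.finite(conc)) {
    rep(rate, n)
  } else {
    stats::rbeta(n, rate * conc, (1 - rate) * conc)
  }
  totalB_abs_cd20 <- totalB_abs * ratio
  naive_pct_cd20 <- pmin(pmax(naive_pct + config$marker_shift_naive, 0), 100)
  switched_pct_cd20 <- pmin(pmax(sw_pct + config$marker_shift_switched, 0), 100)

  lymph <- totalB_abs / (pmax(totalB_pct, 0.1) / 100)

  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age_days = age_days,
    sex = sex,
    crp_positive_or_abnormal_counts = category == "abnormal",
    labs_missing = category == "missing_labs",
    material_insufficient = category == "insufficient_material",
    lymphocytes_abs = lymph,
    totalB_pct_cd19 = totalB_pct,
    totalB_abs_cd19 = totalB_abs,
    totalB_abs_cd20 = totalB_abs_cd20,
    naive_pct_cd19 = naive_pct,
    naive_abs_cd19 = totalB_abs * naive_pct / 100,
    nonswitched_pct_cd19 = ns_pct,
    nonswitched_abs_cd19 = totalB_abs * ns_pct / 100,
    switched_pct_cd19 = sw_pct,
    switched_abs_cd19 = totalB_abs * sw_pct / 100,
    memory_pct_cd19 = memory_pct,
    memory_abs_cd19 = totalB_abs * memory_pct / 100,
    naive_pct_cd20 = naive_pct_cd20,
    switched_pct_cd20 = switched_pct_cd20,
    stringsAsFactors = FALSE
  )
  meas <- setdiff(names(cohort),
                  c("subject_id", "age_days", "sex",
                    "crp_positive_or_abnormal_counts", "labs_missing",
                    "material_insufficient"))
  cohort[cohort$material_insufficient, meas] <- NA_real_
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Ages of a cohort in years
#' @param cohort a cohort data.frame with an `age_days` column.
#' @return Numeric vector, `age_days / 365`.
#' @export
cohort_age_years <- function(cohort) cohort$age_days / 365

#' Dual-platform absolute count
#'
#' Combines a hematology-analyzer lymphocyte count with a flow-cytometric
#' fraction: `lymphocytes_abs * pct / 100`.
#'
#' @param lymphocytes_abs lymphocyte count, cells/ul.
#' @param pct subset fraction, % of lymphocytes.
#' @return Absolute count, cells/ul.
#' @export
absolute_from_dual_platform <- function(lymphocytes_abs, pct) {
  stopifnot(length(lymphocytes_abs) == length(pct))
  lymphocytes_abs * pct / 100
}
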