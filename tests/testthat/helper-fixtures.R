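# Shared fixtures and independent oracles, built in code at test time.

# Brute-force profiled-grid oracle for the exponential fit: for each rate on
# the grid solve the linear subproblem with lm() (a route independent of the
# package's closed-form solver) and return the smallest SSR found.
oracle_grid_ssr <- function(age, y, c_grid = seq(-8, 8, length.out = 200)) {
  min(vapply(c_grid, function(cc) {
    e <- exp(cc * age)
    if (stats::sd(e) < 1e-12) return(sum(stats::resid(stats::lm(y ~ 1))^2))
    sum(stats::resid(stats::lm(y ~ e))^2)
  }, numeric(1)))
}

# Screening manifest with the given category sizes; flags only, no panel.
make_manifest <- function(n_abnormal = 0, n_missing = 0, n_insufficient = 0,
                          n_clean = 0) {
  n <- n_abnormal + n_missing + n_insufficient + n_clean
  data.frame(
    subject_id = sprintf("M%03d", seq_len(n)),
    age_days = rep(1000L, n),
    sex = rep("female", n),
    crp_positive_or_abnormal_counts =
      rep(c(TRUE, FALSE), c(n_abnormal, n - n_abnormal)),
    labs_missing = rep(c(FALSE, TRUE, FALSE),
                       c(n_abnormal, n_missing, n - n_abnormal - n_missing)),
    material_insufficient =
      rep(c(FALSE, TRUE, FALSE),
          c(n_abnormal + n_missing, n_insufficient, n_clean)),
    stringsAsFactors = FALSE)
}

# Trajectory used throughout the band/coverage checks; a count-type measure
# so neither clamp can truncate the noise distribution the oracles assume.
band_trajectory <- function(noise_kind = "skewed", noise_scale = 4,
                            noise_skew = 1) {
  trajectory_spec("exponential", a = 10, b = 88, c = -0.5, unit = "count",
                  noise_kind = noise_kind, noise_scale = noise_scale,
                  noise_skew = noise_skew)
}

# Cohort config with all noise switched off (values fall on the curves).
zero_noise_config <- function(n = 50, seed = 3) {
  tr <- default_trajectories()
  tr <- lapply(tr, function(s) { s$noise_scale <- 0; s$noise_prop <- 0; s })
  class(tr) <- NULL
  tr <- lapply(tr, function(s) structure(s, class = "trajectory_spec"))
  cohort_config(n_subjects = n, seed = seed, trajectories = tr,
                cd20_coexpression_rate = 1,
                marker_shift_naive = 0, marker_shift_switched = 0,
                screening_fail_rates = c(abnormal = 0, missing_labs = 0,
                                         insufficient_material = 0))
}
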