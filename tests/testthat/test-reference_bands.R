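test_that("residual quantile offsets follow the interpolated order statistics", {
  z <- rep(0, 25)
  b0 <- residual_quantile_offsets(z, 0.9)
  expect_equal(c(b0$lower_offset, b0$upper_offset), c(0, 0))

  r <- c(-3.2, 0.5, 1.1, -7, 2.2, 9, 0, -1, 4, 6, -2, 3,
         1, 2, -4, 5, -6, 7, -8, 8.5)
  b1 <- residual_quantile_offsets(r, 1.0)
  expect_equal(c(b1$lower_offset, b1$upper_offset), range(r))

  b2 <- residual_quantile_offsets(-10:10, 0.90)
  expect_equal(c(b2$lower_offset, b2$upper_offset), c(-9, 9))

  expect_error(residual_quantile_offsets(numeric(0), 0.9), "non-empty")
  expect_error(residual_quantile_offsets(1:30, 0), "confidence")
  expect_error(residual_quantile_offsets(1:30, 1.01), "confidence")
  expect_warning(residual_quantile_offsets(1:10, 0.9), "fewer than 20")
})

test_that("references from zero-spread residuals collapse onto the curve", {
  age <- c(0, 0.5, 1, 2, 4, 8, 16)
  fit <- fit_exponential(age, 10 + 88 * exp(-0.5 * age))
  ref <- suppressWarnings(build_reference(fit, "fraction_percent"))
  g <- reference_grid(ref, seq(0, 18, by = 0.5))
  expect_equal(g$lower90, g$predicted, tolerance = 1e-6)
  expect_equal(g$upper95, g$predicted, tolerance = 1e-6)
})

test_that("non-converged fits are refused", {
  fit <- structure(list(a = 1, b = 1, c = -1, residuals = rnorm(30),
                        converged = FALSE, n = 30, age_range = c(0, 18)),
                   class = "exp_fit")
  expect_error(build_reference(fit, "fraction_percent"), "converge")
})

test_that("bands nest, have age-constant width, and clamp to valid ranges", {
  set.seed(11)
  for (i in 1:10) {
    age <- sort(runif(60, 0, 18))
    y <- 10 + 88 * exp(-0.5 * age) + rnorm(60, 0, 5)
    ref <- build_reference(fit_exponential(age, y), "absolute_count")
    g <- reference_grid(ref, seq(0, 18, by = 0.1))
    expect_true(all(g$lower95 <= g$lower90 + 1e-12))
    expect_true(all(g$lower90 <= g$predicted + 1e-12))
    expect_true(all(g$predicted <= g$upper90 + 1e-12))
    expect_true(all(g$upper90 <= g$upper95 + 1e-12))
    # width before clamping is age-constant by construction
    b <- ref$bands[["90"]]
    expect_lt(b$lower_offset, b$upper_offset)
    pred <- predict(ref$fit, g$age_years)
    expect_equal((pred + b$upper_offset) - (pred + b$lower_offset),
                 rep(b$upper_offset - b$lower_offset, nrow(g)))
  }

  # count reference floors at zero under heavy skewed noise
  set.seed(12)
  tr <- trajectory_spec("exponential", a = 20, b = 150, c = -0.8,
                        unit = "count", noise_kind = "skewed",
                        noise_scale = 30, noise_skew = 1)
  age <- sample_ages(500) / 365
  ref <- build_reference(fit_exponential(age, simulate_measure(tr, age)),
                         "absolute_count")
  g <- reference_grid(ref)
  expect_true(all(g$lower90 >= 0) && all(g$lower95 >= 0))

  # fraction reference never exceeds 100 after clamping
  trp <- trajectory_spec("exponential", a = 77, b = 21, c = -0.45,
                         unit = "percent", noise_kind = "gaussian",
                         noise_scale = 6)
  ref2 <- build_reference(fit_exponential(age, simulate_measure(trp, age)),
                          "fraction_percent")
  g2 <- reference_grid(ref2)
  expect_true(all(g2$upper95 <= 100))
})

test_that("in-sample containment matches the quantile construction", {
  set.seed(23)
  age <- sample_ages(400) / 365
  y <- simulate_measure(band_trajectory(), age)
  fit <- fit_exponential(age, y)
  ref <- build_reference(fit, "fraction_percent")
  b <- ref$bands[["90"]]
  inside <- mean(fit$residuals >= b$lower_offset &
                 fit$residuals <= b$upper_offset)
  expect_gte(inside, 0.88)
  expect_lte(inside, 0.92)
})

test_that("coverage is exact on a zero-noise cohort and errors on empty input", {
  cfg <- zero_noise_config(n = 80)
  co <- generate_cohort(cfg)
  age <- cohort_age_years(co)
  ref <- build_reference(fit_exponential(age, co$naive_pct_cd19),
                         "fraction_percent")
  cov <- empirical_coverage(ref, age, co$naive_pct_cd19)
  expect_equal(unname(cov), c(1, 1))
  expect_error(empirical_coverage(ref, numeric(0), numeric(0)), "empty")
})

test_that("gaussian residuals give the normal-theory band half-width", {
  set.seed(19)
  age <- sample_ages(2000) / 365
  y <- simulate_measure(band_trajectory(noise_kind = "gaussian"), age)
  ref <- build_reference(fit_exponential(age, y), "absolute_count")
  b <- ref$bands[["95"]]
  half <- (b$upper_offset - b$lower_offset) / 2
  expect_equal(half, 1.96 * 4, tolerance = 0.4 / (1.96 * 4))
})
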