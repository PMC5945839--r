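test_that("trajectory evaluation matches the closed form and clamps", {
  tr <- trajectory_spec("exponential", a = 10, b = 88, c = -0.5)
  expect_equal(evaluate_trajectory(tr, 0), 98)
  expect_equal(evaluate_trajectory(tr, 2), 10 + 88 * exp(-1), tolerance = 1e-12)
  expect_equal(evaluate_trajectory(tr, c(0, 2)),
               c(98, 10 + 88 * exp(-1)), tolerance = 1e-12)

  flat <- trajectory_spec("exponential", a = 5, b = 0, c = -3)
  expect_equal(evaluate_trajectory(flat, c(0, 1, 17.3)), rep(5, 3))

  bi <- trajectory_spec("biexponential", a = 2, b = -30, c = -2,
                        b2 = 40, c2 = -0.3, unit = "count")
  expect_equal(evaluate_trajectory(bi, 1.5),
               max(0, 2 - 30 * exp(-3) + 40 * exp(-0.45)), tolerance = 1e-12)

  over <- trajectory_spec("exponential", a = 90, b = 40, c = -1)
  expect_equal(evaluate_trajectory(over, 0), 100)   # percent clamp
  neg <- trajectory_spec("exponential", a = 5, b = -30, c = -1, unit = "count")
  expect_equal(evaluate_trajectory(neg, 0), 0)      # count clamp

  expect_error(evaluate_trajectory(tr, -1), "non-negative")
})

test_that("trajectory_spec validates its fields", {
  expect_error(trajectory_spec("exponential", a = 1, b = 1, c = 1, b2 = 2),
               "b2")
  expect_error(trajectory_spec("biexponential", a = 1, b = 1, c = 1), "b2")
  expect_error(trajectory_spec("exponential", a = 1, b = 1, c = 1,
                               noise_scale = -1), "noise_scale")
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(age_min_days = 10, age_max_days = 5), "age_min")
  expect_error(cohort_config(cd20_coexpression_rate = 1.2), "coexpression")
})

test_that("identical (config, seed) yields an identical cohort", {
  cfg <- cohort_config(n_subjects = 120, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_cohort(cfg, seed = 7), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg, seed = 8),
                         generate_cohort(cfg, seed = 7)))
})

test_that("zero-noise cohorts fall exactly on their trajectory curves", {
  cfg <- zero_noise_config(n = 60)
  co <- generate_cohort(cfg)
  age <- cohort_age_years(co)
  for (key in c("totalB_pct_cd19", "totalB_abs_cd19", "naive_pct_cd19",
                "nonswitched_pct_cd19", "switched_pct_cd19")) {
    expect_equal(co[[key]], evaluate_trajectory(cfg$trajectories[[key]], age),
                 tolerance = 1e-12, label = key)
  }
  # and the regression recovers the generating parameters (loop closure)
  fit <- fit_exponential(age, co$naive_pct_cd19)
  tr <- cfg$trajectories$naive_pct_cd19
  expect_equal(c(fit$a, fit$b, fit$c), c(tr$a, tr$b, tr$c), tolerance = 1e-5)
})

test_that("generated cohorts are internally consistent", {
  co <- generate_cohort(cohort_config(n_subjects = 400, seed = 21))
  ok <- !is.na(co$totalB_abs_cd19)
  expect_gt(sum(ok), 300)
  for (s in c("naive", "nonswitched", "switched", "memory")) {
    expect_lt(max(abs(co[[paste0(s, "_abs_cd19")]][ok] -
                      co$totalB_abs_cd19[ok] *
                        co[[paste0(s, "_pct_cd19")]][ok] / 100)),
              0.5, label = s)
  }
  expect_true(all(co$memory_pct_cd19[ok] ==
                    co$nonswitched_pct_cd19[ok] + co$switched_pct_cd19[ok]))
  expect_true(all(co$naive_pct_cd19[ok] + co$memory_pct_cd19[ok] <= 100 + 1e-9))
  pct_cols <- grep("_pct_", names(co), value = TRUE)
  for (p in pct_cols) {
    expect_true(all(co[[p]][ok] >= 0 & co[[p]][ok] <= 100), label = p)
  }
  abs_cols <- grep("_abs", names(co), value = TRUE)
  for (a in abs_cols) expect_true(all(co[[a]][ok] >= 0), label = a)
  expect_true(all(co$age_days >= 2 & co$age_days <= 6570))
  # subjects without material carry no panel
  expect_true(all(is.na(co$totalB_abs_cd19[co$material_insufficient])))
})

test_that("newborns in the default cohort are almost entirely naive", {
  co <- generate_cohort(cohort_config(n_subjects = 1000, seed = 5))
  young <- co$age_days < 7
  expect_gt(sum(young), 20)
  med <- median(co$naive_pct_cd19[young], na.rm = TRUE)
  expect_equal(med, 98, tolerance = 2 / 98)
})

test_that("default absolute memory counts peak in early childhood", {
  co <- generate_cohort(cohort_config(n_subjects = 4000, seed = 9))
  age <- cohort_age_years(co)
  bands <- cut(age, c(0, 0.5, 1.5, 3, 10, 18), include.lowest = TRUE)
  med <- tapply(co$memory_abs_cd19, bands, median, na.rm = TRUE)
  expect_gt(med[3], med[1])   # rises from birth toward the age-2 peak
  expect_gt(med[3], med[5])   # and falls again in adolescence
})
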