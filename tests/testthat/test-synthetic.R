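test_that("meal_kernel matches its closed form", {
  expect_identical(meal_kernel(0, amp = 3, rise_min = 45, decay_min = 90), 0)
  expect_equal(meal_kernel(45, 3, 45, 90), 3)                  # peak at t = rise
  expect_equal(meal_kernel(90, 3, 45, 90), 3 * 2 * exp(-1))    # 2.207276...
  # value-continuous blend into the exponential tail
  eps <- 1e-6
  expect_equal(meal_kernel(90 + eps, 3, 45, 90), meal_kernel(90, 3, 45, 90),
               tolerance = 1e-5)
  # tail decays with the configured time constant
  expect_equal(meal_kernel(90 + 60, 3, 45, 60) / meal_kernel(90, 3, 45, 60),
               exp(-1), tolerance = 1e-12)
  expect_error(meal_kernel(-1, 3, 45, 90), class = "cgm_parameter_error")
  expect_error(meal_kernel(10, 3, 0, 90), class = "cgm_parameter_error")
})

test_that("simulate_patient has the documented length, determinism and limits", {
  prof <- patient_profile(seed = 5)
  s <- simulate_patient(prof, days = 2, interval_min = 5)
  expect_identical(length(s), 576L) # two days at 5-minute sampling

  s2 <- simulate_patient(prof, days = 2, interval_min = 5)
  expect_identical(s$glucose, s2$glucose)
  expect_equal(as.numeric(s$timestamps), as.numeric(s2$timestamps))

  # degenerate limit: no meals, no circadian term, no noise -> flat at basal
  flat <- patient_profile(basal_mmol_l = 8, circadian_amp_mmol_l = 0,
                          meal_times_h = numeric(0), meal_amp_mmol_l = numeric(0),
                          noise_sd_mmol_l = 0)
  sf <- simulate_patient(flat, days = 1)
  expect_identical(unique(sf$glucose), 8)

  expect_error(simulate_patient(prof, days = 1, interval_min = 7),
               class = "cgm_parameter_error")
  expect_error(simulate_patient(prof, days = 0), class = "cgm_parameter_error")
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  # meals and circadian off: the trace is basal + AR(1) noise
  prof <- patient_profile(basal_mmol_l = 8, circadian_amp_mmol_l = 0,
                          meal_times_h = numeric(0), meal_amp_mmol_l = numeric(0),
                          ar_coef = 0.8, noise_sd_mmol_l = 0.3, seed = 21)
  s <- simulate_patient(prof, days = 35) # 10,080 samples
  x <- s$glucose - 8
  n <- length(x)
  rho_hat <- stats::cor(x[-1], x[-n]) # direct autocorrelation estimate
  expect_lt(abs(rho_hat - 0.8), 0.05)
})

test_that("simulate_cohort is deterministic and respects its config", {
  cfg <- generator_config(n_patients = 3, days_per_patient = 2)
  co1 <- simulate_cohort(cfg, seed = 9)
  co2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(lapply(co1, `[[`, "glucose"), lapply(co2, `[[`, "glucose"))
  expect_identical(lapply(co1, `[[`, "calibration_bg"),
                   lapply(co2, `[[`, "calibration_bg"))
  expect_identical(vapply(co1, `[[`, "", "patient_id"), c("P01", "P02", "P03"))

  # patient streams derive from the master seed: different seed, different data
  co3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(co1[[1]]$glucose, co3[[1]]$glucose))

  # clamp bounds hold everywhere
  g <- unlist(lapply(co1, `[[`, "glucose"))
  expect_true(all(g >= cfg$clamp[1] & g <= cfg$clamp[2]))

  # rate-zero cases
  cfg0 <- generator_config(n_patients = 2, days_per_patient = 2,
                           calibration_rate_per_day = 0, gap_rate_per_day = 0)
  co0 <- simulate_cohort(cfg0, seed = 1)
  expect_identical(sum(vapply(co0, function(s) sum(!is.na(s$calibration_bg)), 0)), 0)
  expect_identical(vapply(co0, length, integer(1)), c(576L, 576L)) # no deletions
})

test_that("gaps are deletions that regularize() splits back into segments", {
  cfg <- generator_config(n_patients = 1, days_per_patient = 7,
                          gap_rate_per_day = 1.5, calibration_rate_per_day = 0)
  s <- simulate_cohort(cfg, seed = 4)[[1]]
  expect_lt(length(s), 7 * 288) # something was deleted
  segs <- regularize(s)
  expect_gt(length(segs), 1) # at least one gap exceeded the 15-min trust bound
  rel0 <- s$timestamps[1]
  for (seg in segs) {
    rel <- as.numeric(difftime(seg$timestamps, rel0, units = "mins"))
    expect_true(all(abs(rel %% 5) < 1e-9))
  }
})

test_that("default cohort calibration targets hold for master seed 1", {
  ps <- pooled_summary(simulate_cohort(default_cohort_config(), seed = 1))
  expect_gte(ps$n, 32000)
  expect_lt(abs(ps$mean - 8.32), 0.15)
  expect_lt(abs(ps$sd - 3.51), 0.30)
})

test_that("generator config serializes to YAML", {
  y <- config_to_yaml(default_cohort_config())
  parsed <- yaml::yaml.load(y)
  expect_identical(parsed$n_patients, 8L)
  expect_identical(parsed$profile_sampler, "default_profile_sampler")
})
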