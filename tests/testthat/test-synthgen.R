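test_that("sim_config validates mixes, Gompertz parameters and tau_zero_age", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(device_mix = c(wrist_research = 0.5, hip_research = 0.2,
                                         phone = 0.2, watch = 0.2)))
  expect_error(sim_config(gompertz_M0 = 0.05, gompertz_Gamma = 0.09), "<< 1")
  expect_error(sim_config(tau_zero_age = 75), "tau_zero_age")
})

test_that("accel traces plant detectable peaks and are seed-deterministic", {
  tr1 <- simulate_accel_trace(c(1, 2, 3), peak_height = 2, duration = 10, seed = 5)
  tr2 <- simulate_accel_trace(c(1, 2, 3), peak_height = 2, duration = 10, seed = 5)
  expect_identical(tr1$magnitudes, tr2$magnitudes)
  # no peaks injected: noise stays below the 1.3 g threshold
  tr0 <- simulate_accel_trace(numeric(0), baseline_noise_sd = 0.01,
                              duration = 10, seed = 6)
  expect_lt(max(tr0$magnitudes), 1.3)
  # planted peaks appear exactly at the requested times
  pk <- detect_candidate_peaks(tr1)
  expect_equal(nrow(pk), 3)
  expect_equal(round(pk$time), c(1, 2, 3))
  expect_error(simulate_accel_trace(c(1, 1.001), sampling_rate = 100),
               "overlapping")
  expect_error(simulate_accel_trace(c(11), duration = 10), "within")
})

test_that("step series honour the pattern-only contract", {
  cfg <- sim_config(missing_day_rate = 0)
  s0 <- simulate_step_series(stub_subject(latent_baa0 = 0), 7, cfg, seed = 21)
  s10 <- simulate_step_series(stub_subject(latent_baa0 = 10), 7, cfg, seed = 21)
  daily <- function(s) vapply(1:7, function(d)
    sum(s$counts[((d - 1) * 1440 + 1):(d * 1440)]), numeric(1))
  # identical totals, different minute distribution
  expect_equal(daily(s0), daily(s10))
  expect_false(identical(s0$counts, s10$counts))
  # the planted signal shifts activity from morning (6-12h) to evening
  morning <- function(s) sum(s$counts[rep(6 * 60 + 1:(6 * 60), 7) +
                                        rep((0:6) * 1440, each = 360)])
  expect_gt(morning(s0), morning(s10))
})

test_that("phone undercounting and winter damping scale totals as configured", {
  cfg <- sim_config(missing_day_rate = 0)
  watch <- simulate_step_series(stub_subject(device = "watch"), 14, cfg, seed = 31)
  phone <- simulate_step_series(stub_subject(device = "phone"), 14, cfg, seed = 31)
  ratio <- sum(phone$counts) / sum(watch$counts)
  expect_lt(abs(ratio - cfg$phone_undercount), 0.02)
  summer <- simulate_step_series(stub_subject(season = "summer"), 14, cfg, seed = 32)
  winter <- simulate_step_series(stub_subject(season = "winter"), 14, cfg, seed = 32)
  expect_lt(sum(winter$counts), sum(summer$counts))
})

test_that("missing days are whole-day zero blocks flagged in the mask", {
  cfg <- sim_config(missing_day_rate = 1)
  found3 <- FALSE
  for (seed in 1:20) {
    s <- simulate_step_series(stub_subject(), 7, cfg, seed = seed)
    k <- sum(s$missing_mask)
    expect_gte(k, 1); expect_lte(k, 3)
    for (d in which(s$missing_mask)) {
      expect_true(all(s$counts[((d - 1) * 1440 + 1):(d * 1440)] == 0))
    }
    if (k == 3) found3 <- TRUE
  }
  expect_true(found3)
  expect_error(simulate_step_series(stub_subject(), 6, cfg, seed = 1), "week")
})

test_that("AR(1) BAA tracks have the closed-form autocorrelation structure", {
  # tau -> 0 limit: consecutive values essentially uncorrelated
  tr <- simulate_baa_track(60, 10000, tau = 0.05, sigma = 3, seed = 41)
  r1 <- cor(tr$baa[-1], tr$baa[-length(tr$baa)])
  expect_lt(abs(r1), 3 / sqrt(10000))
  # tau = 14: empirical ACF at lag 14 near exp(-1)
  tr14 <- simulate_baa_track(60, 20000, tau = 14, sigma = 3, seed = 42)
  ac <- baa_autocorrelation(tr14, max_lag = 14)
  expect_lt(abs(ac$values[15] - exp(-1)), 0.05)
  # empirical lag-k ACF matches exp(-k/tau) within 3 standard errors
  for (k in c(1, 4, 7, 14)) {
    se <- sqrt((1 + exp(-2 * k / 14)) / 20000) * 3  # generous normal-theory SE
    expect_lt(abs(ac$values[k + 1] - exp(-k / 14)), max(se, 0.03))
  }
  # sigma = 0 gives a constant zero track
  expect_true(all(simulate_baa_track(60, 100, tau = 7, sigma = 0, seed = 1)$baa == 0))
  expect_identical(simulate_baa_track(50, 60, 7, seed = 9)$baa,
                   simulate_baa_track(50, 60, 7, seed = 9)$baa)
})

test_that("relaxation times decline linearly in the mean and spread log-normally", {
  cfg <- sim_config()
  # mean rate at age a is r0 (1 - a / tau_zero_age): check via many draws
  rates <- function(age, n) vapply(seq_len(n), function(i)
    1 / draw_relaxation_time(age, cfg, seed = i), numeric(1))
  r40 <- mean(rates(40, 3000))
  r75 <- mean(rates(75, 3000))
  expect_lt(abs(r40 / (cfg$r0 * (1 - 40 / 110)) - 1), 0.05)
  expect_lt(abs(r75 / (cfg$r0 * (1 - 75 / 110)) - 1), 0.05)
  # fraction with tau > 21 d grows with age
  frac_slow <- vapply(c(45, 60, 75), function(a)
    mean(vapply(1:1500, function(i)
      draw_relaxation_time(a, cfg, seed = 10000 + i), numeric(1)) > 21),
    numeric(1))
  expect_true(all(diff(frac_slow) > 0))
  expect_error(draw_relaxation_time(115, cfg), "tau_zero_age")
})

test_that("survival simulation follows the Gompertz hazard at effective age", {
  cfg <- sim_config(n_subjects = 10000, seed = 51, age_range = c(40, 80))
  # Gamma = 0 reduces to exponential lifetimes with rate M0
  set.seed(1)
  dts <- rgompertz(50000, M0 = 0.02, Gamma = 0, t0 = 50)
  expect_lt(abs(mean(dts) - 50), 1.5)   # exponential mean 1/M0
  # higher latent BAA means strictly more deaths
  subj <- data.frame(age = rep(70, 20000),
                     latent_baa0 = rep(c(0, 10), each = 10000))
  out <- simulate_survival(subj, cfg, seed = 2)
  d0 <- mean(out$dead[subj$latent_baa0 == 0])
  d10 <- mean(out$dead[subj$latent_baa0 == 10])
  expect_gt(d10, d0)
  # bookkeeping: t_end = age + dt_followup, censored at the follow-up window
  expect_equal(out$t_end, out$age + out$dt_followup)
  expect_true(all(out$dt_followup[!out$dead] == cfg$followup))
  expect_true(all(out$dt_followup[out$dead] < cfg$followup))
})

test_that("cohort generation is reproducible and carries all labels", {
  cfg <- sim_config(n_subjects = 200, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_setequal(unique(c1$device) %in% names(cfg$device_mix), TRUE)
  expect_true(all(c1$age >= 40 & c1$age <= 80))
  # morbidity prevalence increases with biological age
  bioage <- c1$age + c1$latent_baa0
  expect_gt(mean(c1$morbid[bioage > median(bioage)]),
            mean(c1$morbid[bioage <= median(bioage)]))
})
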