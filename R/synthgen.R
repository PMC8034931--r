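#' Simulation configuration
#'
#' Bundles the parameters of the synthetic cohort generator. Defaults encode
#' the study conditions the downstream analyses assume: a Gompertz mortality
#' law at human scale (M0 = 2e-5/yr, Gamma = 0.09/yr, mortality-rate doubling
#' time about 8 years), recovery rates that decline linearly with age and
#' extrapolate to zero at 110 years, and device/season batch effects (phones
#' undercount steps, winter damps activity).
#'
#' @param n_subjects Number of subjects.
#' @param age_range Enrollment age range in years, `c(low, high)`.
#' @param seed Integer seed; every generator draw derives from it.
#' @param device_mix Named proportions over devices
#'   (`wrist_research`, `hip_research`, `phone`, `watch`); must sum to 1.
#' @param season_mix Named proportions over `winter`/`summer`; sum to 1.
#' @param missing_day_rate Probability that a subject has 1-3 zero-imputed
#'   missing days.
#' @param baa_effect_scale Standard deviation of latent BAA at enrollment,
#'   years.
#' @param gompertz_M0 Initial mortality rate, 1/year.
#' @param gompertz_Gamma Mortality doubling exponent, 1/year.
#' @param followup Follow-up window, years.
#' @param tau_zero_age Age (years) at which the mean recovery rate
#'   extrapolates to zero; must exceed `age_range[2]`.
#' @param tau_noise_sd Log-scale spread of individual relaxation times.
#' @param r0 Mean recovery rate at age zero, 1/day. The default 0.157/day
#'   puts the mean recovery time near two weeks at age 60.
#' @param phone_undercount Fraction of true steps a phone records.
#' @param winter_factor Multiplier on total activity in winter.
#' @param pattern_link Log-ratio shift of activity from morning to evening
#'   per year of latent BAA (the planted intraday-pattern signal).
#' @param pattern_only If `TRUE`, latent BAA changes only the intraday
#'   pattern, never the daily total, so a correct model must decouple from
#'   mean steps.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 500,
                       age_range = c(40, 80),
                       seed = 1L,
                       device_mix = c(wrist_research = 0.4, hip_research = 0.2,
                                      phone = 0.2, watch = 0.2),
                       season_mix = c(winter = 0.5, summer = 0.5),
                       missing_day_rate = 0.3,
                       baa_effect_scale = 5,
                       gompertz_M0 = 2e-5,
                       gompertz_Gamma = 0.09,
                       followup = 10,
                       tau_zero_age = 110,
                       tau_noise_sd = 0.5,
                       r0 = 0.157,
                       phone_undercount = 0.6,
                       winter_factor = 0.8,
                       pattern_link = 0.06,
                       pattern_only = TRUE) {
  cfg <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
              seed = as.integer(seed), device_mix = device_mix,
              season_mix = season_mix, missing_day_rate = missing_day_rate,
              baa_effect_scale = baa_effect_scale, gompertz_M0 = gompertz_M0,
              gompertz_Gamma = gompertz_Gamma, followup = followup,
              tau_zero_age = tau_zero_age, tau_noise_sd = tau_noise_sd,
              r0 = r0, phone_undercount = phone_undercount,
              winter_factor = winter_factor, pattern_link = pattern_link,
              pattern_only = pattern_only)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1,
            length(cfg$age_range) == 2, cfg$age_range[1] < cfg$age_range[2],
            abs(sum(cfg$device_mix) - 1) < 1e-8,
            abs(sum(cfg$season_mix) - 1) < 1e-8,
            cfg$gompertz_M0 > 0, cfg$gompertz_Gamma > 0,
            cfg$missing_day_rate >= 0, cfg$missing_day_rate <= 1,
            cfg$followup > 0, cfg$tau_noise_sd >= 0, cfg$r0 > 0)
  if (cfg$gompertz_M0 / cfg$gompertz_Gamma >= 0.1) {
    stop("gompertz_M0/gompertz_Gamma must be << 1 (got ",
         signif(cfg$gompertz_M0 / cfg$gompertz_Gamma, 3), ")")
  }
  if (cfg$tau_zero_age <= cfg$age_range[2]) {
    stop("tau_zero_age must exceed the upper age bound")
  }
  invisible(cfg)
}

#' Simulate a raw acceleration-magnitude trace with planted steps
#'
#' Builds a trace of Gaussian baseline noise around 1 g (resting gravity)
#' with one narrow super-baseline peak of height `peak_height` at each
#' requested step time. Used to exercise the step counter against planted
#' ground truth.
#'
#' @param step_times Step times in seconds within `[0, duration]`.
#' @param peak_height Peak magnitude in g (absolute, not above baseline).
#' @param sampling_rate Hz, at least 25.
#' @param baseline_noise_sd Noise standard deviation, g.
#' @param duration Trace duration, seconds.
#' @param seed Integer seed.
#' @return An `accel_trace`.
#' @export
simulate_accel_trace <- function(step_times, peak_height = 2,
                                 sampling_rate = 100,
                                 baseline_noise_sd = 0.01,
                                 duration = 60, seed = 1L) {
  stopifnot(sampling_rate >= 25, duration > 0, baseline_noise_sd >= 0)
  if (length(step_times) > 0) {
    if (any(step_times < 0 | step_times > duration)) {
      stop("step_times must lie within [0, duration]")
    }
    st <- sort(step_times)
    if (length(st) > 1 && any(diff(st) < 1 / sampling_rate)) {
      stop("overlapping step times: two steps closer than one sample (",
           signif(1 / sampling_rate, 3), " s) cannot be represented")
    }
  }
  n <- floor(duration * sampling_rate)
  set.seed(seed)
  mag <- 1 + stats::rnorm(n, 0, baseline_noise_sd)
  if (length(step_times) > 0) {
    idx <- pmin(pmax(round(step_times * sampling_rate) + 1L, 2L), n - 1L)
    mag[idx] <- peak_height
    # guarantee a strict local maximum even under adverse noise draws
    mag[idx - 1L] <- pmin(mag[idx - 1L], peak_height - 0.05)
    mag[idx + 1L] <- pmin(mag[idx + 1L], peak_height - 0.05)
  }
  accel_trace(pmax(mag, 0), sampling_rate = sampling_rate)
}

# circadian minute weights for one day: two-peak commute template on
# weekdays, flatter and later template on weekends; latent BAA shifts
# activity from the morning bout toward the evening at fixed total
circadian_weights <- function(weekend, baa, pattern_link) {
  m <- (seq_len(1440) - 0.5) / 60   # hour of day
  gauss <- function(mu, sd) exp(-((m - mu)^2) / (2 * sd^2))
  if (!weekend) {
    morning <- 1.0 * gauss(8, 1.0)
    midday  <- 0.35 * gauss(13, 2.5)
    evening <- 0.9 * gauss(18, 1.2)
  } else {
    morning <- 0.45 * gauss(10, 1.6)
    midday  <- 0.45 * gauss(14, 3.0)
    evening <- 0.55 * gauss(19, 1.5)
  }
  base <- 0.02
  # planted signal: log-ratio of morning vs evening amplitude moves with BAA
  shift <- exp(pattern_link * baa)
  w <- morning / shift + midday + evening * shift + base
  w[m < 6.5 | m > 23] <- w[m < 6.5 | m > 23] * 0.02   # sleep
  w / sum(w)
}

#' Simulate a minute-resolution step series for one subject
#'
#' Distributes a subject's daily step total over minutes of the day with a
#' circadian template (morning/evening commute bouts on weekdays, flatter
#' weekends). Latent BAA shifts activity from morning toward evening bouts
#' at a fixed daily total when `config$pattern_only` is `TRUE` (so the
#' pattern signal is independent of mean steps); otherwise it also lowers
#' the total. Phones record a thinned fraction of true steps, winter scales
#' totals down, and with probability `missing_day_rate` 1-3 whole days are
#' zeroed and flagged in the missing mask.
#'
#' @param subject One-row data.frame with at least `age`, `latent_baa0`,
#'   `device`, `season`, `id` (see [simulate_cohort()]).
#' @param n_days Number of days, at least 7.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `step_series`.
#' @export
simulate_step_series <- function(subject, n_days, config, seed = 1L) {
  if (n_days < 7) stop("n_days must be at least 7: the model needs a week")
  validate_sim_config(config)
  set.seed(seed)
  baa <- subject$latent_baa0
  # base daily total: lognormal around ~8500 steps, subject-specific level
  level <- stats::rlnorm(1, log(8500), 0.35)
  if (!config$pattern_only) level <- level * exp(-0.03 * baa)
  if (identical(subject$season, "winter")) level <- level * config$winter_factor
  counts <- integer(n_days * 1440L)
  weekend_idx <- ((seq_len(n_days) - 1L) %% 7L) %in% c(5L, 6L)
  # daily totals are drawn before any pattern-dependent sampling so that in
  # pattern-only mode the totals are identical across latent BAA values
  totals <- stats::rpois(n_days, level * stats::runif(n_days, 0.8, 1.2))
  mask <- rep(FALSE, n_days)
  if (stats::runif(1) < config$missing_day_rate) {
    k <- sample.int(3L, 1L)
    mask[sample.int(n_days, k)] <- TRUE
  }
  for (d in seq_len(n_days)) {
    if (mask[d]) next
    w <- circadian_weights(weekend_idx[d], baa, config$pattern_link)
    day_counts <- as.integer(stats::rmultinom(1, totals[d], w))
    counts[((d - 1L) * 1440L + 1L):(d * 1440L)] <- day_counts
  }
  if (identical(subject$device, "phone")) {
    counts <- stats::rbinom(length(counts), counts, config$phone_undercount)
  }
  step_series(counts, device = subject$device, season = subject$season,
              missing_mask = mask, subject_id = as.character(subject$id))
}

#' Simulate a mean-reverting daily BAA trajectory
#'
#' Discretised Ornstein-Uhlenbeck (AR(1)) process with relaxation time
#' `tau` days and stationary standard deviation `sigma` years:
#' `x(d+1) = x(d) exp(-1/tau) + sigma sqrt(1 - exp(-2/tau)) eps`. Its
#' autocorrelation function is exactly `exp(-lag/tau)`.
#'
#' @param age Subject age in years (carried as an attribute).
#' @param n_days Track length, at least 30.
#' @param tau Relaxation time, days; positive.
#' @param sigma Stationary standard deviation, years.
#' @param seed Integer seed.
#' @return A `baa_track` of daily values, stationary from day 1.
#' @export
simulate_baa_track <- function(age, n_days, tau, sigma = 3, seed = 1L) {
  stopifnot(tau > 0, n_days >= 30, sigma >= 0)
  set.seed(seed)
  phi <- exp(-1 / tau)
  innov_sd <- sigma * sqrt(1 - exp(-2 / tau))
  x <- numeric(n_days)
  x[1] <- stats::rnorm(1, 0, sigma)   # start in the stationary distribution
  eps <- stats::rnorm(n_days - 1)
  for (d in 2:n_days) x[d] <- x[d - 1] * phi + innov_sd * eps[d - 1]
  tr <- baa_track(x)
  attr(tr, "age") <- age
  attr(tr, "tau") <- tau
  tr
}

#' Draw an individual BAA relaxation time
#'
#' The population mean recovery rate declines linearly with age,
#' `rbar(age) = r0 (1 - age / tau_zero_age)`, reaching zero at
#' `tau_zero_age`; an individual's rate is drawn log-normally around the
#' mean with log-sd `tau_noise_sd`. The relaxation time is the inverse rate.
#'
#' @param age Years; must be below `config$tau_zero_age`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Relaxation time tau in days (positive scalar).
#' @export
draw_relaxation_time <- function(age, config, seed = 1L) {
  if (age >= config$tau_zero_age) {
    stop("age must be below tau_zero_age (", config$tau_zero_age, " y)")
  }
  set.seed(seed)
  rbar <- config$r0 * (1 - age / config$tau_zero_age)
  # log-normal with mean rbar: mu = log(rbar) - s^2/2
  s <- config$tau_noise_sd
  r <- stats::rlnorm(1, log(rbar) - s^2 / 2, s)
  1 / r
}

#' Draw Gompertz event times
#'
#' Inverse-CDF sampling of remaining lifetime from age `t0` under the
#' Gompertz hazard `M(t) = M0 exp(Gamma t)`. With `Gamma = 0` this reduces
#' to exponential lifetimes at rate `M0`.
#'
#' @param n Number of draws.
#' @param M0,Gamma Gompertz parameters, 1/year; `M0 > 0`, `Gamma >= 0`.
#' @param t0 Conditioning age(s), years (scalar or length-n).
#' @return Remaining-lifetime draws in years.
#' @export
rgompertz <- function(n, M0, Gamma, t0 = 0) {
  stopifnot(M0 > 0, Gamma >= 0)
  u <- stats::runif(n)
  if (Gamma == 0) return(-log(u) / M0)
  # solve (M0/Gamma) (exp(Gamma (t0+dt)) - exp(Gamma t0)) = -log(u)
  (log(exp(Gamma * t0) - Gamma * log(u) / M0) / Gamma) - t0
}

#' Simulate survival over follow-up for a cohort
#'
#' Samples each subject's event time from the Gompertz hazard evaluated at
#' the effective biological age (chronological age + latent BAA), so higher
#' BAA carries excess mortality. Subjects dying within the follow-up window
#' get `dead = TRUE` and their age at death as `t_end`; survivors are
#' censored at `age + followup`.
#'
#' @param subjects Cohort data.frame from [simulate_cohort()] (columns `age`,
#'   `latent_baa0` used).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return The cohort with `dead`, `t_end`, `dt_followup` filled in.
#' @export
simulate_survival <- function(subjects, config, seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  n <- nrow(subjects)
  t_eff <- subjects$age + subjects$latent_baa0
  dt_event <- rgompertz(n, config$gompertz_M0, config$gompertz_Gamma, t0 = t_eff)
  dead <- dt_event < config$followup
  dt <- pmin(dt_event, config$followup)
  subjects$dead <- dead
  subjects$dt_followup <- dt
  subjects$t_end <- subjects$age + dt
  subjects
}

#' Simulate a full cohort table
#'
#' Draws ages uniformly over `age_range`, binary sex, occupation groups,
#' device and season tags from the configured mixes, latent BAA at
#' enrollment from `N(0, baa_effect_scale^2)`, a morbidity label from a
#' logistic model in biological age (`age + latent_baa0`), and survival
#' labels via [simulate_survival()].
#'
#' @param config A [sim_config()].
#' @param morb_slope Logistic slope on biological age, 1/year.
#' @param morb_midpoint Biological age (years) at 50% morbidity prevalence.
#' @return A data.frame, one row per subject.
#' @export
simulate_cohort <- function(config, morb_slope = 0.09, morb_midpoint = 65) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  subjects <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    sex = stats::rbinom(n, 1, 0.5),
    occupation = sample(c("clerical", "manual", "professional", "service"),
                        n, replace = TRUE),
    device = sample(names(config$device_mix), n, replace = TRUE,
                    prob = config$device_mix),
    season = sample(names(config$season_mix), n, replace = TRUE,
                    prob = config$season_mix),
    latent_baa0 = stats::rnorm(n, 0, config$baa_effect_scale),
    stringsAsFactors = FALSE
  )
  p_morb <- stats::plogis(morb_slope * (subjects$age + subjects$latent_baa0 - morb_midpoint))
  subjects$morbid <- stats::rbinom(n, 1, p_morb) == 1
  simulate_survival(subjects, config, seed = config$seed + 1L)
}
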