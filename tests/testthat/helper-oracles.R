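# Independent brute-force oracles used across the suite.

# Exhaustive sliding-window step selection: enumerate every window start on
# the stride grid; a peak is counted iff it is the (tie -> earliest) maximum
# of every window containing it.
brute_force_window_select <- function(times_s, mags, window_ms = 480,
                                      stride_ms = 160, t_end_s = NULL) {
  if (length(times_s) == 0) return(integer(0))
  t_ms <- times_s * 1000
  if (is.null(t_end_s)) t_end_s <- max(times_s) + 1
  starts <- seq(0, t_end_s * 1000, by = stride_ms)
  beaten <- rep(FALSE, length(t_ms))
  covered <- rep(FALSE, length(t_ms))
  for (s in starts) {
    inside <- which(t_ms >= s & t_ms < s + window_ms)
    if (length(inside) == 0) next
    covered[inside] <- TRUE
    best <- inside[order(-mags[inside], t_ms[inside])][1]
    beaten[setdiff(inside, best)] <- TRUE
  }
  which(covered & !beaten)
}

# brute-force bout partition: greedy left-to-right grouping by the gap rule
brute_force_bouts <- function(times, gap, min_steps) {
  if (length(times) == 0) return(times)
  groups <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] < gap) cur <- c(cur, t)
    else { groups <- c(groups, list(cur)); cur <- t }
  }
  groups <- c(groups, list(cur))
  out <- unlist(Filter(function(g) length(g) >= min_steps, groups))
  if (is.null(out)) numeric(0) else out
}

# brute-force biased normalized ACF (double loop), complete tracks
brute_force_acf <- function(x, max_lag) {
  xm <- mean(x)
  denom <- sum((x - xm)^2)
  vapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(length(x) - k)) s <- s + (x[t] - xm) * (x[t + k] - xm)
    s / denom
  }, numeric(1))
}

# per-subject accumulation of the Gompertz -lnLH (no vectorisation)
brute_force_gompertz_nll <- function(M0, G, t_end, dt, dead) {
  total <- 0
  for (i in seq_along(t_end)) {
    total <- total + (M0 / G) * exp(G * t_end[i]) * (1 - exp(-G * dt[i]))
    if (dead[i]) total <- total - (log(M0) + G * t_end[i])
  }
  total
}

# one-row subject stub for the step-series generator
stub_subject <- function(id = "S1", age = 55, latent_baa0 = 0,
                         device = "wrist_research", season = "summer",
                         sex = 0) {
  data.frame(id = id, age = age, sex = sex, latent_baa0 = latent_baa0,
             device = device, season = season, stringsAsFactors = FALSE)
}

# small cohort + weekly series for network tests
make_training_cohort <- function(n, seed, n_days = 7,
                                 cfg = sim_config(n_subjects = n, seed = seed)) {
  cohort <- simulate_cohort(cfg)
  series <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_step_series(cohort[i, ], n_days, cfg, seed = seed * 1000L + i))
  names(series) <- cohort$id
  list(cohort = cohort, series = series, cfg = cfg)
}

log_mean_daily_steps <- function(series) {
  keep <- which(!series$missing_mask)
  daily <- vapply(keep, function(d)
    sum(series$counts[((d - 1L) * 1440L + 1L):(d * 1440L)]), numeric(1))
  log(mean(daily))
}
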