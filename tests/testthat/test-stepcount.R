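test_that("candidate peak detection finds exactly the planted local maxima", {
  # flat sub-threshold signal: nothing detected
  tr <- accel_trace(rep(1, 1000))
  expect_equal(nrow(detect_candidate_peaks(tr)), 0)

  # single planted 2 g spike
  m <- rep(1, 1000); m[500] <- 2
  pk <- detect_candidate_peaks(accel_trace(m))
  expect_equal(pk$index, 500)
  expect_equal(pk$time, 4.99)
  expect_equal(pk$magnitude, 2)

  # adjacent samples cannot both be strict local maxima
  m <- rep(1, 1000); m[500] <- 2; m[501] <- 2
  expect_equal(nrow(detect_candidate_peaks(accel_trace(m))), 0)
  m[501] <- 1.9   # now 500 is a strict maximum
  expect_equal(detect_candidate_peaks(accel_trace(m))$index, 500)

  expect_error(detect_candidate_peaks(accel_trace(c(1, 1))), "3 samples")
})

test_that("windowed selection keeps isolated peaks and resolves near pairs", {
  # isolated peaks >= 480 ms apart are all counted
  pk <- data.frame(time = c(0.1, 0.6, 1.2), magnitude = c(2, 2.1, 1.9))
  expect_equal(select_peaks_windowed(pk)$time, pk$time)

  # two peaks 100 ms apart share windows: only the larger is counted
  pk <- data.frame(time = c(1.00, 1.10), magnitude = c(1.8, 2.2))
  sel <- select_peaks_windowed(pk)
  expect_equal(sel$time, 1.10)

  # magnitude tie breaks toward the earlier peak
  pk <- data.frame(time = c(1.00, 1.10), magnitude = c(2, 2))
  expect_equal(select_peaks_windowed(pk)$time, 1.00)
})

test_that("saturated traces never register more than 3 steps per 960 ms", {
  # a distinct super-threshold peak in every 160 ms frame for 10 s
  set.seed(42)
  times <- (0:61) * 0.160 + 0.080
  mags <- runif(62, 1.5, 2.5)
  pk <- data.frame(time = times, magnitude = mags)
  sel <- select_peaks_windowed(pk)
  worst <- max(vapply(sel$time, function(t)
    sum(sel$time >= t & sel$time < t + 0.960), numeric(1)))
  expect_lte(worst, 3)
  # counted peaks must be strictly more than 320 ms apart
  expect_true(all(diff(sel$time) > 0.320))
})

test_that("windowed selection matches the exhaustive window-enumeration oracle", {
  set.seed(7)
  for (trial in 1:60) {
    n <- sample(2:40, 1)
    times <- sort(runif(n, 0, 20))
    # keep candidates at least 15 ms apart (distinct local maxima)
    times <- times[c(TRUE, diff(times) > 0.015)]
    mags <- runif(length(times), 1.4, 3)
    pk <- data.frame(time = times, magnitude = mags)
    got <- select_peaks_windowed(pk)$time
    want <- times[brute_force_window_select(times, mags, t_end_s = 21)]
    expect_equal(got, want)
  }
})

test_that("bout aggregation drops short bouts and matches brute force", {
  # 4 steps 1 s apart: one bout of 4 < 5, all discarded
  expect_length(aggregate_bouts(c(0, 1, 2, 3)), 0)
  # 5 steps: boundary case is retained (5 is not less than 5)
  expect_equal(aggregate_bouts(c(0, 1, 2, 3, 4)), c(0, 1, 2, 3, 4))
  # two bouts split by a 196 s > 90 s gap, both retained
  t2 <- c(0:4, 200:204)
  expect_equal(aggregate_bouts(t2), t2)
  # randomized agreement with the brute-force partition
  set.seed(11)
  for (trial in 1:50) {
    times <- sort(runif(sample(1:60, 1), 0, 2000))
    expect_equal(aggregate_bouts(times), brute_force_bouts(times, 90, 5))
  }
  expect_error(aggregate_bouts(c(3, 1, 2)), "sorted")
})

test_that("planted walks are recovered as per-minute counts", {
  # 120 steps at 2 Hz in minute 4 (zero-based minute 3)
  tr <- simulate_accel_trace(step_times = 180 + (0:119) * 0.5,
                             peak_height = 2, duration = 300, seed = 2)
  ss <- count_steps_per_minute(tr)
  expect_equal(ss$counts, c(0, 0, 0, 120, 0))

  # noise only: all zero
  tr0 <- simulate_accel_trace(numeric(0), duration = 120, seed = 3)
  expect_equal(count_steps_per_minute(tr0)$counts, c(0, 0))

  # two 3-step clusters 200 s apart: bouts of 3 < 5 are discarded
  tr3 <- simulate_accel_trace(step_times = c(10, 11, 12, 210, 211, 212),
                              peak_height = 2, duration = 300, seed = 4)
  expect_equal(sum(count_steps_per_minute(tr3)$counts), 0)

  # sub-threshold peaks produce nothing downstream
  trs <- simulate_accel_trace(step_times = 60 + (0:9), peak_height = 1.0,
                              duration = 120, seed = 5)
  expect_equal(sum(count_steps_per_minute(trs)$counts), 0)
})

test_that("raising the threshold never increases the total counted steps", {
  tr <- simulate_accel_trace(step_times = sort(runif(80, 0, 290)),
                             peak_height = 2, duration = 300, seed = 6)
  totals <- vapply(c(1.3, 1.6, 1.9, 2.1), function(th)
    sum(count_steps_per_minute(tr, threshold = th)$counts), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("conservation: minute counts equal the retained-step set bucketed by minute", {
  set.seed(9)
  times <- sort(sample(seq(5, 595, by = 0.5), 150))
  tr <- simulate_accel_trace(times, peak_height = 2, duration = 600, seed = 10)
  ss <- count_steps_per_minute(tr)
  pk <- detect_candidate_peaks(tr)
  kept <- aggregate_bouts(select_peaks_windowed(pk)$time, 90, 5)
  expect_equal(sum(ss$counts), length(kept[kept < 600]))
  expect_equal(ss$counts, tabulate(floor(kept[kept < 600] / 60) + 1L, nbins = 10))
})
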