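mini_cfg <- function(n_bins = 40) {
  encoder_config(profile = "test", n_layers = 2, filters = 3,
                 pool_after = c(1, 2), pool_strides = c(4, 6),
                 minutes_per_day = 24, n_bins = n_bins)
}

# plain integer count vectors stand in for series in miniature-day tests
step_series_mini <- function(counts) as.integer(counts)

test_that("one-hot binning floors, clips and rejects negatives", {
  cfg <- encoder_config(profile = "test")
  expect_equal(as.integer(one_hot_encode(c(0L, 3L, 4L, 7L, 255L, 1000L), cfg)),
               c(0L, 0L, 1L, 1L, 63L, 63L))
  expect_equal(attr(one_hot_encode(0L, cfg), "n_bins"), 64L)
  expect_error(one_hot_encode(c(1L, -2L), cfg), "non-negative")
})

test_that("encoder configuration enforces the one-vector-per-day contract", {
  expect_equal(prod(encoder_config("full")$pool_strides), 1440)
  expect_equal(prod(encoder_config("test")$pool_strides), 1440)
  expect_error(encoder_config("test", pool_strides = c(6, 6, 5, 7)),
               "pool_strides")
})

test_that("encoder emits one feature vector per day with shared weights", {
  cfg <- mini_cfg()
  model <- baa_model_init(cfg, seed = 2)
  set.seed(3)
  counts <- sample(0:100, 24 * 9, replace = TRUE)
  f <- encode_days(step_series_mini(counts), model)
  expect_equal(dim(f), c(9, 4))
  expect_true(all(is.finite(f)))
  # translation: rotating the series by whole days permutes daily features
  # (interior days only: series-boundary days feel the zero padding)
  rot <- c(counts[(24 * 3 + 1):(24 * 9)], counts[1:(24 * 3)])
  f_rot <- encode_days(step_series_mini(rot), model)
  expect_equal(f_rot[2:5, ], f[5:8, ], tolerance = 1e-10)
  # all-zero input: identical features on interior days
  f0 <- encode_days(step_series_mini(rep(0L, 24 * 5)), model)
  expect_equal(f0[rep(2, 3), ], f0[2:4, ], tolerance = 1e-12)
  expect_error(encode_days(one_hot_encode(rep(0L, 30), cfg), model), "whole number")
})

test_that("the BAA head is a 7-day moving average with a sex offset", {
  set.seed(4)
  feats <- matrix(rnorm(12 * 4), 12, 4)
  head_par <- list(w = c(0.5, -1, 2, 0.1), ws = 1.7, b = -0.3)
  tr <- baa_head(feats, sex = 0, head_par)
  expect_equal(sum(tr$valid), 12 - 6)   # N-day series: N - 6 valid values
  expect_true(all(is.na(tr$baa[1:6])))
  # direct hand computation of day 7 and day 12
  for (d in c(7, 12)) {
    expect_equal(tr$baa[d],
                 sum(colMeans(feats[(d - 6):d, ]) * head_par$w) + head_par$b,
                 tolerance = 1e-12)
  }
  # flipping sex shifts every valid day by exactly ws
  tr1 <- baa_head(feats, sex = 1, head_par)
  expect_equal(tr1$baa[7:12] - tr$baa[7:12], rep(1.7, 6), tolerance = 1e-12)
  # constant features give a constant track
  trc <- baa_head(matrix(1, 10, 4), 0, head_par)
  expect_equal(diff(trc$baa[7:10]), rep(0, 3), tolerance = 1e-12)
  expect_error(baa_head(feats[1:6, ], 0, head_par), "7 days")
})

test_that("morbidity link is a calibrated monotone sigmoid of biological age", {
  morb <- list(logk = log(0.09), c = -0.09 * 65)
  # monotone in age at fixed BAA
  expect_lt(morbidity_probability(0, 50, morb), morbidity_probability(0, 70, morb))
  # midpoint: k (age + baa) + c = 0 at biological age 65
  expect_equal(morbidity_probability(0, 65, morb), 0.5, tolerance = 1e-12)
  expect_equal(morbidity_probability(10, 55, morb), 0.5, tolerance = 1e-12)
  # adding to BAA equals adding to age
  expect_equal(morbidity_probability(10, 60, morb),
               morbidity_probability(0, 70, morb), tolerance = 1e-12)
})

test_that("feature KL matches the Gaussian closed form and is symmetric", {
  set.seed(5)
  A <- matrix(rnorm(400), 100, 4)
  expect_equal(feature_kl_loss(A, A), 0, tolerance = 1e-12)
  # equal variances: symmetrised KL per feature is (mu1-mu2)^2 / sigma^2
  sd0 <- 2
  B <- sweep(A, 2, colMeans(A))   # exact zero means
  C <- sweep(B, 2, 1 / apply(B, 2, function(x) sqrt(mean(x^2))), `*`) * sd0
  D <- sweep(C, 2, c(1, -2, 0.5, 3), `+`)
  expect_equal(feature_kl_loss(C, D), sum(c(1, -2, 0.5, 3)^2) / sd0^2,
               tolerance = 1e-10)
  # symmetric in its arguments
  E <- matrix(rnorm(400, 1, 2), 100, 4)
  expect_equal(feature_kl_loss(A, E), feature_kl_loss(E, A), tolerance = 1e-12)
  expect_gt(feature_kl_loss(A, E), 0)
})

test_that("prediction composes the pipeline deterministically", {
  cfg <- mini_cfg()
  model <- baa_model_init(cfg, seed = 6)
  set.seed(7)
  counts <- sample(0:80, 24 * 10, replace = TRUE)
  s <- step_series_mini(counts)
  t1 <- predict_baa(s, sex = 1, model)
  t2 <- predict_baa(s, sex = 1, model)
  expect_identical(t1$baa, t2$baa)
  expect_equal(sum(t1$valid), 4)
  expect_error(predict_baa(step_series_mini(rep(0L, 24 * 6)), 0, model), "7")
})

test_that("nloga is the negative log of masked mean daily steps", {
  counts <- rep(0L, 1440 * 3)
  counts[seq(1, 1440 * 3, by = 2)] <- 10L   # 7200 steps/day
  s <- step_series(counts)
  expect_equal(nloga(s), -log(7200), tolerance = 1e-12)
  # halving all counts raises nloga by ln 2
  s_half <- step_series(counts %/% 2L)
  expect_equal(nloga(s_half) - nloga(s), log(2), tolerance = 1e-12)
  # a masked zero day does not change the mean
  counts_m <- c(counts, rep(0L, 1440))
  s_m <- step_series(counts_m, missing_mask = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(nloga(s_m), nloga(s), tolerance = 1e-12)
  # reference value: 10,000 steps/day
  cflat <- rep(0L, 1440); cflat[1:100] <- 100L
  expect_equal(nloga(step_series(cflat)), -log(10000), tolerance = 1e-12)
  expect_equal(round(-log(10000), 4), -9.2103)
  expect_error(nloga(step_series(rep(0L, 1440))), "zero")
})

test_that("analytic gradients agree with finite differences on a miniature net", {
  # wide bin alphabet avoids exact pooling ties (kinks of the max)
  cfg <- mini_cfg(n_bins = 40)
  model <- baa_model_init(cfg, seed = 8)
  set.seed(9)
  B <- 3
  bins <- matrix(sample(0:39, 24 * 7 * B, replace = TRUE), ncol = B)
  bins_b <- matrix(sample(0:39, 24 * 7 * 2, replace = TRUE), ncol = 2)
  age <- runif(B, 40, 80); sex <- rbinom(B, 1, 0.5); y <- rbinom(B, 1, 0.5)
  loss_fn <- function(pvec) {
    m <- model; m$params <- actiage:::nn_unflatten(pvec, model$params)
    cl <- actiage:::class_loss_pass(bins, age, sex, y, m)
    kl <- actiage:::kl_pair_pass(bins[, 1:2], bins_b, m)
    cl$loss + kl$loss
  }
  grad_fn <- function(pvec) {
    m <- model; m$params <- actiage:::nn_unflatten(pvec, model$params)
    cl <- actiage:::class_loss_pass(bins, age, sex, y, m)
    kl <- actiage:::kl_pair_pass(bins[, 1:2], bins_b, m)
    g <- cl$grads
    g$layers <- actiage:::nn_add(g$layers, kl$grads$layers)
    g$proj <- actiage:::nn_add(g$proj, kl$grads$proj)
    actiage:::nn_flatten(g)
  }
  p0 <- actiage:::nn_flatten(model$params)
  g <- grad_fn(p0)
  set.seed(10)
  idx <- sample(length(p0), 60)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    e <- p0; e[i] <- e[i] + h; f1 <- loss_fn(e)
    e[i] <- p0[i] - h; f0 <- loss_fn(e)
    (f1 - f0) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])), 1e-5)
})

test_that("Adam updates and parameter flattening round-trip", {
  cfg <- mini_cfg()
  model <- baa_model_init(cfg, seed = 11)
  p0 <- model$params
  vec <- actiage:::nn_flatten(p0)
  back <- actiage:::nn_unflatten(vec, p0)
  expect_equal(back, p0, tolerance = 0)
  st <- actiage:::adam_init(p0)
  g <- actiage:::nn_map(function(x) x * 0 + 1, p0)
  up <- actiage:::adam_step(p0, g, st, lr = 0.01)
  # first Adam step moves every parameter by ~lr against the gradient
  expect_equal(actiage:::nn_flatten(up$params), vec - 0.01, tolerance = 1e-6)
})
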