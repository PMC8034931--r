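#' Encoder configuration
#'
#' Describes the convolutional encoder that compresses minute-level step
#' counts into a few features per day. The default matches the reference
#' architecture: 16 one-dimensional convolutional layers of 16 filters
#' (kernel 3, elu activation, batch-normalised), every second layer followed
#' by local max-pooling with strides 2, 3 or 5 whose product is 1440, so the
#' block emits `features_per_day = 4` features per day of input; a 1x1
#' projection reduces the 16 channels to the 4 output features.
#'
#' The scaled-down profile (`profile = "test"`) keeps the same design at a
#' size suitable for continuous testing: 4 layers of 8 filters with pooling
#' after every layer (strides 6, 6, 5, 8 — the product must still be 1440).
#'
#' @param profile `"full"` (default) or `"test"`.
#' @param bin_width Steps/min per one-hot bin (default 4).
#' @param n_bins Number of bins; the top bin is open-ended (default 64).
#' @param n_layers,filters,kernel Convolution stack shape.
#' @param pool_after Layer indices followed by max-pooling.
#' @param pool_strides Pooling strides, one per pooled layer; their product
#'   must equal `minutes_per_day`.
#' @param features_per_day Output features per day (default 4).
#' @param minutes_per_day Minutes per day (1440; reducible for miniature
#'   shape tests only).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(profile = c("full", "test"),
                           bin_width = 4, n_bins = 64,
                           n_layers = NULL, filters = NULL, kernel = 3,
                           pool_after = NULL, pool_strides = NULL,
                           features_per_day = 4, minutes_per_day = 1440) {
  profile <- match.arg(profile)
  if (is.null(n_layers)) n_layers <- if (profile == "full") 16L else 4L
  if (is.null(filters)) filters <- if (profile == "full") 16L else 8L
  if (is.null(pool_after)) {
    pool_after <- if (profile == "full") seq(2L, 16L, by = 2L) else seq_len(4L)
  }
  if (is.null(pool_strides)) {
    pool_strides <- if (profile == "full") c(2, 2, 2, 2, 2, 3, 3, 5) else c(6, 6, 5, 8)
  }
  cfg <- list(profile = profile, bin_width = bin_width, n_bins = as.integer(n_bins),
              n_layers = as.integer(n_layers), filters = as.integer(filters),
              kernel = as.integer(kernel), pool_after = as.integer(pool_after),
              pool_strides = as.integer(pool_strides),
              features_per_day = as.integer(features_per_day),
              minutes_per_day = as.integer(minutes_per_day))
  stopifnot(length(cfg$pool_after) == length(cfg$pool_strides),
            all(cfg$pool_after <= cfg$n_layers),
            cfg$kernel %% 2 == 1, cfg$n_bins >= 2, cfg$bin_width >= 1)
  if (prod(cfg$pool_strides) != cfg$minutes_per_day) {
    stop("product of pool_strides (", prod(cfg$pool_strides),
         ") must equal minutes_per_day (", cfg$minutes_per_day,
         ") so the encoder emits one feature vector per day")
  }
  structure(cfg, class = "encoder_config")
}

#' Training configuration
#'
#' @param iterations Gradient iterations (default 2000; the test profile
#'   uses 200).
#' @param batch_size Samples per class-predictor batch (default 256; test
#'   profile 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param minor_domain_period The minor labelled domain contributes to the
#'   class loss once every this many iterations (default 5).
#' @param adaptation_weight Weight on the summed pairwise feature KL losses
#'   (default 1).
#' @param adapt_batch Samples per side of each adaptation pair.
#' @param head_lr_mult Learning-rate multiplier for the BAA head and the
#'   morbidity link (default 10). These few scalars sit atop a years-scale
#'   output whose gradients are damped by the logistic slope `k` (about
#'   0.09/yr), so they need larger steps than the convolution stack to
#'   reach their operating point.
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(iterations = 2000, batch_size = 256,
                         learning_rate = 1e-3, minor_domain_period = 5,
                         adaptation_weight = 1, adapt_batch = 32,
                         head_lr_mult = 10, seed = 1L) {
  cfg <- list(iterations = as.integer(iterations),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              minor_domain_period = as.integer(minor_domain_period),
              adaptation_weight = adaptation_weight,
              adapt_batch = as.integer(adapt_batch),
              head_lr_mult = head_lr_mult,
              seed = as.integer(seed))
  stopifnot(cfg$iterations > 0, cfg$batch_size > 0, cfg$learning_rate > 0,
            cfg$minor_domain_period > 0, cfg$adaptation_weight >= 0,
            cfg$adapt_batch > 1, cfg$head_lr_mult > 0)
  structure(cfg, class = "train_config")
}

#' One-hot bin encoding of a step series
#'
#' Maps each minute's step count `s` to bin `floor(s / bin_width)`, clipped
#' to `n_bins - 1` (the top bin is open-ended). Exactly one bin is active
#' per minute; the encoding is returned as 0-based bin indices (the dense
#' one-hot matrix is never materialised).
#'
#' @param series A `step_series` or non-negative integer vector.
#' @param config An [encoder_config()].
#' @return Integer vector of 0-based bin indices with attribute `n_bins`.
#' @export
one_hot_encode <- function(series, config = encoder_config()) {
  counts <- if (inherits(series, "step_series")) series$counts else series
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  bins <- pmin(counts %/% config$bin_width, config$n_bins - 1L)
  structure(as.integer(bins), n_bins = config$n_bins)
}

#' Initialise BAA model parameters
#'
#' He-style random initialisation for the convolution stack, unit batch-norm
#' scale, small random head weights, and a morbidity link initialised at the
#' Gompertz-like slope `k = 0.09/yr` centred at biological age 65 (both
#' trainable).
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return A `baa_model` list with `params`, `bn_state`, `config`.
#' @export
baa_model_init <- function(config = encoder_config(), seed = 1L) {
  set.seed(seed)
  K <- config$kernel
  C <- config$filters
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    if (l == 1L) {
      W <- lapply(seq_len(K), function(j)
        matrix(stats::rnorm(config$n_bins * C, 0, sqrt(2 / K)), config$n_bins, C))
    } else {
      W <- lapply(seq_len(K), function(j)
        matrix(stats::rnorm(C * C, 0, sqrt(2 / (K * C))), C, C))
    }
    layers[[l]] <- list(W = W, b = numeric(C),
                        gamma = rep(1, C), beta = numeric(C))
  }
  params <- list(
    layers = layers,
    proj = list(P = matrix(stats::rnorm(C * config$features_per_day, 0,
                                        sqrt(1 / C)), C, config$features_per_day),
                b = numeric(config$features_per_day)),
    head = list(w = stats::rnorm(config$features_per_day, 0, 0.3),
                ws = 0, b = 0),
    morb = list(logk = log(0.09), c = -0.09 * 65)
  )
  bn_state <- lapply(seq_len(config$n_layers), function(l)
    list(mean = numeric(C), var = rep(1, C)))
  structure(list(params = params, bn_state = bn_state, config = config),
            class = "baa_model")
}

# forward through the convolution stack + projection; bins is an integer
# matrix (L x B) of 0-based bin indices, L a multiple of minutes_per_day
encoder_forward <- function(bins_mat, model, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- nrow(bins_mat); B <- ncol(bins_mat)
  if (L %% cfg$minutes_per_day != 0) {
    stop("input length must be a whole number of days (multiple of ",
         cfg$minutes_per_day, " minutes)")
  }
  bins <- as.integer(bins_mat)           # column-major == sample-major rows
  cache <- if (keep_cache) list(bins = bins, L0 = L, B = B) else NULL
  caches <- vector("list", cfg$n_layers)
  A <- NULL
  pool_of <- integer(cfg$n_layers)
  pool_of[cfg$pool_after] <- seq_along(cfg$pool_after)
  for (l in seq_len(cfg$n_layers)) {
    lay <- p$layers[[l]]
    if (l == 1L) {
      cv <- embed_conv_forward(bins, lay$W, lay$b, L, B)
      Z <- cv$Z; conv_cache <- cv$cache
    } else {
      cv <- conv_forward(A, lay$W, lay$b, L, B)
      Z <- cv$Z; conv_cache <- cv$idxs
    }
    bn <- bn_forward(Z, lay$gamma, lay$beta, model$bn_state[[l]], train = train)
    model$bn_state[[l]] <- bn$state
    Y <- elu_forward(bn$Y)
    lay_cache <- list(A_in = if (l > 1L) A else NULL, conv = conv_cache,
                      xhat = bn$xhat, invstd = bn$invstd, Y = Y,
                      L = L, B = B)
    if (pool_of[l] > 0L) {
      s <- cfg$pool_strides[pool_of[l]]
      pl <- pool_forward(Y, s, L, B)
      lay_cache$pool_arg <- pl$arg
      lay_cache$n_pre_pool <- L * B
      A <- pl$Y
      L <- pl$Lp
    } else {
      A <- Y
    }
    caches[[l]] <- lay_cache
  }
  Fday <- A %*% p$proj$P + matrix(p$proj$b, nrow(A), cfg$features_per_day,
                                  byrow = TRUE)
  if (keep_cache) {
    cache$layers <- caches
    cache$A_final <- A
  }
  list(Fday = Fday, n_days = L, B = B, model = model, cache = cache)
}

encoder_backward <- function(dFday, fwd, model) {
  cfg <- model$config
  p <- model$params
  cache <- fwd$cache
  grads <- nn_zeros_like(p)
  grads$proj$P <- crossprod(cache$A_final, dFday)
  grads$proj$b <- colSums(dFday)
  dA <- dFday %*% t(p$proj$P)
  pool_of <- integer(cfg$n_layers)
  pool_of[cfg$pool_after] <- seq_along(cfg$pool_after)
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    if (pool_of[l] > 0L) {
      dY <- pool_backward(dA, lc$pool_arg, lc$n_pre_pool)
    } else {
      dY <- dA
    }
    dZbn <- elu_backward(dY, lc$Y)
    bnb <- bn_backward(dZbn, lc$xhat, lc$invstd, p$layers[[l]]$gamma)
    grads$layers[[l]]$gamma <- bnb$dgamma
    grads$layers[[l]]$beta <- bnb$dbeta
    dZ <- bnb$dX
    if (l == 1L) {
      eb <- embed_conv_backward(dZ, cache$bins, p$layers[[l]]$W, lc$conv)
      grads$layers[[l]]$W <- eb$dW
      grads$layers[[l]]$b <- eb$db
      dA <- NULL
    } else {
      cb <- conv_backward(dZ, lc$A_in, p$layers[[l]]$W, lc$conv, lc$L, lc$B)
      grads$layers[[l]]$W <- cb$dW
      grads$layers[[l]]$b <- cb$db
      dA <- cb$dA
    }
  }
  grads
}

#' Encode a step series into daily feature vectors
#'
#' Runs the convolutional encoder in inference mode (batch-norm running
#' statistics) over a whole-day step series and returns one
#' `features_per_day`-vector per day.
#'
#' @param series A `step_series`, integer count vector (length a multiple of
#'   `minutes_per_day`), or a pre-encoded bin vector from
#'   [one_hot_encode()].
#' @param model A `baa_model`.
#' @return Numeric matrix, `n_days` rows by `features_per_day` columns.
#' @export
encode_days <- function(series, model) {
  bins <- if (is.integer(series) && !is.null(attr(series, "n_bins"))) {
    series
  } else {
    one_hot_encode(series, model$config)
  }
  fwd <- encoder_forward(matrix(bins, ncol = 1), model, train = FALSE)
  fwd$Fday
}

#' Linear BAA head over 7-day averaged features
#'
#' `BAA(d) = w . mean(features[d-6 .. d]) + w_s * sex + b`, in years. The
#' first six days carry no complete trailing week and are flagged invalid.
#'
#' @param daily_features Matrix (days x features).
#' @param sex Binary sex label (0/1).
#' @param head List with `w`, `ws`, `b` (as in `model$params$head`).
#' @param subject_id Optional identifier for the returned track.
#' @return A `baa_track`.
#' @export
baa_head <- function(daily_features, sex, head, subject_id = NA_character_) {
  nd <- nrow(daily_features)
  if (nd < 7) stop("need at least 7 days of features, got ", nd)
  cs <- rbind(0, apply(daily_features, 2, cumsum))
  wmean <- (cs[8:(nd + 1), , drop = FALSE] - cs[1:(nd - 6), , drop = FALSE]) / 7
  baa <- rep(NA_real_, nd)
  baa[7:nd] <- as.numeric(wmean %*% head$w) + head$ws * sex + head$b
  valid <- c(rep(FALSE, 6), rep(TRUE, nd - 6))
  baa[!valid] <- NA_real_
  baa_track(baa, valid, subject_id = subject_id)
}

#' Morbidity probability from BAA and chronological age
#'
#' Biological age is chronological age plus BAA; the morbidity probability
#' is `sigmoid(k * (age + baa) + c)` with trainable slope `k > 0`
#' (parameterised as `exp(logk)`) and offset `c` — the logistic
#' approximation to a proportional-hazards fit.
#'
#' @param baa BAA in years.
#' @param chron_age Chronological age in years.
#' @param morb List with `logk` and `c` (as in `model$params$morb`).
#' @return Probability in (0, 1), monotone increasing in both arguments.
#' @export
morbidity_probability <- function(baa, chron_age, morb) {
  stats::plogis(exp(morb$logk) * (chron_age + baa) + morb$c)
}

#' Symmetrised Gaussian feature KL divergence
#'
#' Fits a univariate Gaussian to each feature of each batch and sums the
#' symmetrised Kullback-Leibler divergences over features:
#' `KL(P||Q) + KL(Q||P)` with
#' `KL(N(m1,v1) || N(m2,v2)) = log(s2/s1) + (v1 + (m1-m2)^2)/(2 v2) - 1/2`.
#' Zero iff means and variances match per feature. Variances are floored at
#' `eps` to keep the loss finite on degenerate batches.
#'
#' @param features_a,features_b Matrices (samples x features), each with at
#'   least 2 rows.
#' @param eps Variance floor.
#' @return Non-negative scalar.
#' @export
feature_kl_loss <- function(features_a, features_b, eps = 1e-6) {
  stopifnot(nrow(features_a) >= 2, nrow(features_b) >= 2,
            ncol(features_a) == ncol(features_b))
  feature_kl_impl(features_a, features_b, eps)$loss
}

# loss + gradients wrt both feature matrices (biased variance)
feature_kl_impl <- function(A, B, eps = 1e-6) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA_raw <- colMeans(sweep(A, 2, mA)^2)
  vB_raw <- colMeans(sweep(B, 2, mB)^2)
  vA <- pmax(vA_raw, eps); vB <- pmax(vB_raw, eps)
  d <- mA - mB
  loss <- sum((vA + d^2) / (2 * vB) + (vB + d^2) / (2 * vA) - 1)
  dmA <- d * (1 / vA + 1 / vB)
  dvA <- 1 / (2 * vB) - (vB + d^2) / (2 * vA^2)
  dvB <- 1 / (2 * vA) - (vA + d^2) / (2 * vB^2)
  dvA[vA_raw < eps] <- 0
  dvB[vB_raw < eps] <- 0
  dA <- sweep(matrix(1, nA, length(mA)), 2, dmA / nA, `*`) +
    sweep(sweep(A, 2, mA), 2, 2 * dvA / nA, `*`)
  dB <- sweep(matrix(1, nB, length(mB)), 2, -dmA / nB, `*`) +
    sweep(sweep(B, 2, mB), 2, 2 * dvB / nB, `*`)
  list(loss = loss, dA = dA, dB = dB)
}

#' Predict a daily BAA track for a step series
#'
#' Composition of [one_hot_encode()], [encode_days()] and [baa_head()]:
#' BAA on day `d` uses the step counts of days `d-6` through `d`.
#' Zero-imputed missing days are fed to the network as-is (it is trained to
#' be robust to them).
#'
#' @param series A `step_series` of at least 7 whole days.
#' @param sex Binary sex label.
#' @param model A trained `baa_model`.
#' @return A `baa_track` with the first 6 days invalid.
#' @export
predict_baa <- function(series, sex, model) {
  counts <- if (inherits(series, "step_series")) series$counts else series
  if (length(counts) %/% model$config$minutes_per_day < 7) {
    stop("need at least 7 whole days of data")
  }
  feats <- encode_days(series, model)
  sid <- if (inherits(series, "step_series")) series$subject_id else NA_character_
  baa_head(feats, sex, model$params$head, subject_id = sid)
}

#' Negative log mean daily steps (nloga)
#'
#' The baseline activity-derived risk proxy: `-ln(mean steps per day)`,
#' the mean taken over non-missing days only.
#'
#' @param series A `step_series`.
#' @return Dimensionless score (higher = less active).
#' @export
nloga <- function(series) {
  nd <- n_days(series)
  if (nd < 1) stop("series shorter than one day")
  mask <- series$missing_mask
  keep <- which(!mask)
  if (length(keep) == 0) stop("all days are missing")
  daily <- vapply(keep, function(d)
    sum(series$counts[((d - 1L) * 1440L + 1L):(d * 1440L)]), numeric(1))
  m <- mean(daily)
  if (m <= 0) stop("mean daily steps is zero; nloga undefined")
  -log(m)
}
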