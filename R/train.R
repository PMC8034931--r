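# Training of the BAA network: morbidity cross-entropy on labelled domains
# plus Kullback-Leibler distribution-alignment losses across device, season
# and missing-data domains.

# per-sample pooled features for a batch of week-long samples:
# Fday has (n_days * B) rows sample-major; pooled = per-sample mean
pool_sample_features <- function(Fday, n_days, B) {
  rowsum(Fday, group = rep(seq_len(B), each = n_days)) / n_days
}

# forward + gradients of the morbidity cross-entropy on a batch of 7-day
# samples; returns loss, grads (full param tree), updated model (BN state)
class_loss_pass <- function(bins_mat, age, sex, y, model, weight = 1) {
  B <- ncol(bins_mat)
  nd <- nrow(bins_mat) / model$config$minutes_per_day
  fwd <- encoder_forward(bins_mat, model, train = TRUE, keep_cache = TRUE)
  model <- fwd$model
  p <- model$params
  Fmean <- pool_sample_features(fwd$Fday, nd, B)
  baa <- as.numeric(Fmean %*% p$head$w) + p$head$ws * sex + p$head$b
  k <- exp(p$morb$logk)
  z <- k * (age + baa) + p$morb$c
  prob <- stats::plogis(z)
  eps <- 1e-12
  loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  dz <- weight * (prob - y) / B
  grads <- nn_zeros_like(p)
  grads$morb$logk <- sum(dz * (age + baa)) * k
  grads$morb$c <- sum(dz)
  dbaa <- dz * k
  grads$head$w <- as.numeric(crossprod(Fmean, dbaa))
  grads$head$ws <- sum(dbaa * sex)
  grads$head$b <- sum(dbaa)
  dFmean <- outer(dbaa, p$head$w)
  dFday <- dFmean[rep(seq_len(B), each = nd), , drop = FALSE] / nd
  enc_grads <- encoder_backward(dFday, fwd, model)
  grads$layers <- nn_add(grads$layers, enc_grads$layers)
  grads$proj <- nn_add(grads$proj, enc_grads$proj)
  list(loss = loss, grads = grads, model = model, baa = baa, prob = prob)
}

# forward + gradients of one KL adaptation pair; the two sides are run as a
# single concatenated batch so batch-norm statistics are shared
kl_pair_pass <- function(bins_a, bins_b, model, weight = 1) {
  m <- ncol(bins_a); n <- ncol(bins_b)
  bins <- cbind(bins_a, bins_b)
  nd <- nrow(bins) / model$config$minutes_per_day
  fwd <- encoder_forward(bins, model, train = TRUE, keep_cache = TRUE)
  model <- fwd$model
  Fmean <- pool_sample_features(fwd$Fday, nd, m + n)
  kl <- feature_kl_impl(Fmean[seq_len(m), , drop = FALSE],
                        Fmean[m + seq_len(n), , drop = FALSE])
  dFmean <- rbind(kl$dA, kl$dB) * weight
  dFday <- dFmean[rep(seq_len(m + n), each = nd), , drop = FALSE] / nd
  enc_grads <- encoder_backward(dFday, fwd, model)
  list(loss = kl$loss, grads = enc_grads, model = model)
}

# KL between two domains' pooled features in inference mode (no training)
domain_feature_kl <- function(bins_a, bins_b, model) {
  nd_a <- nrow(bins_a) / model$config$minutes_per_day
  nd_b <- nrow(bins_b) / model$config$minutes_per_day
  Fa <- pool_sample_features(encoder_forward(bins_a, model)$Fday, nd_a, ncol(bins_a))
  Fb <- pool_sample_features(encoder_forward(bins_b, model)$Fday, nd_b, ncol(bins_b))
  feature_kl_loss(Fa, Fb)
}

sample_cols <- function(ids, k) {
  if (length(ids) == 0) return(integer(0))
  ids[sample.int(length(ids), k, replace = length(ids) < k)]
}

# zero-impute 1-3 random whole days of each column of a bin matrix
zero_impute_days <- function(bins_mat, minutes_per_day) {
  nd <- nrow(bins_mat) / minutes_per_day
  for (b in seq_len(ncol(bins_mat))) {
    k <- sample.int(3L, 1L)
    for (d in sample.int(nd, min(k, nd - 1L))) {
      bins_mat[((d - 1L) * minutes_per_day + 1L):(d * minutes_per_day), b] <- 0L
    }
  }
  bins_mat
}

#' Train the BAA network
#'
#' Minimises morbidity cross-entropy on the labelled domains plus
#' `adaptation_weight` times the summed pairwise feature KL losses. The
#' major labelled domain (`wrist_research`) contributes to the class loss
#' every iteration; the minor one (`hip_research`) once every
#' `minor_domain_period` iterations. Four adaptation pairs are aligned every
#' iteration: wrist vs hip devices, phone vs watch devices, summer vs winter
#' samples, and clean samples vs copies with 1-3 days zero-imputed.
#'
#' @param subjects Cohort data.frame (columns `id`, `age`, `sex`, `morbid`,
#'   `device`, `season`).
#' @param series_list Named list of `step_series` (>= 7 days each), names
#'   matching `subjects$id`. The first 7 days of each series form its
#'   training sample.
#' @param model A `baa_model` from [baa_model_init()].
#' @param tcfg A [train_config()].
#' @param verbose Print progress every 50 iterations.
#' @return The trained `baa_model`, with a `training_log` data.frame
#'   (per-iteration losses) and `kl_initial` attached.
#' @export
train_baa_model <- function(subjects, series_list, model,
                            tcfg = train_config(), verbose = FALSE) {
  stopifnot(all(subjects$id %in% names(series_list)))
  cfg <- model$config
  mpd <- cfg$minutes_per_day
  set.seed(tcfg$seed)
  week <- 7L * mpd
  bins_all <- vapply(subjects$id, function(id) {
    s <- series_list[[id]]
    as.integer(one_hot_encode(s, cfg))[seq_len(week)]
  }, integer(week))
  age <- subjects$age
  sex <- subjects$sex
  y <- as.numeric(subjects$morbid)
  dom <- list(
    major = which(subjects$device == "wrist_research"),
    minor = which(subjects$device == "hip_research"),
    phone = which(subjects$device == "phone"),
    watch = which(subjects$device == "watch"),
    summer = which(subjects$season == "summer"),
    winter = which(subjects$season == "winter")
  )
  if (length(dom$major) == 0) stop("major labelled domain (wrist_research) is empty")
  use_minor <- length(dom$minor) >= 2
  use_devpair <- length(dom$phone) >= 2 && length(dom$watch) >= 2
  use_season <- length(dom$summer) >= 2 && length(dom$winter) >= 2
  adam <- adam_init(model$params)
  log_rows <- vector("list", tcfg$iterations)
  kl_initial <- if (use_devpair) {
    domain_feature_kl(bins_all[, sample_cols(dom$phone, tcfg$adapt_batch), drop = FALSE],
                      bins_all[, sample_cols(dom$watch, tcfg$adapt_batch), drop = FALSE],
                      model)
  } else {
    NA_real_
  }
  for (it in seq_len(tcfg$iterations)) {
    grads <- nn_zeros_like(model$params)
    idx <- sample_cols(dom$major, tcfg$batch_size)
    cl <- class_loss_pass(bins_all[, idx, drop = FALSE],
                          age[idx], sex[idx], y[idx], model)
    model <- cl$model
    grads <- nn_add(grads, cl$grads)
    minor_loss <- NA_real_
    if (use_minor && it %% tcfg$minor_domain_period == 0L) {
      idx2 <- sample_cols(dom$minor, tcfg$batch_size)
      cl2 <- class_loss_pass(bins_all[, idx2, drop = FALSE],
                             age[idx2], sex[idx2], y[idx2], model)
      model <- cl2$model
      grads <- nn_add(grads, cl2$grads)
      minor_loss <- cl2$loss
    }
    w <- tcfg$adaptation_weight
    kl_losses <- c(device = NA_real_, research = NA_real_,
                   season = NA_real_, missing = NA_real_)
    if (w > 0) {
      run_pair <- function(ia, ib) {
        pp <- kl_pair_pass(bins_all[, ia, drop = FALSE],
                           bins_all[, ib, drop = FALSE], model, weight = w)
        model <<- pp$model
        grads$layers <<- nn_add(grads$layers, pp$grads$layers)
        grads$proj <<- nn_add(grads$proj, pp$grads$proj)
        pp$loss
      }
      m <- tcfg$adapt_batch
      if (use_devpair) {
        kl_losses["device"] <- run_pair(sample_cols(dom$phone, m),
                                        sample_cols(dom$watch, m))
      }
      if (use_minor) {
        kl_losses["research"] <- run_pair(sample_cols(dom$major, m),
                                          sample_cols(dom$minor, m))
      }
      if (use_season) {
        kl_losses["season"] <- run_pair(sample_cols(dom$summer, m),
                                        sample_cols(dom$winter, m))
      }
      # missing-day pair: clean samples vs the same samples with days zeroed
      ic <- sample_cols(dom$major, m)
      clean <- bins_all[, ic, drop = FALSE]
      zeroed <- zero_impute_days(clean, mpd)
      pp <- kl_pair_pass(clean, zeroed, model, weight = w)
      model <- pp$model
      grads$layers <- nn_add(grads$layers, pp$grads$layers)
      grads$proj <- nn_add(grads$proj, pp$grads$proj)
      kl_losses["missing"] <- pp$loss
    }
    total <- cl$loss + sum(kl_losses, na.rm = TRUE) * w
    if (!is.finite(total)) {
      stop("training diverged at iteration ", it, " (loss = ", total,
           "); reduce the learning rate or adaptation weight")
    }
    st <- adam_step(model$params, grads, adam, lr = tcfg$learning_rate)
    adam <- st$state
    new_params <- st$params
    if (tcfg$head_lr_mult != 1) {
      # amplify the head/link step: re-apply the same Adam direction scaled
      for (part in c("head", "morb")) {
        new_params[[part]] <- nn_map2(
          function(new, old) old + tcfg$head_lr_mult * (new - old),
          st$params[[part]], model$params[[part]])
      }
    }
    model$params <- new_params
    log_rows[[it]] <- data.frame(
      iteration = it, class_loss = cl$loss, minor_loss = minor_loss,
      kl_device = kl_losses["device"], kl_research = kl_losses["research"],
      kl_season = kl_losses["season"], kl_missing = kl_losses["missing"],
      row.names = NULL)
    if (verbose && it %% 50L == 0L) {
      message(sprintf("iter %d: class %.4f, KL device %.3f", it, cl$loss,
                      kl_losses["device"]))
    }
  }
  model$training_log <- do.call(rbind, log_rows)
  model$kl_initial <- kl_initial
  model$train_config <- tcfg
  model
}

#' Predict BAA and morbidity probability for a cohort of weekly samples
#'
#' Runs the trained model over each subject's first 7 days and returns one
#' BAA value (the day-7 prediction) and one morbidity probability per
#' subject.
#'
#' @inheritParams train_baa_model
#' @return Data.frame: `id`, `baa` (years), `p_morbid`.
#' @export
predict_cohort <- function(subjects, series_list, model) {
  baa <- vapply(seq_len(nrow(subjects)), function(i) {
    s <- series_list[[subjects$id[i]]]
    tr <- predict_baa(s, subjects$sex[i], model)
    tr$baa[7]
  }, numeric(1))
  data.frame(id = subjects$id, baa = baa,
             p_morbid = morbidity_probability(baa, subjects$age,
                                              model$params$morb))
}
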