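# Minimal 1-D convolutional network machinery with hand-derived backprop.
#
# Activations are stored as matrices of (time * batch) rows by channel
# columns, sample-major: row r corresponds to time t = ((r-1) mod L) + 1 of
# sample b = floor((r-1)/L) + 1. Convolutions use zero ("same") padding so
# per-sample lengths are preserved; pooling divides lengths exactly.
# Channel counts are small, so per-channel column loops beat sweep()/aperm().

# row-shift within samples: rows move by `off` time steps, zero-filled at
# per-sample boundaries; returns the source-row index vector (0 = zero row)
shift_index <- function(L, B, off) {
  r <- seq_len(L * B)
  tpos <- ((r - 1L) %% L) + 1L
  ok <- tpos + off >= 1L & tpos + off <= L
  idx <- integer(L * B)
  idx[ok] <- r[ok] + off
  idx
}

shift_rows <- function(A, idx) {
  out <- matrix(0, nrow(A), ncol(A))
  ok <- idx > 0L
  out[ok, ] <- A[idx[ok], , drop = FALSE]
  out
}

add_bias <- function(Z, b) {
  for (c in seq_along(b)) Z[, c] <- Z[, c] + b[c]
  Z
}

# --- embedding convolution (first layer over one-hot step bins) ----------
# With a one-hot input, convolution reduces to a table lookup: the output at
# time t is the sum over kernel offsets of the weight row selected by the
# active bin at t + off.
embed_conv_forward <- function(bins, W, b, L, B) {
  C <- ncol(W[[1]])
  N <- L * B
  Z <- matrix(0, N, C)
  cache_idx <- vector("list", length(W))
  offs <- seq_along(W) - (length(W) + 1L) %/% 2L   # e.g. -1, 0, 1
  for (j in seq_along(W)) {
    idx <- shift_index(L, B, offs[j])
    ok <- idx > 0L
    sel <- integer(N)                 # row of padded weight table; 1 = zeros
    sel[ok] <- bins[idx[ok]] + 2L
    sel[!ok] <- 1L
    Z <- Z + rbind(0, W[[j]])[sel, , drop = FALSE]
    cache_idx[[j]] <- list(idx = idx, ok = ok)
  }
  list(Z = add_bias(Z, b), cache = cache_idx)
}

embed_conv_backward <- function(dZ, bins, W, cache) {
  dW <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  for (j in seq_along(W)) {
    ok <- cache[[j]]$ok
    grp <- bins[cache[[j]]$idx[ok]] + 1L     # 1-based bin
    acc <- rowsum(dZ[ok, , drop = FALSE], group = grp)
    rows <- as.integer(rownames(acc))
    dW[[j]][rows, ] <- dW[[j]][rows, ] + acc
  }
  list(dW = dW, db = colSums(dZ))
}

# --- dense 1-D convolution ----------------------------------------------
conv_forward <- function(A, W, b, L, B) {
  offs <- seq_along(W) - (length(W) + 1L) %/% 2L
  Z <- matrix(0, L * B, ncol(W[[1]]))
  idxs <- lapply(offs, function(off) shift_index(L, B, off))
  for (j in seq_along(W)) {
    Z <- Z + shift_rows(A, idxs[[j]]) %*% W[[j]]
  }
  list(Z = add_bias(Z, b), idxs = idxs)
}

conv_backward <- function(dZ, A, W, idxs, L, B) {
  dA <- matrix(0, nrow(A), ncol(A))
  dW <- vector("list", length(W))
  for (j in seq_along(W)) {
    Ash <- shift_rows(A, idxs[[j]])
    dW[[j]] <- crossprod(Ash, dZ)
    # scatter dZ %*% t(W) back through the shift: reverse mapping
    contrib <- dZ %*% t(W[[j]])
    idx <- idxs[[j]]
    ok <- idx > 0L
    dA[idx[ok], ] <- dA[idx[ok], ] + contrib[ok, , drop = FALSE]
  }
  list(dA = dA, dW = dW, db = colSums(dZ))
}

# --- batch normalisation -------------------------------------------------
bn_forward <- function(X, gamma, beta, state, train = TRUE,
                       momentum = 0.9, eps = 1e-5) {
  C <- ncol(X)
  if (train) {
    mu <- colMeans(X)
    v <- numeric(C)
    xhat <- X
    for (c in seq_len(C)) {
      xc <- X[, c] - mu[c]
      v[c] <- mean(xc * xc)
      xhat[, c] <- xc
    }
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xhat <- X
    for (c in seq_len(C)) xhat[, c] <- X[, c] - mu[c]
  }
  invstd <- 1 / sqrt(v + eps)
  Y <- xhat
  for (c in seq_len(C)) {
    xhat[, c] <- xhat[, c] * invstd[c]
    Y[, c] <- xhat[, c] * gamma[c] + beta[c]
  }
  list(Y = Y, xhat = xhat, invstd = invstd, state = state)
}

bn_backward <- function(dY, xhat, invstd, gamma) {
  N <- nrow(dY)
  C <- ncol(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dX <- dY
  # standard batch-norm backward (batch statistics), per channel
  for (c in seq_len(C)) {
    dxh <- dY[, c] * gamma[c]
    dX[, c] <- (dxh - mean(dxh) - xhat[, c] * mean(dxh * xhat[, c])) * invstd[c]
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- elu -----------------------------------------------------------------
elu_forward <- function(X) {
  i <- which(X < 0)
  X[i] <- expm1(X[i])
  X
}

elu_backward <- function(dY, Y) {
  i <- which(Y < 0)
  dY[i] <- dY[i] * (Y[i] + 1)
  dY
}

# --- non-overlapping max pooling over time ------------------------------
pool_forward <- function(A, stride, L, B) {
  Lp <- L %/% stride
  N <- Lp * B
  rows1 <- seq(1L, L * B, by = stride)
  Y <- A[rows1, , drop = FALSE]
  arg <- matrix(rep(rows1, ncol(A)), N, ncol(A))
  for (j in 2:stride) {
    rows <- rows1 + (j - 1L)
    Aj <- A[rows, , drop = FALSE]
    upd <- Aj > Y                      # strict: ties keep the earlier sample
    if (any(upd)) {
      Y[upd] <- Aj[upd]
      arg[upd] <- matrix(rep(rows, ncol(A)), N, ncol(A))[upd]
    }
  }
  list(Y = Y, arg = arg, Lp = Lp)
}

pool_backward <- function(dY, arg, n_in) {
  dA <- matrix(0, n_in, ncol(dY))
  for (c in seq_len(ncol(dY))) {
    dA[arg[, c], c] <- dY[, c]
  }
  dA
}

# --- parameter-tree helpers ---------------------------------------------
nn_map <- function(f, p) {
  if (is.list(p)) lapply(p, function(x) nn_map(f, x)) else f(p)
}

nn_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nn_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

nn_zeros_like <- function(p) nn_map(function(x) x * 0, p)

nn_add <- function(a, b) nn_map2(`+`, a, b)

nn_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, nn_flatten), use.names = FALSE) else as.numeric(p)
}

nn_unflatten <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) {
      lapply(p, fill)
    } else {
      n <- length(p)
      out <- p
      out[] <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      out
    }
  }
  fill(skeleton)
}

# --- Adam ---------------------------------------------------------------
adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nn_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                 state$m, state$v)
  params <- nn_map2(`-`, params, upd)
  list(params = params, state = state)
}
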