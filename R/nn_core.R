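# Minimal neural-network engine: fully-connected frontend + two-layer LSTM
# (or 1D temporal convolution) with masked-MSE loss, analytic backprop and
# Adam. Vectorised over the batch; single-threaded and deterministic under
# set.seed. Correctness of every backward pass is pinned by finite-difference
# gradient checks in the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# uniform Glorot-style init in [-r, r]
init_mat <- function(nr, nc, r = sqrt(6 / (nr + nc))) {
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# ---- parameter initialisation --------------------------------------------

# arch: list(kind = "lstm"|"cnn1d", d_in, frontend_widths, hidden, n_layers,
#            kernel_width, n_filters, n_out)
nn_init <- function(arch) {
  p <- list()
  if (arch$kind == "lstm") {
    d <- arch$d_in
    p$front <- lapply(arch$frontend_widths, function(w) {
      layer <- list(W = init_mat(d, w), b = rep(0, w))
      d <<- w
      layer
    })
    p$lstm <- vector("list", arch$n_layers)
    din <- d
    for (l in seq_len(arch$n_layers)) {
      h <- arch$hidden
      p$lstm[[l]] <- list(
        Wx = init_mat(din, 4 * h, r = 1 / sqrt(din)),
        Wh = init_mat(h, 4 * h, r = 1 / sqrt(h)),
        b = rep(c(0, 1, 0, 0), each = h)  # forget-gate bias 1
      )
      din <- h
    }
    p$out <- list(W = init_mat(din, arch$n_out), b = rep(0, arch$n_out))
  } else if (arch$kind == "cnn1d") {
    k <- arch$kernel_width
    f <- arch$n_filters
    p$conv <- list(W = lapply(seq_len(k), function(j) init_mat(arch$d_in, f)),
                   b = rep(0, f))
    p$out <- list(W = init_mat(f, arch$n_out), b = rep(0, arch$n_out))
  } else {
    stop("unknown architecture kind: ", arch$kind)
  }
  p
}

# ---- forward --------------------------------------------------------------

# X: array n x T x D. Returns list(yhat, cache).
nn_forward <- function(params, arch, X, keep_cache = FALSE) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; D <- dim(X)[3]
  cache <- list()
  if (arch$kind == "lstm") {
    A <- matrix(X, n * Tn, D)  # rows: sample-major within each step
    front_cache <- list()
    for (l in seq_along(params$front)) {
      Z <- add_bias(A %*% params$front[[l]]$W, params$front[[l]]$b)
      if (keep_cache) front_cache[[l]] <- list(A_in = A, Z = Z)
      A <- pmax(Z, 0)
    }
    H <- array(A, c(n, Tn, ncol(A)))
    lstm_cache <- vector("list", length(params$lstm))
    for (l in seq_along(params$lstm)) {
      res <- lstm_layer_forward(params$lstm[[l]], H, keep_cache)
      H <- res$H
      lstm_cache[[l]] <- res$cache
    }
    hT <- matrix(H[, Tn, ], n)
    yhat <- add_bias(hT %*% params$out$W, params$out$b)
    if (keep_cache) {
      cache <- list(front = front_cache, lstm = lstm_cache, hT = hT,
                    n = n, Tn = Tn, D = D)
    }
  } else {
    k <- length(params$conv$W)
    if (Tn < k) stop("sequence shorter than convolution kernel")
    P <- Tn - k + 1
    f <- length(params$conv$b)
    S <- array(0, c(n, P, f))
    Xs <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], n))
    for (p in seq_len(P)) {
      Z <- matrix(params$conv$b, n, f, byrow = TRUE)
      for (j in seq_len(k)) Z <- Z + Xs[[p + j - 1]] %*% params$conv$W[[j]]
      S[, p, ] <- Z
    }
    Hc <- pmax(S, 0)
    pooled <- matrix(apply(Hc, c(1, 3), mean), n, f)
    yhat <- add_bias(pooled %*% params$out$W, params$out$b)
    if (keep_cache) cache <- list(Xs = Xs, S = S, P = P, n = n, Tn = Tn)
  }
  list(yhat = yhat, cache = cache)
}

lstm_layer_forward <- function(lp, H_in, keep_cache) {
  n <- dim(H_in)[1]; Tn <- dim(H_in)[2]
  h_sz <- nrow(lp$Wh)
  h <- matrix(0, n, h_sz); cc <- matrix(0, n, h_sz)
  H <- array(0, c(n, Tn, h_sz))
  steps <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    x <- matrix(H_in[, t, ], n)
    z <- add_bias(x %*% lp$Wx + h %*% lp$Wh, lp$b)
    i <- sigm(z[, 1:h_sz, drop = FALSE])
    f <- sigm(z[, h_sz + 1:h_sz, drop = FALSE])
    g <- tanh(z[, 2 * h_sz + 1:h_sz, drop = FALSE])
    o <- sigm(z[, 3 * h_sz + 1:h_sz, drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    H[, t, ] <- h
    if (keep_cache) {
      steps[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, cc = cc, tc = tc)
    }
  }
  list(H = H, cache = list(steps = steps, h_sz = h_sz))
}

# ---- backward -------------------------------------------------------------

# dyhat: n x n_out gradient of the loss wrt the output. Returns gradients in
# the same nested shape as params.
nn_backward <- function(params, arch, cache, dyhat) {
  g <- list()
  if (arch$kind == "lstm") {
    n <- cache$n; Tn <- cache$Tn
    g$out <- list(W = crossprod(cache$hT, dyhat), b = colSums(dyhat))
    dhT <- dyhat %*% t(params$out$W)
    L <- length(params$lstm)
    g$lstm <- vector("list", L)
    # dH: gradient flowing into each lstm layer's output sequence
    dH <- array(0, c(n, Tn, nrow(params$lstm[[L]]$Wh)))
    dH[, Tn, ] <- dhT
    for (l in rev(seq_len(L))) {
      res <- lstm_layer_backward(params$lstm[[l]], cache$lstm[[l]], dH)
      g$lstm[[l]] <- res$grads
      dH <- res$dX
    }
    # dH is now n x T x F (frontend output); back through the MLP
    Fw <- dim(dH)[3]
    dA <- matrix(dH, n * Tn, Fw)
    g$front <- vector("list", length(params$front))
    for (l in rev(seq_along(params$front))) {
      fc <- cache$front[[l]]
      dZ <- dA * (fc$Z > 0)
      g$front[[l]] <- list(W = crossprod(fc$A_in, dZ), b = colSums(dZ))
      dA <- dZ %*% t(params$front[[l]]$W)
    }
  } else {
    n <- cache$n; Tn <- cache$Tn; P <- cache$P
    k <- length(params$conv$W)
    f <- length(params$conv$b)
    Hc_pos <- cache$S > 0
    # pooled layer
    pooled <- matrix(apply(pmax(cache$S, 0), c(1, 3), mean), n, f)
    g$out <- list(W = crossprod(pooled, dyhat), b = colSums(dyhat))
    dpooled <- dyhat %*% t(params$out$W)
    dW <- lapply(seq_len(k), function(j) {
      matrix(0, nrow(params$conv$W[[j]]), f)
    })
    db <- rep(0, f)
    for (p in seq_len(P)) {
      dS <- (dpooled / P) * matrix(Hc_pos[, p, ], n)
      db <- db + colSums(dS)
      for (j in seq_len(k)) {
        dW[[j]] <- dW[[j]] + crossprod(cache$Xs[[p + j - 1]], dS)
      }
    }
    g$conv <- list(W = dW, b = db)
  }
  g
}

lstm_layer_backward <- function(lp, lcache, dH) {
  n <- dim(dH)[1]; Tn <- dim(dH)[2]
  h_sz <- lcache$h_sz
  d_in <- nrow(lp$Wx)
  dWx <- matrix(0, d_in, 4 * h_sz)
  dWh <- matrix(0, h_sz, 4 * h_sz)
  db <- rep(0, 4 * h_sz)
  dX <- array(0, c(n, Tn, d_in))
  dh_next <- matrix(0, n, h_sz)
  dc_next <- matrix(0, n, h_sz)
  for (t in rev(seq_len(Tn))) {
    st <- lcache$steps[[t]]
    dh <- matrix(dH[, t, ], n) + dh_next
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    do_ <- dh * st$tc
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$x, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(lp$Wx)
    dh_next <- dz %*% t(lp$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

# ---- masked MSE loss ------------------------------------------------------

# yhat, y, mask: n x n_out. Masked entries contribute exactly zero to the
# loss (and to its gradient), so arbitrary values in masked label slots leave
# the computed loss bit-identical.
masked_mse <- function(yhat, y, mask) {
  m <- sum(mask)
  if (m == 0) stop("all labels masked", call. = FALSE)
  diff <- (yhat - y) * mask
  list(loss = sum(diff * diff) / m, dyhat = 2 * diff / m)
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]  # grads may be ordered differently
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  walk(params, grads, m, v)
}

# ---- training loop --------------------------------------------------------

# X: n x T x D array; y, mask: n x n_out matrices (targets already on the
# normalised [0,1] score scale). Optional validation list(X, y, mask) enables
# early stopping on validation MAE.
nn_train <- function(X, y, mask, arch, learning_rate = 1e-3, epochs = 200,
                     batch_size = 64, seed = 1L, validation = NULL,
                     patience = 20L) {
  n <- dim(X)[1]
  with_seed(seed, {
    params <- nn_init(arch)
    m <- adam_state(params)
    v <- adam_state(params)
    step <- 0L
    loss_trace <- numeric(0)
    best <- list(val_mae = Inf, params = params, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        b <- idx[s:min(s + batch_size - 1, n)]
        Xb <- X[b, , , drop = FALSE]
        fw <- nn_forward(params, arch, Xb, keep_cache = TRUE)
        ls <- masked_mse(fw$yhat, y[b, , drop = FALSE],
                         mask[b, , drop = FALSE])
        if (!is.finite(ls$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        grads <- nn_backward(params, arch, fw$cache, ls$dyhat)
        step <- step + 1L
        upd <- adam_step(params, grads, m, v, learning_rate, step)
        params <- upd$p; m <- upd$m; v <- upd$v
      }
      full <- masked_mse(nn_forward(params, arch, X)$yhat, y, mask)$loss
      if (!is.finite(full)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch), call. = FALSE)
      }
      loss_trace <- c(loss_trace, full)
      if (!is.null(validation)) {
        vp <- nn_forward(params, arch, validation$X)$yhat
        vmae <- sum(abs(vp - validation$y) * validation$mask) /
          sum(validation$mask)
        if (vmae < best$val_mae - 1e-9) {
          best <- list(val_mae = vmae, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
    if (!is.null(validation) && is.finite(best$val_mae)) {
      params <- best$params
    }
    list(params = params, loss_trace = loss_trace,
         best_epoch = if (is.null(validation)) length(loss_trace)
                      else best$epoch)
  })
}

nn_predict <- function(params, arch, X) {
  nn_forward(params, arch, X)$yhat
}
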