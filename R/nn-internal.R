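# Compact convolutional + recurrent binary window classifier, implemented
# directly on BLAS-backed matrix operations: same-padding 1-D convolutions via
# im2col, max-pooling by 2 after each block, an LSTM over the pooled sequence,
# and a sigmoid head trained with class-weighted binary cross-entropy (Adam).
#
# Layout convention: activations are channels x (time * batch) matrices with
# sample-major columns (all time steps of sample 1, then sample 2, ...).

sigmoid <- function(x) 1 / (1 + exp(-x))

# source-column index map for im2col with same padding; column L*B + 1 of the
# zero-padded activation stands for "outside the sample"
nn_conv_idx <- function(L, B, K) {
  half <- (K - 1L) %/% 2L
  t_of_j <- rep(seq_len(L), B)
  j <- seq_len(L * B)
  idx <- matrix(0L, K, L * B)
  for (k in seq_len(K)) {
    off <- k - 1L - half
    src_t <- t_of_j + off
    ok <- src_t >= 1L & src_t <= L
    idx[k, ] <- ifelse(ok, j + off, L * B + 1L)
  }
  idx
}

nn_pool_idx <- function(L, B) {
  L2 <- L %/% 2L
  u <- rep(seq_len(L2), B)
  b <- rep(seq_len(B) - 1L, each = L2)
  list(odd = b * L + 2L * u - 1L, even = b * L + 2L * u, L2 = L2)
}

# per-(L, B) cached index maps
nn_maps <- function(L, B, K) {
  list(conv = nn_conv_idx(L, B, K), pool = nn_pool_idx(L, B))
}

nn_init <- function(n_channels, n_samples, spec) {
  set.seed(spec$seed)
  glorot <- function(nr, nc) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  }
  conv <- list()
  f_in <- n_channels
  for (w in spec$conv_channels) {
    conv[[length(conv) + 1]] <- list(W = glorot(w, f_in * spec$kernel),
                                     b = numeric(w))
    f_in <- w
  }
  H <- spec$recurrent_units
  lstm <- list(Wx = glorot(4 * H, f_in), Wh = glorot(4 * H, H),
               b = c(rep(0, H), rep(1, H), rep(0, 2 * H))) # forget-gate bias 1
  head <- list(w = glorot(1, H), b = 0)
  list(conv = conv, lstm = lstm, head = head)
}

# index maps for every conv level at a given batch size
nn_level_maps <- function(n_samples, B, spec) {
  maps <- list()
  L <- n_samples
  for (i in seq_along(spec$conv_channels)) {
    maps[[i]] <- nn_maps(L, B, spec$kernel)
    L <- L %/% 2L
  }
  maps
}

# forward pass; returns probabilities and, if train = TRUE, the cache needed
# for backprop. `A0` is channels x (n_samples * B); maps are per-level index
# maps produced by nn_forward_maps().
nn_forward <- function(params, A0, B, n_samples, spec, maps,
                       train = FALSE, drop_mask = NULL) {
  cache <- list(A = list(), Z = list(), P = list(), mask = list(), x = list())
  A <- A0
  L <- n_samples
  for (i in seq_along(params$conv)) {
    mp <- maps[[i]]
    K <- spec$kernel
    F_in <- nrow(A)
    Acat <- cbind(A, 0)
    X <- matrix(0, F_in * K, L * B)
    for (k in seq_len(K)) {
      X[((k - 1) * F_in + 1):(k * F_in), ] <- Acat[, mp$conv[k, ], drop = FALSE]
    }
    Z <- params$conv[[i]]$W %*% X + params$conv[[i]]$b
    H1 <- Z * (Z > 0)
    P <- pmax(H1[, mp$pool$odd, drop = FALSE], H1[, mp$pool$even, drop = FALSE])
    if (train) {
      cache$A[[i]] <- A; cache$X[[i]] <- X; cache$Z[[i]] <- Z
      cache$mask[[i]] <- (H1[, mp$pool$odd, drop = FALSE] >=
                            H1[, mp$pool$even, drop = FALSE]) * 1
    }
    A <- P
    L <- mp$pool$L2
  }
  # LSTM over the pooled sequence
  H <- spec$recurrent_units
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  if (train) cache$lstm <- vector("list", L)
  step_cols <- function(t) t + (seq_len(B) - 1L) * L
  for (t in seq_len(L)) {
    x_t <- A[, step_cols(t), drop = FALSE]
    G <- params$lstm$Wx %*% x_t + params$lstm$Wh %*% h + params$lstm$b
    i_g <- sigmoid(G[1:H, , drop = FALSE])
    f_g <- sigmoid(G[(H + 1):(2 * H), , drop = FALSE])
    o_g <- sigmoid(G[(2 * H + 1):(3 * H), , drop = FALSE])
    g_g <- tanh(G[(3 * H + 1):(4 * H), , drop = FALSE])
    cc_new <- f_g * cc + i_g * g_g
    h_new <- o_g * tanh(cc_new)
    if (train) {
      cache$lstm[[t]] <- list(x = x_t, h_prev = h, c_prev = cc, i = i_g,
                              f = f_g, o = o_g, g = g_g, c = cc_new)
    }
    h <- h_new; cc <- cc_new
  }
  h_out <- h
  if (train && !is.null(drop_mask)) h_out <- h_out * drop_mask
  z <- as.numeric(params$head$w %*% h_out + params$head$b)
  p <- sigmoid(z)
  if (!train) return(p)
  cache$h_T <- h_out
  cache$seq_len <- L
  cache$p <- p
  list(p = p, cache = cache)
}

# gradients of the class-weighted BCE loss wrt all parameters
nn_backward <- function(params, cache, y, w_pos, B, spec, maps,
                        drop_mask = NULL) {
  p <- cache$p
  dz <- (p * (w_pos * y + 1 - y) - w_pos * y) / B   # 1 x B
  g <- list(conv = list(), lstm = NULL, head = NULL)
  g$head <- list(w = matrix(dz, 1) %*% t(cache$h_T), b = sum(dz))
  dh <- t(params$head$w) %*% matrix(dz, 1)
  if (!is.null(drop_mask)) dh <- dh * drop_mask
  H <- spec$recurrent_units
  L <- cache$seq_len
  dWx <- matrix(0, 4 * H, nrow(cache$lstm[[1]]$x))
  dWh <- matrix(0, 4 * H, H)
  db <- numeric(4 * H)
  dc <- matrix(0, H, ncol(dh))
  dX_seq <- vector("list", L)
  for (t in rev(seq_len(L))) {
    st <- cache$lstm[[t]]
    tc <- tanh(st$c)
    do_g <- dh * tc
    dct <- dc + dh * st$o * (1 - tc^2)
    di <- dct * st$g
    dg <- dct * st$i
    df <- dct * st$c_prev
    dc <- dct * st$f
    dG <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_g * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + dG %*% t(st$x)
    dWh <- dWh + dG %*% t(st$h_prev)
    db <- db + rowSums(dG)
    dX_seq[[t]] <- t(params$lstm$Wx) %*% dG
    dh <- t(params$lstm$Wh) %*% dG
  }
  g$lstm <- list(Wx = dWx, Wh = dWh, b = db)

  # assemble gradient wrt the last pooled activation
  Bn <- ncol(dX_seq[[1]])
  dP <- matrix(0, nrow(dX_seq[[1]]), L * Bn)
  for (t in seq_len(L)) dP[, t + (seq_len(Bn) - 1L) * L] <- dX_seq[[t]]

  for (i in rev(seq_along(params$conv))) {
    mp <- maps[[i]]
    mask <- cache$mask[[i]]
    dH <- matrix(0, nrow(dP), ncol(cache$Z[[i]]))
    dH[, mp$pool$odd] <- dP * mask
    dH[, mp$pool$even] <- dH[, mp$pool$even, drop = FALSE] + dP * (1 - mask)
    dZ <- dH * (cache$Z[[i]] > 0)
    g$conv[[i]] <- list(W = dZ %*% t(cache$X[[i]]), b = rowSums(dZ))
    if (i > 1) {
      F_in <- nrow(cache$A[[i]])
      K <- spec$kernel
      dXc <- t(params$conv[[i]]$W) %*% dZ       # (F_in*K) x (L_i * B)
      dA <- matrix(0, F_in, ncol(cache$A[[i]]) + 1L)
      for (k in seq_len(K)) {
        src <- mp$conv[k, ]
        ok <- src <= ncol(cache$A[[i]])
        rows <- ((k - 1) * F_in + 1):(k * F_in)
        dA[, src[ok]] <- dA[, src[ok], drop = FALSE] +
          dXc[rows, ok, drop = FALSE]
      }
      dP <- dA[, seq_len(ncol(cache$A[[i]])), drop = FALSE]
    }
  }
  g
}

nn_adam_init <- function(params) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                           else numeric(length(p))
  rec <- function(x) if (is.list(x)) lapply(x, rec) else zero_like(x)
  list(m = rec(params), v = rec(params), t = 0)
}

nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# reshape a subset of a (n, samples, channels) window array into the
# channels x (samples * B) sample-major activation matrix
nn_batch_input <- function(data, rows) {
  arr <- data[rows, , , drop = FALSE]
  a <- aperm(arr, c(3, 2, 1))
  dim(a) <- c(dim(arr)[3], dim(arr)[2] * dim(arr)[1])
  a
}
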