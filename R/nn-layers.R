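# Neural building blocks on top of the autodiff tape: parameter
# initialisers, an LSTM run in either direction, a character-level CNN,
# additive attention pooling, and a lazy Adam optimiser.

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

embed_init <- function(nvocab, dim, scale = 0.1) {
  matrix(stats::rnorm(nvocab * dim, 0, scale), nvocab, dim)
}

# Parameter names for one LSTM direction under a prefix.
lstm_init <- function(in_dim, hidden, prefix) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- glorot(in_dim, 4L * hidden)
  p[[paste0(prefix, ".U")]] <- glorot(hidden, 4L * hidden)
  b <- matrix(0, 1L, 4L * hidden)
  b[1L, (hidden + 1L):(2L * hidden)] <- 1 # forget-gate bias
  p[[paste0(prefix, ".b")]] <- b
  p
}

# One LSTM direction as a single fused tape node: the whole recurrence
# (and its backward-through-time pass) runs as vectorised plain-R matrix
# code inside one node, which keeps the tape short. `xw` is the
# precomputed input projection X W + b (n x 4H); `u` the recurrent weight
# node (H x 4H). Gate layout along columns: input, forget, cell, output.
ad_lstm_seq <- function(xw, u, hidden, reverse = FALSE) {
  n <- nrow(xw$val)
  H <- hidden
  ii <- 1:H; fi <- (H + 1L):(2L * H)
  gi <- (2L * H + 1L):(3L * H); oi <- (3L * H + 1L):(4L * H)
  steps <- if (reverse) n:1 else 1:n
  Uv <- u$val
  ig <- matrix(0, n, H); fg <- matrix(0, n, H)
  gg <- matrix(0, n, H); og <- matrix(0, n, H)
  cs <- matrix(0, n, H); tc <- matrix(0, n, H)
  hs <- matrix(0, n, H)
  h <- matrix(0, 1L, H); cc <- matrix(0, 1L, H)
  for (t in steps) {
    z <- xw$val[t, ] + h %*% Uv
    ig[t, ] <- 1 / (1 + exp(-z[, ii]))
    fg[t, ] <- 1 / (1 + exp(-z[, fi]))
    gg[t, ] <- tanh(z[, gi])
    og[t, ] <- 1 / (1 + exp(-z[, oi]))
    cc <- fg[t, , drop = FALSE] * cc + ig[t, , drop = FALSE] * gg[t, , drop = FALSE]
    cs[t, ] <- cc
    tc[t, ] <- tanh(cc)
    h <- og[t, , drop = FALSE] * tc[t, , drop = FALSE]
    hs[t, ] <- h
  }
  ad_node(hs, back = function(nd) {
    gH <- nd$grad
    gxw <- matrix(0, n, 4L * H)
    gU <- matrix(0, H, 4L * H)
    dh <- matrix(0, 1L, H); dc <- matrix(0, 1L, H)
    for (t in rev(steps)) {
      dht <- gH[t, , drop = FALSE] + dh
      i_t <- ig[t, , drop = FALSE]; f_t <- fg[t, , drop = FALSE]
      g_t <- gg[t, , drop = FALSE]; o_t <- og[t, , drop = FALSE]
      tct <- tc[t, , drop = FALSE]
      do_ <- dht * tct
      dct <- dc + dht * o_t * (1 - tct * tct)
      di <- dct * g_t; dg <- dct * i_t
      prev <- if (t == steps[1L]) matrix(0, 1L, H) else {
        pt <- if (reverse) t + 1L else t - 1L
        cs[pt, , drop = FALSE]
      }
      df <- dct * prev
      dz <- cbind(di * i_t * (1 - i_t), df * f_t * (1 - f_t),
                  dg * (1 - g_t * g_t), do_ * o_t * (1 - o_t))
      gxw[t, ] <- dz
      hprev <- if (t == steps[1L]) matrix(0, 1L, H) else {
        pt <- if (reverse) t + 1L else t - 1L
        hs[pt, , drop = FALSE]
      }
      gU <- gU + crossprod(hprev, dz)
      dh <- dz %*% t(Uv)
      dc <- dct * f_t
    }
    ad_acc(xw, gxw)
    ad_acc(u, gU)
  })
}

# One LSTM direction over X (n x d node); returns n x hidden node.
lstm_run <- function(params, prefix, x, hidden, reverse = FALSE) {
  W <- ad_par(params, paste0(prefix, ".W"))
  U <- ad_par(params, paste0(prefix, ".U"))
  b <- ad_par(params, paste0(prefix, ".b"))
  xw <- ad_badd_row(ad_mm(x, W), b)
  ad_lstm_seq(xw, U, hidden, reverse = reverse)
}

bilstm_init <- function(in_dim, hidden_total, prefix) {
  h <- hidden_total %/% 2L
  c(lstm_init(in_dim, h, paste0(prefix, ".fw")),
    lstm_init(in_dim, h, paste0(prefix, ".bw")))
}

# Bidirectional LSTM: concatenated forward and backward states (n x hidden_total).
bilstm_run <- function(params, prefix, x, hidden_total) {
  h <- hidden_total %/% 2L
  ad_hcat(list(
    lstm_run(params, paste0(prefix, ".fw"), x, h, reverse = FALSE),
    lstm_run(params, paste0(prefix, ".bw"), x, h, reverse = TRUE)
  ))
}

char_cnn_init <- function(nchar_vocab, char_dim, filters, kernel, prefix = "char") {
  p <- list()
  p[[paste0(prefix, ".emb")]] <- embed_init(nchar_vocab, char_dim)
  for (j in seq_len(kernel)) {
    p[[paste0(prefix, ".W", j)]] <- glorot(char_dim, filters)
  }
  p[[paste0(prefix, ".b")]] <- matrix(0, 1L, filters)
  p
}

# Character CNN for one token: embed characters, convolve with a width-k
# kernel (token padded so at least one window exists), tanh, max-pool over
# positions. Returns a 1 x filters node. Results are cached per tape by
# token text (the representation depends only on the characters).
char_cnn_run <- function(params, prefix, char_idx, kernel, pad_idx, cache_key = NULL) {
  tp <- .ad$tape
  if (!is.null(cache_key)) {
    hit <- tp$ccache[[cache_key]]
    if (!is.null(hit)) return(hit)
  }
  m <- length(char_idx)
  pad <- max(0L, kernel - m)
  idx <- c(char_idx, rep(pad_idx, pad))
  L <- length(idx) - kernel + 1L
  emb <- ad_par(params, paste0(prefix, ".emb"))
  e <- ad_rows(emb, idx)
  acc <- NULL
  for (j in seq_len(kernel)) {
    wj <- ad_par(params, paste0(prefix, ".W", j))
    sj <- ad_mm(ad_rows(e, j:(j + L - 1L)), wj)
    acc <- if (is.null(acc)) sj else ad_add(acc, sj)
  }
  out <- ad_colmax(ad_tanh(ad_badd_row(acc, ad_par(params, paste0(prefix, ".b")))))
  if (!is.null(cache_key)) assign(cache_key, out, envir = tp$ccache)
  out
}

attention_init <- function(hidden, attn_dim, prefix = "attn") {
  p <- list()
  p[[paste0(prefix, ".W")]] <- glorot(hidden, attn_dim)
  p[[paste0(prefix, ".b")]] <- matrix(0, 1L, attn_dim)
  p[[paste0(prefix, ".v")]] <- glorot(attn_dim, 1L)
  p
}

# Additive attention pooling over H (n x h): scores via a learned vector on a
# tanh projection, softmax weights, weighted sum. Returns list(context 1 x h,
# weights n x 1).
attention_run <- function(params, prefix, h) {
  proj <- ad_tanh(ad_badd_row(ad_mm(h, ad_par(params, paste0(prefix, ".W"))),
                              ad_par(params, paste0(prefix, ".b"))))
  scores <- ad_mm(proj, ad_par(params, paste0(prefix, ".v")))
  w <- ad_softmax(scores)
  list(context = ad_mm(ad_t(w), h), weights = w)
}

## ---- optimiser -----------------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$m <- list(); st$v <- list(); st$t <- list()
  st
}

# Lazy Adam: only parameters that received gradient on this batch are
# stepped (per-parameter step counts keep the bias correction right).
# Untouched parameters are therefore bitwise unchanged, which is what makes
# the multi-task gradient-partition contract exactly checkable.
adam_step <- function(st, params, grads) {
  for (name in names(grads)) {
    g <- grads[[name]]
    t1 <- (st$t[[name]] %||% 0L) + 1L
    m <- st$m[[name]] %||% (g * 0)
    v <- st$v[[name]] %||% (g * 0)
    m <- st$beta1 * m + (1 - st$beta1) * g
    v <- st$beta2 * v + (1 - st$beta2) * g * g
    mhat <- m / (1 - st$beta1^t1)
    vhat <- v / (1 - st$beta2^t1)
    params[[name]] <- params[[name]] - st$lr * mhat / (sqrt(vhat) + st$eps)
    st$m[[name]] <- m; st$v[[name]] <- v; st$t[[name]] <- t1
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
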