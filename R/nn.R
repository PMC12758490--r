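# Minimal dense feed-forward machinery with hand-derived reverse-mode
# gradients. The networks here are tiny (tens of units, latent dim 2), so
# plain BLAS-backed matrix algebra is all that is needed; no external
# deep-learning runtime is involved.

mlp_init <- function(d_in, d_out, hidden = c(64L, 64L), zero_last = FALSE) {
  sizes <- c(d_in, hidden, d_out)
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  if (zero_last) {
    W[[n_layers]][] <- 0
    b[[n_layers]][] <- 0
  }
  list(W = W, b = b)
}

# Forward pass; h[[1]] is the input, h[[l+1]] the post-activation of layer l.
# Hidden activations are tanh, the output layer is linear.
mlp_forward <- function(net, X) {
  n_layers <- length(net$W)
  h <- vector("list", n_layers + 1L)
  h[[1L]] <- X
  for (l in seq_len(n_layers)) {
    a <- t.default(t.default(h[[l]] %*% net$W[[l]]) + net$b[[l]])
    h[[l + 1L]] <- if (l < n_layers) tanh(a) else a
  }
  list(out = h[[n_layers + 1L]], h = h)
}

# Reverse pass. `G` is dLoss/d(out); returns parameter gradients and the
# gradient with respect to the input rows.
mlp_backward <- function(net, cache, G) {
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  h <- cache$h
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers) G <- G * (1 - h[[l + 1L]]^2)
    gW[[l]] <- crossprod(h[[l]], G)
    gb[[l]] <- colSums(G)
    G <- G %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, gX = G)
}

mlp_zero_grads <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(b) b * 0))
}

# --- Adam over arbitrary nested lists of numeric arrays ------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        if (is.null(g[[i]])) next
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
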