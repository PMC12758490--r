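# RealNVP normalizing flow between the information-bottleneck (IB) latent
# space and the prior space. Each coupling block updates one coordinate
# channel by an affine map whose scale and shift are small feed-forward
# networks of the frozen channel; masks alternate between blocks, so the
# composed Jacobian stays triangular and its log-determinant is the sum of
# the per-block scale outputs. The final layers of the scale/shift networks
# are zero-initialized, so a fresh flow is exactly the identity.

#' Initialize a RealNVP flow
#'
#' @param dim Latent dimension (default 2; in 2D each coupling channel is one
#'   coordinate).
#' @param n_blocks Number of coupling blocks (default 6).
#' @param hidden Hidden-layer widths of the scale and shift networks.
#' @param s_max The raw scale output is squashed through `s_max * tanh` to
#'   keep the per-block expansion bounded.
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `"flow_model"`; freshly initialized flows map
#'   `u` to `u` with zero log-determinant.
#' @export
flow_init <- function(dim = 2L, n_blocks = 6L, hidden = c(64L, 64L),
                      s_max = 2, seed = NULL) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L, n_blocks >= 1L)
  with_seed(seed, {
    blocks <- vector("list", n_blocks)
    for (i in seq_len(n_blocks)) {
      update <- (seq_len(dim) %% 2L) == (i %% 2L)  # alternating channel mask
      d_pass <- sum(!update); d_act <- sum(update)
      # one conditioner per block; its output splits into the raw scale
      # (first d_act columns, squashed by s_max * tanh) and the shift
      blocks[[i]] <- list(
        update = update, d_act = d_act,
        net = mlp_init(d_pass, 2L * d_act, hidden, zero_last = TRUE))
    }
    structure(list(blocks = blocks, dim = dim, s_max = s_max),
              class = "flow_model")
  })
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("RealNVP flow: %d coupling blocks, dim = %d, s_max = %g\n",
              length(x$blocks), x$dim, x$s_max))
  invisible(x)
}

# Internal forward with per-block caches (for backprop).
flow_forward_cached <- function(flow, u) {
  n_blocks <- length(flow$blocks)
  caches <- vector("list", n_blocks)
  logdet <- numeric(nrow(u))
  for (i in seq_len(n_blocks)) {
    blk <- flow$blocks[[i]]
    up <- u[, !blk$update, drop = FALSE]
    fc <- mlp_forward(blk$net, up)
    k <- blk$d_act
    raw_s <- fc$out[, seq_len(k), drop = FALSE]
    t_out <- fc$out[, k + seq_len(k), drop = FALSE]
    s <- flow$s_max * tanh(raw_s)
    ua <- u[, blk$update, drop = FALSE]
    if (!all(is.finite(s)) || !all(is.finite(t_out)))
      stop(sprintf("non-finite activation in coupling block %d", i))
    caches[[i]] <- list(ua = ua, s = s, raw_s = raw_s, cond = fc)
    u[, blk$update] <- ua * exp(s) + t_out
    logdet <- logdet + rowSums(s)
  }
  list(w = u, logdet = logdet, caches = caches)
}

#' Map IB-space points through the flow
#'
#' @param flow A [flow_init()] model.
#' @param u Matrix of points (rows) in IB space, `flow$dim` columns.
#' @return A list with `w` (prior-space images) and `logdet` (per-point exact
#'   log |det Jacobian| of the forward map).
#' @export
flow_forward <- function(flow, u) {
  stopifnot(inherits(flow, "flow_model"))
  u <- as_matrix_rows(u, flow$dim, "u")
  logdet <- numeric(nrow(u))
  for (i in seq_along(flow$blocks)) {
    blk <- flow$blocks[[i]]
    out <- mlp_forward(blk$net, u[, !blk$update, drop = FALSE])$out
    k <- blk$d_act
    s <- flow$s_max * tanh(out[, seq_len(k), drop = FALSE])
    t <- out[, k + seq_len(k), drop = FALSE]
    if (!all(is.finite(s)) || !all(is.finite(t)))
      stop(sprintf("non-finite activation in coupling block %d", i))
    u[, blk$update] <- u[, blk$update, drop = FALSE] * exp(s) + t
    logdet <- logdet + rowSums(s)
  }
  list(w = u, logdet = logdet)
}

#' Invert the flow exactly
#'
#' Algebraic inverse of [flow_forward()]: blocks are undone in reverse order,
#' and `logdet` is minus the forward log-determinant at the preimage.
#'
#' @param flow A flow model.
#' @param w Matrix of prior-space points.
#' @return A list with `u` (IB-space preimages) and `logdet`.
#' @export
flow_inverse <- function(flow, w) {
  stopifnot(inherits(flow, "flow_model"))
  w <- as_matrix_rows(w, flow$dim, "w")
  logdet <- numeric(nrow(w))
  for (i in rev(seq_along(flow$blocks))) {
    blk <- flow$blocks[[i]]
    wp <- w[, !blk$update, drop = FALSE]
    out <- mlp_forward(blk$net, wp)$out
    k <- blk$d_act
    s <- flow$s_max * tanh(out[, seq_len(k), drop = FALSE])
    t <- out[, k + seq_len(k), drop = FALSE]
    if (!all(is.finite(s)) || !all(is.finite(t)))
      stop(sprintf("non-finite activation in coupling block %d", i))
    w[, blk$update] <- (w[, blk$update, drop = FALSE] - t) * exp(-s)
    logdet <- logdet - rowSums(s)
  }
  list(u = w, logdet = logdet)
}

# Backward pass through a cached forward run. Gw is dL/dw (n x dim),
# g_logdet dL/d(logdet_i) (length n). Returns nested block gradients plus
# dL/du.
flow_backward <- function(flow, caches, Gw, g_logdet) {
  n_blocks <- length(flow$blocks)
  grads <- vector("list", n_blocks)
  for (i in rev(seq_len(n_blocks))) {
    blk <- flow$blocks[[i]]
    cc <- caches[[i]]
    Ga <- Gw[, blk$update, drop = FALSE]
    Gp <- Gw[, !blk$update, drop = FALSE]
    es <- exp(cc$s)
    g_ua <- Ga * es
    g_s <- Ga * cc$ua * es + g_logdet          # recycled across columns
    g_raw_s <- g_s * flow$s_max * (1 - tanh(cc$raw_s)^2)
    bc <- mlp_backward(blk$net, cc$cond, cbind(g_raw_s, Ga))
    grads[[i]] <- list(net = list(W = bc$W, b = bc$b))
    Gw[, blk$update] <- g_ua
    Gw[, !blk$update] <- Gp + bc$gX
  }
  list(blocks = grads, Gu = Gw)
}

flow_params <- function(flow) {
  lapply(flow$blocks, function(b) list(net = b$net))
}

flow_set_params <- function(flow, params) {
  for (i in seq_along(flow$blocks)) {
    flow$blocks[[i]]$net <- params[[i]]$net
  }
  flow
}

#' Exact log-likelihood of IB-space points under the flow + tilted prior
#'
#' Change of variables: `log r(f(u)) + log |det J_f(u)|`, with `r` the
#' normalized tilted Gaussian prior.
#'
#' @param flow A flow model.
#' @param u Points in IB space (matrix rows).
#' @param spec A [prior_spec()]; its `temperature` is used unless
#'   `temperatures` supplies one per row.
#' @param temperatures Optional per-row steerable temperatures.
#' @return Per-point log-likelihood.
#' @export
flow_log_likelihood <- function(flow, u, spec, temperatures = NULL) {
  fw <- flow_forward(flow, u)
  if (is.null(temperatures)) {
    tilted_log_density(fw$w, spec) + fw$logdet
  } else {
    tilted_log_density_multi(fw$w, spec$tau, spec$dim, temperatures) +
      fw$logdet
  }
}

#' Fit a flow to fixed points by maximum likelihood
#'
#' Trains the coupling networks alone (no encoder) to maximize the mean exact
#' log-likelihood of `u` under the tilted prior pulled back through the flow.
#' Used for density estimation on a fixed latent sample and as the
#' building block of tilting-factor screens.
#'
#' @param u Matrix of training points.
#' @param spec A [prior_spec()].
#' @param flow Optional starting flow (default: fresh identity-initialized).
#' @param epochs,batch_size,lr Optimization settings (Adam).
#' @param temperatures Optional per-row steerable temperatures.
#' @param seed Optional seed (weight init + batch shuffling).
#' @return The trained `"flow_model"`, with attribute `"history"` holding the
#'   per-epoch mean negative log-likelihood.
#' @export
fit_flow <- function(u, spec, flow = NULL, epochs = 100L, batch_size = 512L,
                     lr = 1e-3, temperatures = NULL, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  u <- as_matrix_rows(u, spec$dim, "u")
  n <- nrow(u)
  flow <- flow %||% flow_init(spec$dim, seed = fan_seed(seed, 1L))
  params <- flow_params(flow)
  opt <- adam_init(params)
  hist <- numeric(epochs)
  with_seed(fan_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        ub <- u[idx, , drop = FALSE]
        tb <- if (is.null(temperatures)) NULL else temperatures[idx]
        fwd <- flow_forward_cached(flow, ub)
        if (is.null(tb)) {
          ll <- tilted_log_density(fwd$w, spec) + fwd$logdet
          gw <- tilted_log_density_grad(fwd$w, spec)
        } else {
          ll <- tilted_log_density_multi(fwd$w, spec$tau, spec$dim, tb) +
            fwd$logdet
          gw <- tilted_log_density_grad_multi(fwd$w, spec$tau, spec$dim, tb)
        }
        m <- length(idx)
        bk <- flow_backward(flow, fwd$caches, -gw / m, rep(-1 / m, m))
        st <- adam_step(params, bk$blocks, opt, lr = lr)
        params <- st$params; opt <- st$state
        flow <- flow_set_params(flow, params)
        tot <- tot - sum(ll)
      }
      hist[ep] <- tot / n
    }
  })
  attr(flow, "history") <- hist
  flow
}
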