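# Joint training of the time-lagged encoder/decoder and the RealNVP flow
# under the unified objective
#
#   L = E[ -log q(y_{t+lag} | u_t) ]
#     + beta * E[ log N(u_t; mu_t, sigma^2 I) - (log r(f(u_t)) + log|J_f|) ]
#
# with u_t = mu_t + sigma * eps drawn from the Gaussian posterior around the
# encoded mean. The first term is the future-state reconstruction error; the
# second and third jointly regularize encoder and flow towards the tilted
# Gaussian prior r. The vanilla baseline replaces the flow-refined prior
# with a VampPrior mixture. Training follows the two-step schedule: the
# baseline model is first trained to a converged state assignment
# (alternating optimization with label refinement), then encoder, decoder,
# posterior scale and flow are optimized jointly with labels frozen and one
# final refinement pass.

#' Training configuration
#'
#' @param hidden_encoder,hidden_decoder,flow_hidden Hidden-layer widths of
#'   the encoder, decoder and coupling networks.
#' @param flow_blocks Number of RealNVP coupling blocks.
#' @param s_max Bound on the coupling log-scale (squashing `s_max * tanh`).
#' @param beta Information-bottleneck tradeoff weight.
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param epochs_stage1 Epochs between label-refinement passes in stage 1.
#' @param max_refine Maximum number of refinement passes.
#' @param tol_relabel Convergence: fraction of changed labels below this for
#'   two consecutive passes.
#' @param epochs_stage2 Fixed epoch budget for joint (stage-2) training.
#' @param max_pairs_per_epoch Cap on the number of time-lagged pairs visited
#'   per epoch (a fresh random subset each epoch); `Inf` uses all pairs.
#'   Keeps the epoch cost flat on long trajectories.
#' @param epochs_polish Flow-refinement epochs after joint training: with
#'   encoder, decoder and posterior scale frozen, the flow alone continues
#'   maximum-likelihood training on fresh posterior draws each epoch. This
#'   sharpens the density estimate without moving the representation.
#' @param n_pseudo Number of learnable VampPrior pseudo-inputs.
#' @param sigma0 Initial posterior scale.
#' @param dim Latent (IB) dimension.
#' @return A list of class `"ibflow_control"`.
#' @export
ibflow_control <- function(hidden_encoder = c(64L, 64L),
                           hidden_decoder = 64L,
                           flow_blocks = 6L,
                           flow_hidden = c(64L, 64L),
                           s_max = 2,
                           beta = 0.01,
                           lr = 1e-3,
                           batch_size = 512L,
                           epochs_stage1 = 4L,
                           max_refine = 20L,
                           tol_relabel = 0.005,
                           epochs_stage2 = 50L,
                           max_pairs_per_epoch = Inf,
                           epochs_polish = 40L,
                           n_pseudo = 10L,
                           sigma0 = 0.1,
                           dim = 2L) {
  structure(as.list(environment()), class = "ibflow_control")
}

#' Time-lagged index pairs
#'
#' Builds all `(t, t + lag)` frame-index pairs that do not cross a contiguous
#' segment boundary.
#'
#' @param x A [feature_trajectory()], a list of them, or an integer vector of
#'   segment lengths.
#' @param lag Lag in recorded frames (`>= 1`).
#' @return A two-column integer matrix (`t`, `t_lag`); a segment of length L
#'   contributes `L - lag` pairs.
#' @export
make_lagged_pairs <- function(x, lag) {
  if (length(lag) != 1L || !is.finite(lag) || lag < 1L)
    stop("lag must be a positive integer (got ", lag, ")")
  lag <- as.integer(lag)
  segs <- if (inherits(x, "feature_trajectory")) x$segments
          else if (is.list(x)) unlist(lapply(x, `[[`, "segments"))
          else as.integer(x)
  offset <- 0L
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    L <- segs[i]
    if (L > lag) {
      t0 <- offset + seq_len(L - lag)
      out[[i]] <- cbind(t0, t0 + lag)
    }
    offset <- offset + L
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("lag (", lag, ") is not smaller than any segment length")
  colnames(pairs) <- c("t", "t_lag")
  pairs
}

#' Steerable temperature parameters from physical temperatures
#'
#' The lowest training temperature maps to 1; the others are rescaled
#' proportionally.
#'
#' @param temperatures Vector of positive physical temperatures.
#' @return `temperatures / min(temperatures)`.
#' @export
temperature_scale <- function(temperatures) {
  if (length(temperatures) == 0L) stop("empty temperature list")
  if (any(!is.finite(temperatures) | temperatures <= 0))
    stop("temperatures must be positive")
  temperatures / min(temperatures)
}

# --- internal: data preparation ------------------------------------------

prepare_training_data <- function(x) {
  trajs <- if (inherits(x, "feature_trajectory")) list(x)
           else if (is.list(x)) x
           else list(feature_trajectory(as.matrix(x)))
  stopifnot(all(vapply(trajs, inherits, TRUE, "feature_trajectory")))
  frames <- do.call(rbind, lapply(trajs, `[[`, "frames"))
  segments <- unlist(lapply(trajs, `[[`, "segments"))
  kT <- vapply(trajs, `[[`, numeric(1), "temperature")
  steer <- temperature_scale(kT)
  temps <- rep(steer, vapply(trajs, function(t) nrow(t$frames), integer(1)))
  coords <- lapply(trajs, `[[`, "coords")
  coords <- if (all(vapply(coords, is.null, TRUE))) NULL
            else do.call(rbind, coords)
  list(frames = frames, segments = segments, temps = temps,
       kT = kT, steer = steer, coords = coords,
       frame_interval = trajs[[1]]$frame_interval)
}

add_grad_lists <- function(a, b) {
  for (i in seq_along(a)) a[[i]] <- a[[i]] + b[[i]]
  a
}

# --- internal: loss + gradients on one minibatch -------------------------

# Returns loss components and gradients matching the `params` layout
# (enc, dec, log_sigma, and flow blocks or pseudo-inputs).
batch_loss_grads <- function(model, Xb, y, temps_b, eps, want_grads = TRUE) {
  n <- nrow(Xb)
  d <- model$dim
  sigma <- exp(model$log_sigma)
  fe <- mlp_forward(model$encoder, Xb)
  mu <- fe$out
  u <- mu + sigma * eps

  fd <- mlp_forward(model$decoder, u)
  p <- softmax_rows(fd$out)
  ce <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-300)))

  log_q <- -d * model$log_sigma - (d / 2) * log(2 * pi) -
    rowSums(eps * eps) / 2

  if (model$type == "ibflow") {
    fwd <- flow_forward_cached(model$flow, u)
    if (is.null(temps_b)) {
      log_r <- tilted_log_density(fwd$w, model$prior) + fwd$logdet
      gw <- if (want_grads) tilted_log_density_grad(fwd$w, model$prior)
    } else {
      log_r <- tilted_log_density_multi(fwd$w, model$prior$tau, d, temps_b) +
        fwd$logdet
      gw <- if (want_grads)
        tilted_log_density_grad_multi(fwd$w, model$prior$tau, d, temps_b)
    }
  } else {
    fp <- mlp_forward(model$encoder, model$pseudo)
    e <- fp$out
    M <- nrow(e)
    sigma2 <- sigma^2
    comp <- matrix(0, n, M)
    for (m in seq_len(M)) {
      dz <- sweep(u, 2L, e[m, ], "-")
      comp[, m] <- -rowSums(dz * dz) / (2 * sigma2) -
        (d / 2) * log(2 * pi * sigma2)
    }
    log_r <- logsumexp_rows(comp) - log(M)
  }

  reg <- mean(log_q - log_r)
  total <- ce + model$beta * reg
  out <- list(total = total, reconstruction = ce, regularization = reg,
              log_q = mean(log_q), log_r = mean(log_r))
  if (!want_grads) return(out)

  # reconstruction path
  Y <- matrix(0, n, ncol(p))
  Y[cbind(seq_len(n), y)] <- 1
  bdec <- mlp_backward(model$decoder, fd, (p - Y) / n)
  G_u <- bdec$gX
  g_log_sigma <- -model$beta * d  # d/dlogsigma of beta*mean(log q)

  if (model$type == "ibflow") {
    bflow <- flow_backward(model$flow, fwd$caches, -model$beta / n * gw,
                           rep(-model$beta / n, n))
    G_u <- G_u + bflow$Gu
    grads_extra <- list(flow = bflow$blocks)
  } else {
    gam <- softmax_rows(comp)
    dlr_du <- (gam %*% e - u) / sigma2
    G_u <- G_u + (-model$beta / n) * dlr_du
    G_e <- (-model$beta / n) * (crossprod(gam, u) - colSums(gam) * e) / sigma2
    dev2 <- matrix(0, n, M)
    for (m in seq_len(M)) {
      dz <- sweep(u, 2L, e[m, ], "-")
      dev2[, m] <- rowSums(dz * dz)
    }
    dlr_dls <- rowSums(gam * (dev2 / sigma2 - d))
    g_log_sigma <- g_log_sigma - model$beta * mean(dlr_dls)
    bpse <- mlp_backward(model$encoder, fp, G_e)
    grads_extra <- list(pseudo = bpse$gX, enc_pseudo = bpse)
  }

  g_log_sigma <- g_log_sigma + sum(G_u * (sigma * eps))
  benc <- mlp_backward(model$encoder, fe, G_u)
  gW <- benc$W; gb <- benc$b
  if (!is.null(grads_extra$enc_pseudo)) {
    gW <- add_grad_lists(gW, grads_extra$enc_pseudo$W)
    gb <- add_grad_lists(gb, grads_extra$enc_pseudo$b)
  }
  out$grads <- list(enc = list(W = gW, b = gb),
                    dec = list(W = bdec$W, b = bdec$b),
                    log_sigma = g_log_sigma,
                    flow = grads_extra$flow,
                    pseudo = grads_extra$pseudo)
  out
}

#' Evaluate the unified training objective at fixed parameters
#'
#' Computes the loss (and its reconstruction / regularization components)
#' on the given time-lagged pairs without updating the model. With the flow
#' at its identity initialization and `tau = 0`, the objective coincides with
#' the standard-Gaussian-prior time-lagged bottleneck objective.
#'
#' @param model A fitted or initialized model.
#' @param x Training data ([feature_trajectory()] or list).
#' @param labels Integer per-frame labels (defaults to the model's stored
#'   labels).
#' @param pairs Optional pair matrix from [make_lagged_pairs()].
#' @param epsilon Optional fixed posterior noise (matrix, one row per pair);
#'   defaults to draws controlled by `seed`.
#' @param seed Optional seed for the posterior draw.
#' @return A list with `total`, `reconstruction`, `regularization`,
#'   `log_q`, `log_r`.
#' @export
unified_loss <- function(model, x, labels = NULL, pairs = NULL,
                         epsilon = NULL, seed = NULL) {
  dat <- prepare_training_data(x)
  pairs <- pairs %||% make_lagged_pairs(dat$segments, model$lag)
  labels <- labels %||% model$labels$labels
  Xs <- standardize_features(model, dat$frames)
  y <- labels[pairs[, 2L]]
  eps <- epsilon %||% with_seed(seed, matrix(rnorm(nrow(pairs) * model$dim),
                                            nrow(pairs)))
  temps_b <- if (length(unique(dat$temps)) > 1L) dat$temps[pairs[, 1L]]
             else NULL
  r <- batch_loss_grads(model, Xs[pairs[, 1L], , drop = FALSE], y, temps_b,
                        eps, want_grads = FALSE)
  if (!is.finite(r$total))
    stop(sprintf(paste0("non-finite loss (reconstruction = %g, ",
                        "regularization = %g)"),
                 r$reconstruction, r$regularization))
  r
}

# --- internal: one optimization stage ------------------------------------

collect_params <- function(model) {
  p <- list(enc = list(W = model$encoder$W, b = model$encoder$b),
            dec = list(W = model$decoder$W, b = model$decoder$b),
            log_sigma = model$log_sigma)
  if (model$type == "ibflow") p$flow <- flow_params(model$flow)
  else p$pseudo <- model$pseudo
  p
}

apply_params <- function(model, p) {
  model$encoder$W <- p$enc$W; model$encoder$b <- p$enc$b
  model$decoder$W <- p$dec$W; model$decoder$b <- p$dec$b
  model$log_sigma <- p$log_sigma
  if (model$type == "ibflow") model$flow <- flow_set_params(model$flow, p$flow)
  else model$pseudo <- p$pseudo
  model
}

run_epochs <- function(model, Xs, labels, pairs, temps, control, epochs,
                       opt_env) {
  n_pairs <- nrow(pairs)
  multi_T <- length(unique(temps)) > 1L
  params <- collect_params(model)
  if (is.null(opt_env$state)) opt_env$state <- adam_init(params)
  hist <- vector("list", epochs)
  n_visit <- min(n_pairs, control$max_pairs_per_epoch)
  for (ep in seq_len(epochs)) {
    ord <- if (n_visit < n_pairs) sample.int(n_pairs, n_visit)
           else sample.int(n_pairs)
    tot <- c(total = 0, reconstruction = 0, regularization = 0)
    n_batches <- 0L
    for (start in seq(1L, n_visit, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1L, n_visit)]
      ib <- pairs[idx, 1L]
      Xb <- Xs[ib, , drop = FALSE]
      y <- labels[pairs[idx, 2L]]
      eps <- matrix(rnorm(length(idx) * model$dim), length(idx))
      tb <- if (multi_T) temps[ib] else NULL
      r <- batch_loss_grads(model, Xb, y, tb, eps)
      if (!is.finite(r$total))
        stop(sprintf(paste0("non-finite loss (reconstruction = %g, ",
                            "regularization = %g)"),
                     r$reconstruction, r$regularization))
      st <- adam_step(params, r$grads, opt_env$state, lr = control$lr)
      params <- st$params
      opt_env$state <- st$state
      model <- apply_params(model, params)
      tot <- tot + c(r$total, r$reconstruction, r$regularization)
      n_batches <- n_batches + 1L
    }
    hist[[ep]] <- tot / n_batches
  }
  attr(model, "epoch_log") <- do.call(rbind, hist)
  model
}

# --- the fitting function ------------------------------------------------

#' Fit a latent-flow information-bottleneck model
#'
#' Two-step training on one or more time-ordered descriptor trajectories:
#' stage 1 trains the vanilla time-lagged bottleneck (VampPrior) with
#' iterative state-label refinement until the assignment converges; stage 2
#' jointly optimizes encoder, decoder, posterior scale and RealNVP flow
#' under the unified objective with the exponentially tilted Gaussian prior,
#' followed by one final refinement pass. With `type = "spib"` the model
#' stops after stage 1 (the vanilla baseline).
#'
#' For multi-temperature data, pass a list of trajectories whose
#' `temperature` fields hold the physical temperatures; each sample's prior
#' term then uses its own steerable parameter (lowest temperature = 1).
#'
#' @param x A [feature_trajectory()], a list of them, or a plain matrix.
#' @param lag Prediction lag in recorded frames.
#' @param tau Tilting factor of the prior.
#' @param k_init Number of initial k-means states (ignored when `labels`
#'   given).
#' @param labels Optional initial labels (integer vector or
#'   [state_assignment()]).
#' @param init_space Passed to [init_labels()]: `"features"` or `"moments"`.
#' @param type `"ibflow"` (full model) or `"spib"` (VampPrior baseline).
#' @param control An [ibflow_control()] list.
#' @param seed Integer seed; given the seed the fit is deterministic.
#' @return An object of class `"ibflow"`.
#' @examples
#' \donttest{
#' traj <- simulate_langevin(sim_protocol("three_hole", n_steps = 2e5), seed = 1)
#' fit <- ibflow(traj, lag = 5, tau = 2.5, k_init = 4,
#'               control = ibflow_control(epochs_stage2 = 10), seed = 1)
#' print(fit)
#' }
#' @export
ibflow <- function(x, lag = 10L, tau = 2, k_init = 6L, labels = NULL,
                   init_space = c("features", "moments"),
                   type = c("ibflow", "spib"),
                   control = ibflow_control(), seed = NULL) {
  type <- match.arg(type)
  init_space <- match.arg(init_space)
  cl <- match.call()
  dat <- prepare_training_data(x)
  pairs <- make_lagged_pairs(dat$segments, lag)

  if (is.null(labels)) {
    labels <- init_labels(dat$frames, k_init, seed = fan_seed(seed, 1L),
                          space = init_space)
  }
  if (inherits(labels, "state_assignment")) labels <- labels$labels
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(dat$frames))
  K <- max(labels)

  center <- colMeans(dat$frames)
  scl <- apply(dat$frames, 2L, sd)
  scl[scl < 1e-12] <- 1
  model <- structure(list(
    type = "spib", dim = control$dim, beta = control$beta, lag = lag,
    center = center, scale = scl, log_sigma = log(control$sigma0),
    prior = prior_spec(tau, control$dim, 1), control = control,
    call = cl), class = "ibflow")
  Xs <- standardize_features(model, dat$frames)

  with_seed(fan_seed(seed, 2L), {
    model$encoder <- mlp_init(ncol(Xs), control$dim, control$hidden_encoder)
    model$decoder <- mlp_init(control$dim, K, control$hidden_decoder)
    model$pseudo <- Xs[sample.int(nrow(Xs), control$n_pseudo), , drop = FALSE]
  })

  history <- list()
  opt_env <- new.env(parent = emptyenv())

  # ---- stage 1: vanilla baseline with iterative refinement ----
  with_seed(fan_seed(seed, 3L), {
    consecutive <- 0L
    for (it in seq_len(control$max_refine)) {
      model <- run_epochs(model, Xs, labels, pairs, dat$temps, control,
                          control$epochs_stage1, opt_env)
      history[[length(history) + 1L]] <-
        cbind(stage = 1, attr(model, "epoch_log"), n_states = K)
      new_labels <- decode_labels(model, dat$frames)
      changed <- mean(new_labels != labels)
      keep <- sort(unique(new_labels))
      if (length(keep) == 1L)
        stop("stage-1 state collapse: all frames assigned to one state; ",
             "reduce beta or the lag, or provide better initial labels")
      if (length(keep) < K) {
        model$decoder <- decoder_drop_states(model$decoder, keep)
        new_labels <- match(new_labels, keep)
        K <- length(keep)
        opt_env$state <- NULL  # decoder head changed shape
      }
      labels <- new_labels
      consecutive <- if (changed < control$tol_relabel) consecutive + 1L
                     else 0L
      if (consecutive >= 2L) break
    }
  })

  # ---- stage 2: joint training with the flow ----
  if (type == "ibflow") {
    model$type <- "ibflow"
    model$flow <- flow_init(control$dim, control$flow_blocks,
                            control$flow_hidden, control$s_max,
                            seed = fan_seed(seed, 4L))
    opt_env$state <- NULL
    with_seed(fan_seed(seed, 5L), {
      model <- run_epochs(model, Xs, labels, pairs, dat$temps, control,
                          control$epochs_stage2, opt_env)
    })
    history[[length(history) + 1L]] <-
      cbind(stage = 2, attr(model, "epoch_log"), n_states = K)
    if (control$epochs_polish > 0L) {
      with_seed(fan_seed(seed, 6L), {
        model$flow <- polish_flow(model, Xs, dat$temps, control)
      })
    }
    final <- refine_labels(model, dat$frames, current = labels)
    if (final$n_states < K) {
      keep <- sort(unique(decode_labels(model, dat$frames)))
      model$decoder <- decoder_drop_states(model$decoder, keep)
    }
    labels <- final$labels
    K <- final$n_states
  }

  attr(model, "epoch_log") <- NULL
  model$labels <- state_assignment(labels, K)
  model$n_states <- K
  model$latent <- encode(model, dat$frames)
  model$temperatures <- dat$temps
  model$train_kT <- dat$kT
  model$frame_interval <- dat$frame_interval
  model$segments <- dat$segments
  model$coords <- dat$coords
  hist <- as.data.frame(do.call(rbind, history))
  hist$epoch <- seq_len(nrow(hist))
  model$history <- hist
  model$pseudo <- if (model$type == "spib") model$pseudo else NULL
  model
}

# Samples from the VampPrior mixture of the baseline model: a uniformly
# chosen pseudo-input's encoding plus posterior-scale Gaussian noise.
generate_vamp <- function(model, n, seed = NULL) {
  if (is.null(model$pseudo) || nrow(model$pseudo) == 0L)
    stop("baseline model has no pseudo-inputs")
  e <- mlp_forward(model$encoder, model$pseudo)$out
  with_seed(seed, {
    comp <- sample.int(nrow(e), n, replace = TRUE)
    e[comp, , drop = FALSE] +
      exp(model$log_sigma) * matrix(rnorm(n * model$dim), n)
  })
}

# Flow-only maximum-likelihood refinement on the frozen representation:
# each epoch visits a fresh random subset of frames with fresh posterior
# draws, so the flow is fitted to the aggregated posterior itself rather
# than to one fixed draw.
polish_flow <- function(model, Xs, temps, control) {
  n <- nrow(Xs)
  multi_T <- length(unique(temps)) > 1L
  sigma <- exp(model$log_sigma)
  flow <- model$flow
  params <- flow_params(flow)
  opt <- adam_init(params)
  n_visit <- min(n, control$max_pairs_per_epoch)
  n_ep <- control$epochs_polish
  for (ep in seq_len(n_ep)) {
    # step-decay schedule over thirds of the refinement budget
    lr_ep <- control$lr * c(1, 0.4, 0.15)[1L + (3L * (ep - 1L)) %/% n_ep]
    idx <- if (n_visit < n) sample.int(n, n_visit) else sample.int(n)
    mu <- mlp_forward(model$encoder, Xs[idx, , drop = FALSE])$out
    u <- mu + sigma * matrix(rnorm(length(mu)), nrow(mu))
    for (start in seq(1L, n_visit, by = control$batch_size)) {
      rows <- start:min(start + control$batch_size - 1L, n_visit)
      ub <- u[rows, , drop = FALSE]
      fwd <- flow_forward_cached(flow, ub)
      gw <- if (multi_T)
        tilted_log_density_grad_multi(fwd$w, model$prior$tau, model$dim,
                                      temps[idx[rows]])
      else tilted_log_density_grad(fwd$w, model$prior)
      m <- length(rows)
      bk <- flow_backward(flow, fwd$caches, -gw / m, rep(-1 / m, m))
      st <- adam_step(params, bk$blocks, opt, lr = lr_ep)
      params <- st$params; opt <- st$state
      flow <- flow_set_params(flow, params)
    }
  }
  flow
}

# --- cross-validation utilities ------------------------------------------

# Split every trajectory into `folds` contiguous segments; fold i uses the
# i-th segment of each trajectory for validation and the rest for training.
make_folds <- function(x, folds) {
  trajs <- if (inherits(x, "feature_trajectory")) list(x) else x
  lapply(seq_len(folds), function(i) {
    train <- list(); val <- list()
    for (tr in trajs) {
      n <- nrow(tr$frames)
      bounds <- floor(seq(0, n, length.out = folds + 1L))
      lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
      mk <- function(rows) feature_trajectory(
        tr$frames[rows, , drop = FALSE], tr$frame_interval, tr$temperature,
        coords = if (is.null(tr$coords)) NULL
                 else tr$coords[rows, , drop = FALSE])
      val[[length(val) + 1L]] <- mk(lo:hi)
      if (i == 1L) train[[length(train) + 1L]] <- mk((hi + 1L):n)
      else if (i == folds) train[[length(train) + 1L]] <- mk(1L:(lo - 1L))
      else {
        train[[length(train) + 1L]] <- mk(1L:(lo - 1L))
        train[[length(train) + 1L]] <- mk((hi + 1L):n)
      }
    }
    list(train = train, val = val)
  })
}

#' Generation error of a fitted model on held-out data
#'
#' Symmetric KL divergence between generated latent samples and the latent
#' distribution the model assigns to the validation data (the aggregated
#' Gaussian posterior), averaged over the training temperatures. The flow
#' transports exactly the aggregated posterior, so that is the calibrated
#' reference; deterministic means would compare distributions at two
#' different smoothing scales.
#'
#' @param model A fitted full model.
#' @param val Validation data ([feature_trajectory()] or list of them).
#' @param n_generate Generated sample size per temperature.
#' @param seed Optional integer seed.
#' @param n_draws Posterior draws per validation frame used to estimate the
#'   reference histogram (lower-variance estimate of the same density).
#' @return The mean symmetric KL over training temperatures.
#' @export
generation_kl <- function(model, val, n_generate = 1e5, seed = NULL,
                          n_draws = 4L) {
  val_list <- if (inherits(val, "feature_trajectory")) list(val) else val
  steer <- temperature_scale(vapply(val_list, `[[`, numeric(1),
                                    "temperature"))
  kls <- vapply(seq_along(val_list), function(i) {
    mu <- encode(model, val_list[[i]]$frames)
    # several posterior draws per frame: a lower-variance Monte Carlo
    # estimate of the same aggregated-posterior histogram
    ref <- do.call(rbind, lapply(seq_len(n_draws), function(k)
      sample_posterior(mu, exp(model$log_sigma),
                       seed = fan_seed(seed, 1000L + 10L * i + k))))
    gen <- if (model$type == "ibflow") {
      generate_latent(model, n_generate, temperature = steer[i],
                      seed = fan_seed(seed, i), decode = FALSE)$z
    } else {
      generate_vamp(model, n_generate, seed = fan_seed(seed, i))
    }
    h_ref <- histogram_density(ref, ref)
    h_gen <- histogram_density(gen, ref)
    symmetric_kl(h_ref, h_gen)
  }, numeric(1))
  mean(kls)
}

#' Select the tilting factor by cross-validated generation error
#'
#' For every `tau` in the grid, trains the model on each cross-validation
#' fold (contiguous trajectory segments) and measures the symmetric KL
#' divergence between generated latent samples and the validation-encoded
#' distribution, averaged over folds and training temperatures. The `tau`
#' with the lowest mean divergence is selected.
#'
#' @param x Training data ([feature_trajectory()] or list).
#' @param tau_grid Candidate tilting factors (default 0, 0.5, ..., 5).
#' @param lag Lag in frames.
#' @param folds Number of contiguous cross-validation folds (>= 2).
#' @param k_init,init_space,control,seed As in [ibflow()].
#' @param n_generate Generated sample size per KL evaluation.
#' @return A list with `tau` (the argmin), `table` (per-tau mean and sd of
#'   the fold KLs) and `kl` (the folds x tau matrix). Folds that fail to
#'   train are recorded as `NA` with a warning and excluded from the
#'   averages.
#' @export
select_tau <- function(x, tau_grid = seq(0, 5, by = 0.5), lag = 10L,
                       folds = 5L, k_init = 6L,
                       init_space = c("features", "moments"),
                       control = ibflow_control(), seed = NULL,
                       n_generate = 20000L) {
  stopifnot(length(tau_grid) >= 1L, folds >= 2L)
  init_space <- match.arg(init_space)
  fold_data <- make_folds(x, folds)
  kl <- matrix(NA_real_, folds, length(tau_grid),
               dimnames = list(NULL, paste0("tau", tau_grid)))
  for (j in seq_along(tau_grid)) {
    for (i in seq_len(folds)) {
      fit <- tryCatch(
        ibflow(fold_data[[i]]$train, lag = lag, tau = tau_grid[j],
               k_init = k_init, init_space = init_space, control = control,
               seed = fan_seed(seed, 100L * j + i)),
        error = function(e) {
          warning(sprintf("fold %d failed for tau = %g: %s", i,
                          tau_grid[j], conditionMessage(e)))
          NULL
        })
      if (!is.null(fit))
        kl[i, j] <- generation_kl(fit, fold_data[[i]]$val, n_generate,
                                  seed = fan_seed(seed, 200L * j + i))
    }
  }
  mean_kl <- colMeans(kl, na.rm = TRUE)
  ok <- is.finite(mean_kl)
  if (!any(ok)) stop("no tau value trained successfully")
  tab <- data.frame(tau = tau_grid, mean_kl = mean_kl,
                    sd_kl = apply(kl, 2L, sd, na.rm = TRUE),
                    n_folds = colSums(is.finite(kl)))
  rownames(tab) <- NULL
  list(tau = tau_grid[ok][which.min(mean_kl[ok])], table = tab, kl = kl)
}

#' Cross-validated comparison against the vanilla baseline
#'
#' Trains the full model and the VampPrior baseline on each fold and
#' reports, per fold, the symmetric KL between generated and
#' validation-encoded latent distributions and the GMRQ score of the
#' decoded state assignment on the held-out segment.
#'
#' @inheritParams select_tau
#' @param tau Tilting factor for the full model.
#' @return A data frame with one row per fold: `kl_ibflow`, `kl_spib`,
#'   `gmrq_ibflow`, `gmrq_spib`, `n_states_ibflow`, `n_states_spib`.
#' @export
cv_benchmark <- function(x, tau = 2.5, lag = 10L, folds = 5L, k_init = 6L,
                         init_space = c("features", "moments"),
                         control = ibflow_control(), seed = NULL,
                         n_generate = 20000L) {
  init_space <- match.arg(init_space)
  fold_data <- make_folds(x, folds)
  rows <- vector("list", folds)
  for (i in seq_len(folds)) {
    fit_l <- ibflow(fold_data[[i]]$train, lag = lag, tau = tau,
                    k_init = k_init, init_space = init_space,
                    control = control, seed = fan_seed(seed, i))
    fit_s <- ibflow(fold_data[[i]]$train, lag = lag, tau = tau,
                    k_init = k_init, init_space = init_space, type = "spib",
                    control = control, seed = fan_seed(seed, i))
    kl_l <- generation_kl(fit_l, fold_data[[i]]$val, n_generate,
                          seed = fan_seed(seed, 300L + i))
    kl_s <- generation_kl(fit_s, fold_data[[i]]$val, n_generate,
                          seed = fan_seed(seed, 400L + i))
    k <- min(fit_l$n_states, fit_s$n_states)
    g_l <- fold_gmrq(fit_l, fold_data[[i]]$val, lag, k)
    g_s <- fold_gmrq(fit_s, fold_data[[i]]$val, lag, k)
    rows[[i]] <- data.frame(fold = i, kl_ibflow = kl_l, kl_spib = kl_s,
                            gmrq_ibflow = g_l, gmrq_spib = g_s,
                            n_states_ibflow = fit_l$n_states,
                            n_states_spib = fit_s$n_states)
  }
  do.call(rbind, rows)
}

fold_gmrq <- function(model, val, lag, k) {
  val_list <- if (inherits(val, "feature_trajectory")) list(val) else val
  labels <- unlist(lapply(val_list, function(v) decode_labels(model,
                                                             v$frames)))
  segments <- vapply(val_list, function(v) nrow(v$frames), integer(1))
  if (length(unique(labels)) < 2L) return(NA_real_)
  gmrq(labels, lag = lag, k = k, segments = segments)
}
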