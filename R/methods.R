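# S3 methods for fitted models.

#' @export
print.ibflow <- function(x, ...) {
  kind <- if (x$type == "ibflow") "latent-flow bottleneck model"
          else "vanilla time-lagged bottleneck (VampPrior baseline)"
  cat(kind, "\n")
  cat(sprintf("  features: %d, latent dim: %d, lag: %d frames\n",
              length(x$center), x$dim, x$lag))
  if (x$type == "ibflow")
    cat(sprintf("  prior: tilted Gaussian, tau = %g; flow: %d blocks\n",
                x$prior$tau, length(x$flow$blocks)))
  cat(sprintf("  states: %d, populations: %s\n", x$n_states,
              paste(sprintf("%.3f", x$labels$populations), collapse = " ")))
  cat(sprintf("  posterior scale sigma = %.4f, beta = %g\n",
              exp(x$log_sigma), x$beta))
  invisible(x)
}

#' @export
summary.ibflow <- function(object, ...) {
  h <- object$history
  out <- list(
    type = object$type, n_states = object$n_states,
    populations = object$labels$populations,
    sigma = exp(object$log_sigma), beta = object$beta,
    lag = object$lag, tau = object$prior$tau,
    train_kT = object$train_kT,
    final_loss = h$total[nrow(h)],
    final_reconstruction = h$reconstruction[nrow(h)],
    epochs = nrow(h))
  class(out) <- "summary.ibflow"
  out
}

#' @export
print.summary.ibflow <- function(x, ...) {
  cat(sprintf("%s fit: %d states, lag %d, tau %g, beta %g\n",
              if (x$type == "ibflow") "latent-flow" else "baseline",
              x$n_states, x$lag, x$tau, x$beta))
  cat(sprintf("  trained %d epochs; final loss %.4f (reconstruction %.4f)\n",
              x$epochs, x$final_loss, x$final_reconstruction))
  cat(sprintf("  posterior scale sigma = %.4f\n", x$sigma))
  cat("  state populations:",
      paste(sprintf("%.3f", x$populations), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.ibflow <- function(object, ...) {
  c(sigma = exp(object$log_sigma), beta = object$beta,
    tau = object$prior$tau, lag = object$lag,
    n_states = object$n_states)
}

#' Predict from a fitted model
#'
#' @param object A fitted [ibflow()] model.
#' @param newdata Descriptor matrix or [feature_trajectory()] (default: the
#'   training latent means are used where possible).
#' @param type `"latent"` (encoded means), `"prior"` (flow-forward images
#'   and log-determinants), `"prob"` (decoded state probabilities),
#'   `"class"` (hard state labels), or `"loglik"` (exact per-frame
#'   log-likelihood).
#' @param ... Unused.
#' @return Matrix, vector, or list according to `type`.
#' @export
predict.ibflow <- function(object, newdata = NULL,
                           type = c("latent", "prior", "prob", "class",
                                    "loglik"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) NULL else gather_frames(newdata)
  mu <- if (is.null(X)) object$latent else encode(object, X)
  switch(type,
    latent = mu,
    prior = flow_forward(object$flow, mu),
    prob = decode(object, mu),
    class = max.col(decode(object, mu), ties.method = "first"),
    loglik = {
      if (object$type != "ibflow") stop("loglik requires the flow model")
      flow_log_likelihood(object$flow, mu, object$prior)
    })
}

#' Simulate (generate) latent samples from a fitted model
#'
#' @param object A fitted full model.
#' @param nsim Number of samples.
#' @param seed Optional integer seed.
#' @param temperature Steerable temperature (default 1).
#' @param ... Passed to [generate_latent()].
#' @return A data frame with latent coordinates `z1..zd` and decoded `state`.
#' @export
simulate.ibflow <- function(object, nsim = 1L, seed = NULL,
                            temperature = 1, ...) {
  g <- generate_latent(object, nsim, temperature = temperature, seed = seed,
                       ...)
  out <- as.data.frame(g$z)
  names(out) <- paste0("z", seq_len(ncol(g$z)))
  out$state <- g$labels
  out
}

#' @export
logLik.ibflow <- function(object, ...) {
  if (object$type != "ibflow") stop("logLik requires the flow model")
  ll <- sum(flow_log_likelihood(object$flow, object$latent, object$prior))
  structure(ll, df = NA_integer_, nobs = nrow(object$latent),
            class = "logLik")
}

#' Plot a fitted model's latent space
#'
#' Scatter of the training latent means colored by metastable state, with
#' the free-energy surface of the latent density as filled contours
#' underneath.
#'
#' @param x A fitted model.
#' @param n_points Maximum number of latent points to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ibflow <- function(x, n_points = 5000L, ...) {
  z <- x$latent
  idx <- if (nrow(z) > n_points)
    round(seq(1L, nrow(z), length.out = n_points)) else seq_len(nrow(z))
  h <- histogram_density(z, z)
  f <- fes(h)
  graphics::image(attr(f, "x"), attr(f, "y"), f,
                  col = grDevices::hcl.colors(24, "YlGnBu", rev = TRUE),
                  xlab = "IB CV1", ylab = "IB CV2", ...)
  graphics::points(z[idx, 1], z[idx, 2], pch = 16, cex = 0.3,
                   col = x$labels$labels[idx] + 1L)
  invisible(x)
}
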