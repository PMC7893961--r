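#' Optimize model parameters by first-order gradient ascent (Adam)
#'
#' Point-optimizes the joint unnormalized log posterior with the Adam
#' optimizer, typically to obtain hyperparameter point estimates on a data
#' subset that are then frozen while the latent functions are sampled (the
#' optimize-then-sample workflow for large data sets). By default all state
#' entries are optimized jointly (whitened latents included); `params`
#' restricts the update to named blocks, holding the rest at `init`.
#'
#' @param model A [movement_model()].
#' @param data Trajectory, list of segments, or a [prepare_likelihood()]
#'   plan (use a subset of the data for speed).
#' @param params Character vector of state-block names to optimize
#'   (default: all).
#' @param init Named list of starting values (see [initial_state()]).
#' @param n_iter Number of Adam iterations.
#' @param lr Learning rate.
#' @param beta1,beta2,eps_adam Adam moment-decay and stabilization
#'   constants.
#' @return A list with `theta` (optimized scalar parameters, natural
#'   scale), `state` (full optimized state vector), `loss_trace` (negative
#'   log posterior per iteration) and `value`.
#' @export
optimize_hyperparameters <- function(model, data, params = NULL, init = list(),
                                     n_iter = 300, lr = 0.05,
                                     beta1 = 0.9, beta2 = 0.999,
                                     eps_adam = 1e-8) {
  plan <- if (inherits(data, "movegp_plan")) data else prepare_likelihood(model, data)
  x <- initial_state(model, init)
  d <- length(x)
  mask <- rep(TRUE, d)
  if (!is.null(params)) {
    mask <- rep(FALSE, d)
    for (nm in params) {
      e <- model$index$entries[[nm]]
      if (is.null(e)) stop("unknown state block: ", nm)
      mask[e$start:e$end] <- TRUE
    }
  }
  m1 <- m2 <- numeric(d)
  loss_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    lp <- log_posterior(x, model, plan, grad = TRUE)
    g <- -attr(lp, "gradient")        # gradient of the loss (negative lp)
    loss_trace[it] <- -as.numeric(lp)
    if (!is.finite(loss_trace[it]) || any(!is.finite(g[mask])))
      stop("optimization diverged (non-finite loss or gradient); ",
           "try a smaller learning rate")
    m1 <- beta1 * m1 + (1 - beta1) * g
    m2 <- beta2 * m2 + (1 - beta2) * g^2
    mh <- m1 / (1 - beta1^it)
    vh <- m2 / (1 - beta2^it)
    x[mask] <- x[mask] - lr * (mh / (sqrt(vh) + eps_adam))[mask]
  }
  sc <- vapply(model$index$entries, function(e) e$kind == "scalar", TRUE)
  theta <- stats::setNames(
    vapply(model$index$entries[sc], function(e) {
      v <- x[e$start]
      if (startsWith(e$name, "log_")) exp(v) else v
    }, 0),
    vapply(model$index$entries[sc], function(e)
      sub("^log_", "", e$name), ""))
  list(theta = theta, state = x, loss_trace = loss_trace,
       value = -loss_trace[n_iter])
}
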