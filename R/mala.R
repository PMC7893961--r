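#' Sampler configuration
#'
#' @param n_steps Total MCMC steps per chain.
#' @param n_burnin Burn-in steps (discarded; the step size and diagonal
#'   preconditioner adapt only during burn-in and are then frozen).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param initial_step_size Initial MALA step size.
#' @param target_acceptance Robbins-Monro target acceptance rate; 0.574 is
#'   the asymptotically optimal MALA acceptance.
#' @param init_sd Overdispersion of each chain's starting state: standard
#'   deviation in preconditioned coordinates (so starts are overdispersed
#'   relative to the posterior scale).
#' @param precondition Proposal preconditioning: `"laplace"` (default)
#'   fixes a dense preconditioner at the inverse curvature of a Laplace
#'   approximation found by gradient ascent before sampling; `"diag"`
#'   estimates a diagonal preconditioner adaptively from burn-in draws;
#'   `"none"` uses the identity.
#' @param seed Integer seed; each chain receives an independent sub-seed.
#' @return A list of class `movegp_sampler_config`.
#' @export
sampler_config <- function(n_steps = 10000, n_burnin = 2500, thin = 15,
                           n_chains = 4, initial_step_size = 0.5,
                           target_acceptance = 0.574, init_sd = 1,
                           precondition = c("laplace", "diag", "none"),
                           seed = 1) {
  stopifnot(n_burnin < n_steps, thin >= 1, n_chains >= 1,
            initial_step_size > 0, target_acceptance > 0, target_acceptance < 1)
  structure(list(n_steps = as.integer(n_steps), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 initial_step_size = initial_step_size,
                 target_acceptance = target_acceptance, init_sd = init_sd,
                 precondition = match.arg(precondition),
                 seed = as.integer(seed)),
            class = "movegp_sampler_config")
}

# model with every latent switched to the given parameterization
set_parameterization <- function(model, parameterization) {
  for (nm in c("sigma", "L", "mean"))
    if (model[[nm]]$type == "latent")
      model[[nm]]$latent$parameterization <- parameterization
  model$index <- build_state_index(model)
  model
}

# translate a whitened-coordinate state into `model`'s own coordinates:
# centered blocks become f = mu + R(theta) w; everything else is shared
state_from_whitened <- function(model, model_w, state_w) {
  x <- numeric(model$index$d)
  names(x) <- model$index$names
  for (e in model$index$entries) {
    if (e$kind == "f") {
      nm <- sub("^f_", "", e$name)
      comp_name <- if (nm %in% c("mean_x", "mean_y")) "mean" else nm
      lat <- model[[comp_name]]$latent
      w <- slice_state(state_w, model_w$index, paste0("w_", nm))
      mu <- if (identical(lat$mu, "estimate"))
        slice_state(state_w, model_w$index, paste0("mu_", comp_name))
      else if (comp_name == "mean") 0 else lat$mu
      hn <- estimated_params(lat$kernel)
      hyper <- stats::setNames(vapply(hn, function(h)
        exp(slice_state(state_w, model_w$index,
                        paste0("log_", h, "_", comp_name))), 0), hn)
      kern <- if (length(hyper)) fill_kernel(lat$kernel, as.list(hyper)) else lat$kernel
      f <- chol_with_jitter(kernel_matrix(kern, lat$support_times))
      x[e$start:e$end] <- mu + as.numeric(crossprod(f$U, w))
    } else {
      x[e$start:e$end] <- slice_state(state_w, model_w$index, e$name)
    }
  }
  x
}

# Dense preconditioner from the curvature of a Laplace approximation at the
# MAP: M ~ (-H)^{-1} with the spectrum clipped so no direction proposes with
# more than the largest prior variance or less than ~1e-8 of it. The mode
# is located in whitened coordinates (where the objective is well
# conditioned) by L-BFGS on the analytic gradient, then translated into the
# model's own coordinates for the curvature evaluation.
laplace_preconditioner <- function(model, plan, init = list(), maxit = 600) {
  model_w <- set_parameterization(model, "whitened")
  x_start <- initial_state(model_w, init[names(init) %in%
                                          names(model_w$index$entries)])
  opt <- stats::optim(x_start,
                      fn = function(x) tryCatch(
                        -log_posterior(x, model_w, plan, grad = FALSE),
                        error = function(e) 1e10),
                      gr = function(x) tryCatch(
                        -attr(log_posterior(x, model_w, plan), "gradient"),
                        error = function(e) numeric(length(x))),
                      method = "L-BFGS-B", control = list(maxit = maxit))
  x0 <- state_from_whitened(model, model_w, opt$par)
  names(x0) <- model$index$names
  if (any(vapply(model$index$entries, function(e) e$kind == "f", TRUE))) {
    # the centered posterior carries an extra Jacobian term, so the mapped
    # whitened mode is only a warm start: polish in the model's coordinates
    opt2 <- stats::optim(x0,
                         fn = function(x) tryCatch(
                           -log_posterior(x, model, plan, grad = FALSE),
                           error = function(e) 1e10),
                         gr = function(x) tryCatch(
                           -attr(log_posterior(x, model, plan), "gradient"),
                           error = function(e) numeric(length(x))),
                         method = "L-BFGS-B", control = list(maxit = maxit))
    x0 <- opt2$par
  }
  d <- length(x0)
  h <- 1e-3
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    gp <- attr(log_posterior(xp, model, plan), "gradient")
    gm <- attr(log_posterior(xm, model, plan), "gradient")
    H[i, ] <- (gp - gm) / (2 * h)
  }
  H <- (H + t(H)) / 2
  e <- eigen(-H, symmetric = TRUE)
  pv_max <- max(1, model$prior_sd^2)   # largest prior variance in the state
  lam <- pmin(pmax(e$values, 1 / pv_max), 1e8 / pv_max)
  list(type = "dense", V = e$vectors, lam = lam, map = x0)
}

precond_sqrt_mult <- function(P, z) {
  # returns M^{1/2} z
  if (is.null(P) || (is.numeric(P) && !is.list(P))) return(sqrt(P) * z)
  P$V %*% (z / sqrt(P$lam))
}

precond_mult <- function(P, v) {
  if (is.null(P) || (is.numeric(P) && !is.list(P))) return(P * v)
  P$V %*% (crossprod(P$V, v) / P$lam)
}

precond_quad <- function(P, r) {
  # r' M^{-1} r
  if (is.null(P) || (is.numeric(P) && !is.list(P))) return(sum(r^2 / P))
  sum(crossprod(P$V, r)^2 * P$lam)
}

#' One Metropolis-adjusted Langevin step
#'
#' Proposes `x' = x + (eps^2/2) M grad(x) + eps sqrt(M) xi` with `xi`
#' standard normal and `M` a diagonal preconditioner, and accepts with the
#' Metropolis-Hastings ratio including the asymmetric Langevin proposal
#' densities. A proposal where the target (or its gradient) is not finite
#' is rejected.
#'
#' @param state Current state vector.
#' @param logpost Function of the state returning the log target with
#'   attribute `"gradient"`.
#' @param step_size Step size `eps > 0`.
#' @param precond Preconditioner `M`: a vector (diagonal), scalar 1, or the
#'   dense object produced by the Laplace preconditioner.
#' @param current Optional cached `list(value, grad)` at `state`.
#' @return `list(state, current = list(value, grad), accepted, log_ratio)`.
#' @export
mala_step <- function(state, logpost, step_size, precond = 1, current = NULL) {
  stopifnot(step_size > 0)
  if (is.null(current)) {
    lp <- logpost(state)
    current <- list(value = as.numeric(lp), grad = attr(lp, "gradient"))
  }
  if (!is.finite(current$value) || any(!is.finite(current$grad)))
    stop("non-finite log posterior or gradient at the current state; state = ",
         paste(signif(utils::head(state, 10), 4), collapse = ", "), " ...")
  d <- length(state)
  e2 <- step_size^2
  fwd_mean <- state + 0.5 * e2 * as.numeric(precond_mult(precond, current$grad))
  prop <- fwd_mean + step_size * as.numeric(precond_sqrt_mult(precond, stats::rnorm(d)))
  lp_prop <- tryCatch(logpost(prop), error = function(e) -Inf)
  val_prop <- as.numeric(lp_prop)
  grad_prop <- attr(lp_prop, "gradient")
  ok <- is.finite(val_prop) && !is.null(grad_prop) && all(is.finite(grad_prop))
  if (ok) {
    rev_mean <- prop + 0.5 * e2 * as.numeric(precond_mult(precond, grad_prop))
    log_q_fwd <- -0.5 * precond_quad(precond, prop - fwd_mean) / e2
    log_q_rev <- -0.5 * precond_quad(precond, state - rev_mean) / e2
    log_ratio <- val_prop - current$value + log_q_rev - log_q_fwd
  } else log_ratio <- -Inf
  if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
    list(state = prop, current = list(value = val_prop, grad = grad_prop),
         accepted = TRUE, log_ratio = log_ratio)
  } else {
    list(state = state, current = current, accepted = FALSE,
         log_ratio = log_ratio)
  }
}

#' Sample the posterior with independent adaptive MALA chains
#'
#' Runs `n_chains` chains of the Metropolis-adjusted Langevin algorithm on
#' the whitened joint posterior. Under the default `"laplace"`
#' preconditioning the proposal covariance is fixed at the inverse
#' curvature of a Laplace approximation located by Adam before sampling,
#' and chains start overdispersed around the mode. During burn-in the step
#' size follows a Robbins-Monro recursion towards the target acceptance
#' rate (with `"diag"` preconditioning a diagonal preconditioner is also
#' estimated from trailing windows of the burn-in draws); all adaptation is
#' frozen when burn-in ends. Post-burn-in draws are thinned by `thin`.
#'
#' @param model A [movement_model()].
#' @param data Trajectory, list of segments, or a [prepare_likelihood()]
#'   plan.
#' @param config A [sampler_config()].
#' @param init Named list of state-block initial values (see
#'   [initial_state()]); each chain adds `N(0, init_sd^2)` jitter.
#' @param progress Print a line per chain?
#' @return A `movegp_samples` object: `draws` array
#'   (chain x draw x parameter), acceptance rates, step-size traces, the
#'   config and seed.
#' @export
run_chains <- function(model, data, config = sampler_config(), init = list(),
                       progress = interactive()) {
  plan <- if (inherits(data, "movegp_plan")) data else prepare_likelihood(model, data)
  logpost <- function(x) log_posterior(x, model, plan, grad = TRUE)
  base_init <- initial_state(model, init)
  d <- model$index$d
  P0 <- switch(config$precondition,
    laplace = {
      lp <- laplace_preconditioner(model, plan, init = init)
      base_init <- lp$map
      lp
    },
    diag = rep(1, d),
    none = rep(1, d))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  n_keep <- (config$n_steps - config$n_burnin) %/% config$thin
  draws <- array(NA_real_, c(config$n_chains, n_keep, d),
                 dimnames = list(NULL, NULL, model$index$names))
  acc_rate <- step_sizes <- numeric(config$n_chains)
  step_trace <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    t0 <- proc.time()[3]
    set.seed(chain_seeds[ch])
    x <- unname(base_init) +
      as.numeric(precond_sqrt_mult(P0, stats::rnorm(d, 0, config$init_sd)))
    cur <- NULL
    # fall back towards the prior centre if the jittered start is infeasible
    for (try in 1:20) {
      lp <- tryCatch(logpost(x), error = function(e) -Inf)
      if (is.finite(as.numeric(lp)) && all(is.finite(attr(lp, "gradient") %||% NaN))) {
        cur <- list(value = as.numeric(lp), grad = attr(lp, "gradient"))
        break
      }
      x <- x / 2
    }
    if (is.null(cur)) stop("could not find a feasible starting state for chain ", ch)
    eps <- config$initial_step_size
    M <- P0
    adapt_diag <- config$precondition == "diag"
    burn_store <- if (adapt_diag) matrix(NA_real_, config$n_burnin, d)
    n_acc <- 0L; recent <- integer(0)
    trace <- numeric(0)
    kd <- 0L
    adapt_k <- 0L
    for (k in seq_len(config$n_steps)) {
      st <- mala_step(x, logpost, eps, M, current = cur)
      x <- st$state; cur <- st$current
      alpha <- min(1, exp(st$log_ratio))
      if (is.na(alpha)) alpha <- 0
      if (k <= config$n_burnin) {
        adapt_k <- adapt_k + 1L
        gain <- max(adapt_k^-0.6, 0.01)
        eps <- eps * exp(gain * (alpha - config$target_acceptance))
        if (adapt_diag) {
          burn_store[k, ] <- x
          half <- config$n_burnin %/% 2L; three_q <- (3L * config$n_burnin) %/% 4L
          if (k == half || k == three_q) {
            win <- burn_store[max(1L, k - half %/% 2L):k, , drop = FALSE]
            v <- apply(win, 2, stats::var)
            if (all(is.finite(v)) && any(v > 0)) {
              M <- pmax(v, 1e-8 * max(v))
              adapt_k <- 100L   # let the step size re-equilibrate quickly
            }
          }
        }
        if (k %% 50 == 0) trace <- c(trace, eps)
      } else {
        n_acc <- n_acc + st$accepted
        recent <- c(recent, st$accepted)
        if (length(recent) == 200L) {
          if (mean(recent) < 0.01)
            warning("chain ", ch, ": acceptance below 1% over the last 200 steps",
                    call. = FALSE)
          recent <- integer(0)
        }
        if ((k - config$n_burnin) %% config$thin == 0L) {
          kd <- kd + 1L
          draws[ch, kd, ] <- x
        }
      }
    }
    acc_rate[ch] <- n_acc / (config$n_steps - config$n_burnin)
    step_sizes[ch] <- eps
    step_trace[[ch]] <- trace
    if (progress)
      message(sprintf("chain %d: acceptance %.2f, step size %.3g, %.1fs",
                      ch, acc_rate[ch], eps, proc.time()[3] - t0))
  }
  structure(list(draws = draws, acceptance = acc_rate,
                 step_size = step_sizes, step_trace = step_trace,
                 config = config, seed = config$seed,
                 chain_seeds = chain_seeds,
                 param_names = model$index$names),
            class = "movegp_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.movegp_samples <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("<posterior samples: %d chains x %d draws x %d parameters; mean acceptance %.2f>\n",
              dm[1], dm[2], dm[3], mean(x$acceptance)))
  invisible(x)
}

#' Extract draws of one parameter block, on a transformed scale
#'
#' @param samples A `movegp_samples` object.
#' @param pattern Regular expression matched against parameter names.
#' @param pool Collapse chains into one matrix?
#' @return If `pool`, a (chains*draws) x k matrix; otherwise the raw
#'   subarray.
#' @export
extract_draws <- function(samples, pattern, pool = TRUE) {
  sel <- grep(pattern, samples$param_names)
  if (!length(sel)) stop("no parameters match ", pattern)
  out <- samples$draws[, , sel, drop = FALSE]
  if (!pool) return(out)
  dm <- dim(out)
  mat <- matrix(aperm(out, c(2, 1, 3)), dm[1] * dm[2], dm[3])
  colnames(mat) <- samples$param_names[sel]
  mat
}
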