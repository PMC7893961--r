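#' Specify a hierarchical movement model
#'
#' Assembles the multilevel model for a 2-D trajectory (positions or
#' velocities) observed with white measurement noise: the observations are a
#' bivariate Gaussian process whose two coordinates are modelled as
#' independent univariate GPs sharing a non-stationary Matern 1/2 covariance
#' with amplitude `sigma(t)` and lengthscale `L(t)`, plus per-coordinate
#' mean functions. Any of `sigma`, `L` and `mean` may be dynamic (a
#' [latent_gp()]), a constant to be estimated, or fixed.
#'
#' @param sigma Kernel amplitude (standard-deviation scale; the marginal
#'   variance of the process is `sigma(t)^2`): a [latent_gp()] with
#'   exponential transform, the string `"estimate"` (constant, sampled on
#'   the log scale), or a fixed positive number.
#' @param L Correlation lengthscale: same choices as `sigma`.
#' @param mean Mean location: `NULL` (fixed at zero) or a [latent_gp()] with
#'   identity transform and `mu = 0`, applied independently to the x and y
#'   coordinates (separate whitened vectors, shared kernel).
#' @param sigma_m Measurement-noise standard deviation: a fixed number
#'   `>= 0` or `"estimate"`.
#' @param prior_sd Standard deviation of the independent normal priors
#'   placed on every sampled scalar (log-hyperparameters, log-constants,
#'   latent prior means, log sigma_m).
#' @return An object of class `movegp_model`.
#' @examples
#' m <- movement_model(
#'   sigma = latent_gp(periodic_kernel(a = "estimate", l = "estimate", P = 24),
#'                     support_times = place_support_points(0, 24, 40, periodic = TRUE)),
#'   L = "estimate")
#' @export
movement_model <- function(sigma, L, mean = NULL, sigma_m = 0, prior_sd = 2) {
  norm_pos <- function(x, nm) {
    if (inherits(x, "movegp_latent")) {
      if (x$transform != "exponential")
        stop(nm, " latent must use the exponential transform")
      list(type = "latent", latent = x)
    } else if (identical(x, "estimate")) {
      list(type = "constant")
    } else if (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0) {
      list(type = "fixed", value = as.numeric(x))
    } else stop(nm, " must be a latent_gp, \"estimate\", or a positive number")
  }
  sigma <- norm_pos(sigma, "sigma")
  L <- norm_pos(L, "L")
  if (is.null(mean)) {
    mean <- list(type = "zero")
  } else if (inherits(mean, "movegp_latent")) {
    if (mean$transform != "identity")
      stop("mean latent must use the identity transform")
    if (!identical(mean$mu, 0))
      stop("mean latent must have mu = 0")
    mean <- list(type = "latent", latent = mean)
  } else stop("mean must be NULL (zero) or a latent_gp")
  if (identical(sigma_m, "estimate")) {
    sigma_m <- list(type = "constant")
  } else if (is.numeric(sigma_m) && length(sigma_m) == 1L && sigma_m >= 0) {
    sigma_m <- list(type = "fixed", value = as.numeric(sigma_m))
  } else stop("sigma_m must be a non-negative number or \"estimate\"")
  stopifnot(is.numeric(prior_sd), prior_sd > 0)
  model <- structure(list(sigma = sigma, L = L, mean = mean, sigma_m = sigma_m,
                          prior_sd = prior_sd),
                     class = "movegp_model")
  model$index <- build_state_index(model)
  model
}

#' @export
print.movegp_model <- function(x, ...) {
  desc <- function(comp) switch(comp$type,
    latent = sprintf("latent GP (%s kernel, %d support points)",
                     comp$latent$kernel$type, length(comp$latent$support_times)),
    constant = "constant (estimated)",
    fixed = sprintf("fixed at %g", comp$value),
    zero = "fixed at zero")
  cat("<movement model>\n",
      "  sigma:   ", desc(x$sigma), "\n",
      "  L:       ", desc(x$L), "\n",
      "  mean:    ", desc(x$mean), "\n",
      "  sigma_m: ", desc(x$sigma_m), "\n",
      "  ", x$index$d, " sampled unknowns\n", sep = "")
  invisible(x)
}

# ---- state indexing --------------------------------------------------------

# The model state is a flat named vector of every sampled unknown: whitened
# latent vectors, latent prior means, log kernel hyperparameters,
# log-constants and log sigma_m. build_state_index() records the layout.
build_state_index <- function(model) {
  entries <- list()
  add <- function(name, len, kind, comp, param = NA_character_) {
    entries[[length(entries) + 1L]] <<- list(name = name, len = len, kind = kind,
                                             comp = comp, param = param)
  }
  latent_prefix <- function(lat)
    if (lat$parameterization == "centered") "f_" else "w_"
  latent_kind <- function(lat)
    if (lat$parameterization == "centered") "f" else "w"
  add_pos_comp <- function(comp, nm) {
    if (comp$type == "latent") {
      lat <- comp$latent
      add(paste0(latent_prefix(lat), nm), length(lat$support_times),
          latent_kind(lat), nm)
      if (identical(lat$mu, "estimate")) add(paste0("mu_", nm), 1L, "scalar", nm, "mu")
      for (h in estimated_params(lat$kernel))
        add(paste0("log_", h, "_", nm), 1L, "scalar", nm, h)
    } else if (comp$type == "constant") {
      add(paste0("log_", nm), 1L, "scalar", nm, "const")
    }
  }
  add_pos_comp(model$sigma, "sigma")
  add_pos_comp(model$L, "L")
  if (model$mean$type == "latent") {
    lat <- model$mean$latent
    add(paste0(latent_prefix(lat), "mean_x"), length(lat$support_times),
        latent_kind(lat), "mean")
    add(paste0(latent_prefix(lat), "mean_y"), length(lat$support_times),
        latent_kind(lat), "mean")
    for (h in estimated_params(lat$kernel))
      add(paste0("log_", h, "_mean"), 1L, "scalar", "mean", h)
  }
  if (model$sigma_m$type == "constant") add("log_sigma_m", 1L, "scalar", "sigma_m", "const")
  if (length(entries) == 0L) stop("model has no sampled unknowns")
  lens <- vapply(entries, `[[`, 1L, "len")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(entries)) {
    entries[[i]]$start <- starts[i]; entries[[i]]$end <- ends[i]
  }
  names(entries) <- vapply(entries, `[[`, "", "name")
  nm <- unlist(lapply(entries, function(e)
    if (e$len == 1L) e$name else sprintf("%s[%d]", e$name, seq_len(e$len))))
  list(entries = entries, d = sum(lens), names = unname(nm))
}

#' Parameter names of a model's sampled state
#'
#' @param model A [movement_model()].
#' @return Character vector naming every entry of the flat state vector.
#' @export
state_names <- function(model) model$index$names

#' Initial state vector for a model
#'
#' Returns the default starting point (whitened vectors and scalars at 0,
#' i.e. latents at their prior mean and scalars at their prior centre),
#' optionally overridden entry-wise.
#'
#' @param model A [movement_model()].
#' @param init Named list of overrides, keyed by block name (e.g.
#'   `log_L = -2` or `w_sigma = rep(0.1, 40)`).
#' @return Named numeric state vector.
#' @export
initial_state <- function(model, init = list()) {
  x <- numeric(model$index$d)
  names(x) <- model$index$names
  for (nm in names(init)) {
    e <- model$index$entries[[nm]]
    if (is.null(e)) stop("unknown state block: ", nm)
    v <- as.numeric(init[[nm]])
    if (!length(v) %in% c(1L, e$len)) stop("bad length for init block ", nm)
    x[e$start:e$end] <- v
  }
  x
}

#' Split a flat state vector into a named list of blocks
#'
#' Useful for feeding one run's result into another as `init` (e.g. warm
#' starting the optimizer).
#'
#' @param model A [movement_model()].
#' @param state Flat state vector for `model`.
#' @return Named list with one numeric vector per state block.
#' @export
state_blocks <- function(model, state) {
  lapply(model$index$entries, function(e) unname(state[e$start:e$end]))
}

slice_state <- function(state, index, name) {
  e <- index$entries[[name]]
  if (is.null(e)) NULL else state[e$start:e$end]
}

# Structured view of a flat state vector.
unpack_state <- function(state, model) {
  idx <- model$index
  if (length(state) != idx$d) stop("state has wrong length")
  get_pos_comp <- function(comp, nm) {
    if (comp$type == "fixed") return(list(type = "fixed", value = comp$value))
    if (comp$type == "constant")
      return(list(type = "constant", value = exp(slice_state(state, idx, paste0("log_", nm)))))
    lat <- comp$latent
    pre <- if (lat$parameterization == "centered") "f_" else "w_"
    mu <- if (identical(lat$mu, "estimate")) slice_state(state, idx, paste0("mu_", nm)) else lat$mu
    hn <- estimated_params(lat$kernel)
    hyper <- stats::setNames(vapply(hn, function(h)
      exp(slice_state(state, idx, paste0("log_", h, "_", nm))), 0), hn)
    list(type = "latent", latent = lat, block = paste0(pre, nm),
         coef = slice_state(state, idx, paste0(pre, nm)),
         mu = unname(mu), hyper = hyper)
  }
  out <- list(sigma = get_pos_comp(model$sigma, "sigma"),
              L = get_pos_comp(model$L, "L"))
  if (model$mean$type == "latent") {
    lat <- model$mean$latent
    pre <- if (lat$parameterization == "centered") "f_" else "w_"
    hn <- estimated_params(lat$kernel)
    hyper <- stats::setNames(vapply(hn, function(h)
      exp(slice_state(state, idx, paste0("log_", h, "_mean"))), 0), hn)
    out$mean <- list(type = "latent", latent = lat,
                     blockx = paste0(pre, "mean_x"), blocky = paste0(pre, "mean_y"),
                     wx = slice_state(state, idx, paste0(pre, "mean_x")),
                     wy = slice_state(state, idx, paste0(pre, "mean_y")),
                     hyper = hyper)
  } else out$mean <- list(type = "zero")
  out$sigma_m <- if (model$sigma_m$type == "fixed") model$sigma_m$value
                 else exp(slice_state(state, idx, "log_sigma_m"))
  out
}

# ---- likelihood plan (local GP experts, with covariance sharing) -----------

#' Prepare trajectory segments for likelihood evaluation
#'
#' Groups conditionally independent segments that provably share the same
#' covariance matrix under the model -- segments whose relative time grids
#' coincide and whose dynamic latents are all strictly periodic with the
#' segments' start times congruent modulo the period (or constant). For
#' such groups the Cholesky factorization is computed once per posterior
#' evaluation regardless of the number of segments, which is what makes
#' long multi-day fits tractable.
#'
#' @param model A [movement_model()].
#' @param data A [trajectory()] or list of trajectories/segments (e.g. from
#'   [segment_trajectory()]).
#' @return A likelihood plan (class `movegp_plan`).
#' @export
prepare_likelihood <- function(model, data) {
  if (inherits(data, "movegp_trajectory")) data <- list(data)
  if (!length(data)) stop("no trajectory data supplied")
  stopifnot(all(vapply(data, inherits, TRUE, "movegp_trajectory")))
  dyn <- list()
  for (nm in c("sigma", "L", "mean"))
    if (model[[nm]]$type == "latent") dyn[[nm]] <- model[[nm]]$latent
  groupable_latent <- function(lat) lat$kernel$type == "periodic"
  keys <- vapply(seq_along(data), function(i) {
    tr <- data[[i]]
    rel <- tr$times - tr$times[1L]
    parts <- paste(round(rel, 9), collapse = ",")
    for (lat in dyn) {
      parts <- paste(parts, if (groupable_latent(lat))
        round(tr$times[1L] %% lat$kernel$params$P, 9) else i)
    }
    parts
  }, "")
  groups <- lapply(split(seq_along(data), keys), function(ii) {
    times <- data[[ii[1L]]]$times
    n <- length(times)
    Y <- matrix(0, n, 2L * length(ii))
    for (k in seq_along(ii)) Y[, c(2L * k - 1L, 2L * k)] <- data[[ii[k]]]$values
    list(times = times, d = abs(outer(times, times, "-")), Y = Y,
         xcols = seq(1L, 2L * length(ii), by = 2L),
         ycols = seq(2L, 2L * length(ii), by = 2L),
         n = n, q = 2L * length(ii), nseg = length(ii), members = ii)
  })
  structure(list(groups = unname(groups),
                 n_total = sum(vapply(data, function(tr) length(tr$times), 0L)),
                 n_segments = length(data)),
            class = "movegp_plan")
}

#' @export
print.movegp_plan <- function(x, ...) {
  cat(sprintf("<likelihood plan: %d segments (%d points) in %d covariance group(s)>\n",
              x$n_segments, x$n_total, length(x$groups)))
  invisible(x)
}

# Gaussian log-likelihood (and gradients) of one covariance group: q column
# vectors sharing C = K_NS + sigma_m^2 I. Gradients follow from
# dll/dC = (sum_k alpha_k alpha_k' - q C^{-1}) / 2 with alpha = C^{-1} y.
loglik_group <- function(g, sigma_t, L_t, mean_x, mean_y, sigma_m, grad = TRUE) {
  L2 <- L_t^2
  u <- outer(L2, L2, "+")
  K <- sqrt(2 * outer(sigma_t^2 * L_t, sigma_t^2 * L_t) / u) *
    exp(-sqrt(2) * g$d / sqrt(u))
  C <- K
  diag(C) <- diag(C) + sigma_m^2
  f <- chol_with_jitter(C)
  Yc <- g$Y
  if (!is.null(mean_x)) {
    Yc[, g$xcols] <- Yc[, g$xcols] - mean_x
    Yc[, g$ycols] <- Yc[, g$ycols] - mean_y
  }
  Cinv <- chol2inv(f$U)
  Alpha <- Cinv %*% Yc
  ll <- -0.5 * g$q * g$n * log(2 * pi) - 0.5 * g$q * f$logdet -
    0.5 * sum(Yc * Alpha)
  if (!grad) return(list(ll = ll))
  G <- 0.5 * (tcrossprod(Alpha) - g$q * Cinv)
  GK <- G * K
  rsGK <- rowSums(GK)
  gsig <- 2 * rsGK / sigma_t
  gL <- rsGK / L_t - 2 * L_t * rowSums(GK / u) +
    2 * sqrt(2) * L_t * rowSums(GK * g$d / u^1.5)
  list(ll = ll,
       gsig = gsig, gL = gL,
       gmx = rowSums(Alpha[, g$xcols, drop = FALSE]),
       gmy = rowSums(Alpha[, g$ycols, drop = FALSE]),
       gsm = 2 * sigma_m * sum(diag(G)))
}

#' Gaussian-process data log-likelihood of a 2-D series
#'
#' Evaluates the log density of a bivariate series under the non-stationary
#' Matern 1/2 model: both coordinates share the covariance
#' `K_NS + sigma_m^2 I` built from `sigma_t` and `L_t`, with per-coordinate
#' means.
#'
#' @param times Observation times (or a [trajectory()], in which case its
#'   times and values are used).
#' @param values `n` x 2 matrix of observations (ignored when `times` is a
#'   trajectory).
#' @param sigma_t,L_t Amplitude and lengthscale at `times` (scalars are
#'   recycled).
#' @param mean_t `n` x 2 matrix of means, or `NULL` for zero.
#' @param sigma_m Measurement-noise sd.
#' @return The log-likelihood (scalar).
#' @export
log_data_likelihood <- function(times, values = NULL, sigma_t, L_t,
                                mean_t = NULL, sigma_m = 0) {
  if (inherits(times, "movegp_trajectory")) {
    values <- times$values; times <- times$times
  }
  times <- as.numeric(times)
  values <- as.matrix(values)
  n <- length(times)
  if (nrow(values) != n || ncol(values) != 2L) stop("values must be n x 2")
  if (length(sigma_t) == 1L) sigma_t <- rep(sigma_t, n)
  if (length(L_t) == 1L) L_t <- rep(L_t, n)
  if (length(sigma_t) != n || length(L_t) != n)
    stop("sigma_t and L_t must align with times")
  if (any(sigma_t <= 0) || any(L_t <= 0)) stop("sigma_t and L_t must be positive")
  g <- list(times = times, d = abs(outer(times, times, "-")), Y = values,
            xcols = 1L, ycols = 2L, n = n, q = 2L)
  mx <- my <- NULL
  if (!is.null(mean_t)) {
    mean_t <- as.matrix(mean_t)
    if (nrow(mean_t) != n || ncol(mean_t) != 2L) stop("mean_t must be n x 2")
    mx <- mean_t[, 1L]; my <- mean_t[, 2L]
  }
  loglik_group(g, sigma_t, L_t, mx, my, sigma_m, grad = FALSE)$ll
}

# ---- joint posterior -------------------------------------------------------

# step used for the finite-difference chain through the latent-realization
# map with respect to log kernel hyperparameters
FD_EPS <- 1e-4

#' Joint unnormalized log posterior (whitened coordinates) with gradient
#'
#' Sums the per-segment data log-likelihoods (segments and individuals are
#' conditionally independent given the latent functions), the latent GP
#' priors -- standard normal log densities of the whitened vectors for
#' whitened latents, the multivariate normal support-value prior for
#' centered ones -- and the normal priors on all sampled scalars. The gradient with respect to every state entry is returned as
#' attribute `"gradient"`: analytic throughout, except that the Jacobian of
#' the (cheap) latent-realization map with respect to log kernel
#' hyperparameters is formed by central differences.
#'
#' @param state Flat named state vector (see [initial_state()]).
#' @param model A [movement_model()].
#' @param data Trajectory, list of segments, or a [prepare_likelihood()]
#'   plan.
#' @param grad Compute the gradient?
#' @return Scalar log posterior; if `grad = TRUE`, with attribute
#'   `"gradient"`.
#' @export
log_posterior <- function(state, model, data, grad = TRUE) {
  plan <- if (inherits(data, "movegp_plan")) data else prepare_likelihood(model, data)
  up <- unpack_state(state, model)
  idx <- model$index
  ng <- length(plan$groups)

  # realize each component on every group's time grid
  comp_vals <- list()  # comp -> list over groups of list(value, s, B, A1)
  for (nm in c("sigma", "L")) {
    cv <- up[[nm]]
    comp_vals[[nm]] <- lapply(plan$groups, function(g) {
      if (cv$type == "latent")
        realize_latent_core(cv$latent, cv$coef, g$times, cv$mu, cv$hyper,
                            jacobian = grad, warn_extrapolation = FALSE)
      else list(value = rep(cv$value, g$n))
    })
  }
  if (up$mean$type == "latent") {
    lat <- up$mean$latent
    comp_vals$mean <- lapply(plan$groups, function(g) {
      rx <- realize_latent_core(lat, up$mean$wx, g$times, 0, up$mean$hyper,
                                jacobian = grad, warn_extrapolation = FALSE)
      # the two coordinates share the kernel, so the x-latent's Jacobian
      # realizes the y coordinate too (mu = 0 for mean latents)
      my <- if (grad) as.numeric(rx$B %*% up$mean$wy)
            else realize_latent_core(lat, up$mean$wy, g$times, 0, up$mean$hyper,
                                     jacobian = FALSE,
                                     warn_extrapolation = FALSE)$value
      list(mx = rx$value, my = my, B = rx$B)
    })
  }

  ll <- 0
  gr_groups <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- plan$groups[[i]]
    mx <- my <- NULL
    if (up$mean$type == "latent") {
      mx <- comp_vals$mean[[i]]$mx; my <- comp_vals$mean[[i]]$my
    }
    res <- loglik_group(g, comp_vals$sigma[[i]]$value, comp_vals$L[[i]]$value,
                        mx, my, up$sigma_m, grad = grad)
    ll <- ll + res$ll
    gr_groups[[i]] <- res
  }

  # priors on whitened vectors and sampled scalars; centered latents carry
  # their GP prior, handled with the component chain below
  lp <- ll
  gvec <- if (grad) numeric(idx$d) else NULL
  cent_priors <- list()
  for (e in idx$entries) {
    v <- unname(state[e$start:e$end])
    if (e$kind == "w") {
      lp <- lp - 0.5 * sum(v^2) - 0.5 * e$len * log(2 * pi)
      if (grad) gvec[e$start:e$end] <- -v
    } else if (e$kind == "scalar") {
      lp <- lp + stats::dnorm(v, 0, model$prior_sd, log = TRUE)
      if (grad) gvec[e$start:e$end] <- -v / model$prior_sd^2
    }
  }
  for (nm in c("sigma", "L")) {
    cv <- up[[nm]]
    if (cv$type == "latent" && cv$latent$parameterization == "centered") {
      pr <- centered_latent_prior(cv$latent, cv$coef, cv$mu, cv$hyper, grad = grad)
      lp <- lp + pr$lp
      cent_priors[[nm]] <- pr
    }
  }
  if (up$mean$type == "latent" && up$mean$latent$parameterization == "centered") {
    prx <- centered_latent_prior(up$mean$latent, up$mean$wx, 0, up$mean$hyper, grad = grad)
    pry <- centered_latent_prior(up$mean$latent, up$mean$wy, 0, up$mean$hyper, grad = grad)
    lp <- lp + prx$lp + pry$lp
    cent_priors$mean <- list(x = prx, y = pry)
  }
  if (!grad) return(lp)

  add_grad <- function(name, val) {
    e <- idx$entries[[name]]
    gvec[e$start:e$end] <<- gvec[e$start:e$end] + val
  }

  # chain rule: data-likelihood gradients back to state entries
  for (nm in c("sigma", "L")) {
    cv <- up[[nm]]
    if (cv$type == "fixed") next
    gname <- if (nm == "sigma") "gsig" else "gL"
    if (cv$type == "constant") {
      tot <- 0
      for (i in seq_len(ng))
        tot <- tot + sum(gr_groups[[i]][[gname]]) * cv$value
      add_grad(paste0("log_", nm), tot)
    } else {
      centered <- cv$latent$parameterization == "centered"
      gw <- numeric(length(cv$coef)); gmu <- 0
      for (i in seq_len(ng)) {
        gval <- gr_groups[[i]][[gname]] * comp_vals[[nm]][[i]]$value  # d ll / d s
        gw <- gw + as.numeric(crossprod(comp_vals[[nm]][[i]]$B, gval))
        gmu <- gmu + if (centered)
          sum(gval * (1 - comp_vals[[nm]][[i]]$A1)) else sum(gval)
      }
      if (centered) {
        gw <- gw + cent_priors[[nm]]$gf
        gmu <- gmu + cent_priors[[nm]]$gmu
      }
      add_grad(cv$block, gw)
      if (identical(cv$latent$mu, "estimate")) add_grad(paste0("mu_", nm), gmu)
      for (h in names(cv$hyper)) {
        tot <- if (centered) cent_priors[[nm]]$ghyper[[h]] else 0
        for (pm in c(1, -1)) {
          hp <- cv$hyper
          hp[h] <- exp(log(cv$hyper[[h]]) + pm * FD_EPS)
          for (i in seq_len(ng)) {
            v <- realize_latent_core(cv$latent, cv$coef, plan$groups[[i]]$times,
                                     cv$mu, hp, jacobian = FALSE,
                                     warn_extrapolation = FALSE)$value
            tot <- tot + pm * sum(gr_groups[[i]][[gname]] * v) / (2 * FD_EPS)
          }
        }
        add_grad(paste0("log_", h, "_", nm), tot)
      }
    }
  }
  if (up$mean$type == "latent") {
    lat <- up$mean$latent
    centered <- lat$parameterization == "centered"
    gwx <- numeric(length(up$mean$wx)); gwy <- gwx
    for (i in seq_len(ng)) {
      B <- comp_vals$mean[[i]]$B
      gwx <- gwx + as.numeric(crossprod(B, gr_groups[[i]]$gmx))
      gwy <- gwy + as.numeric(crossprod(B, gr_groups[[i]]$gmy))
    }
    if (centered) {
      gwx <- gwx + cent_priors$mean$x$gf
      gwy <- gwy + cent_priors$mean$y$gf
    }
    add_grad(up$mean$blockx, gwx)
    add_grad(up$mean$blocky, gwy)
    coefs <- cbind(up$mean$wx, up$mean$wy)
    for (h in names(up$mean$hyper)) {
      tot <- if (centered)
        cent_priors$mean$x$ghyper[[h]] + cent_priors$mean$y$ghyper[[h]] else 0
      for (pm in c(1, -1)) {
        hp <- up$mean$hyper
        hp[h] <- exp(log(up$mean$hyper[[h]]) + pm * FD_EPS)
        for (i in seq_len(ng)) {
          v <- realize_latent_multi(lat, coefs, plan$groups[[i]]$times, 0, hp)
          tot <- tot + pm * (sum(gr_groups[[i]]$gmx * v[, 1]) +
                             sum(gr_groups[[i]]$gmy * v[, 2])) / (2 * FD_EPS)
        }
      }
      add_grad(paste0("log_", h, "_mean"), tot)
    }
  }
  if (model$sigma_m$type == "constant") {
    tot <- 0
    for (i in seq_len(ng)) tot <- tot + gr_groups[[i]]$gsm * up$sigma_m
    add_grad("log_sigma_m", tot)
  }
  attr(lp, "gradient") <- gvec
  lp
}
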