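#' Specify a latent lower-level Gaussian process
#'
#' Declares a time-varying movement parameter as a GP represented at a small
#' set of support points. Values away from the support points come from the
#' noiseless GP conditional mean given the support values, and an
#' exponential transform is applied last for positivity-constrained
#' parameters (amplitude and lengthscale).
#'
#' Two sampling parameterizations are available. Under `"whitened"` (the
#' default) the sampled coordinates are `w ~ N(0, I)` and the support
#' values are `f = mu + R w`, with `R` the lower Cholesky factor of the
#' support kernel matrix: the prior is decorrelated, which suits
#' gradient-based samplers when the data only weakly constrain the latent
#' function. Under `"centered"` the support values `f` themselves are
#' sampled with their GP prior `N(mu, K)`: when the data pin the latent
#' function down tightly this decouples the kernel hyperparameters from the
#' likelihood and mixes far better, because a change in the
#' hyperparameters no longer has to be compensated by a coordinated
#' rescaling of the whitened vector.
#'
#' @param kernel A [movegp_kernel][kernels]; hyperparameters may be
#'   `"estimate"`.
#' @param support_times Strictly increasing vector of `m >= 2` support
#'   times. For a strictly periodic kernel they should span one period.
#' @param mu Constant prior mean of the (untransformed) latent: a number or
#'   `"estimate"`. Mean-function latents use `mu = 0`.
#' @param transform `"exponential"` (for amplitude/lengthscale latents) or
#'   `"identity"` (for mean-function latents).
#' @param parameterization `"whitened"` or `"centered"` (see above).
#' @param nugget Small variance added to the support kernel's diagonal (on
#'   the untransformed latent scale, where values are O(1)). Smooth
#'   periodic kernels with moderate lengthscales are numerically
#'   near-singular on a dense support grid; the nugget bounds the prior's
#'   curvature so that factorization and sampling stay stable, at the cost
#'   of letting the latent function deviate from strict GP interpolation by
#'   about `sqrt(nugget)` — 0.01 by default, far below posterior spread.
#' @param extrapolation_margin Evaluations further than this outside the
#'   support range trigger a warning (non-periodic kernels only); default is
#'   the support spacing.
#' @return An object of class `movegp_latent`.
#' @export
latent_gp <- function(kernel, support_times,
                      mu = "estimate",
                      transform = c("exponential", "identity"),
                      parameterization = c("whitened", "centered"),
                      nugget = 1e-4,
                      extrapolation_margin = NULL) {
  stopifnot(inherits(kernel, "movegp_kernel"), nugget >= 0)
  transform <- match.arg(transform)
  parameterization <- match.arg(parameterization)
  support_times <- as.numeric(support_times)
  if (length(support_times) < 2L || any(diff(support_times) <= 0))
    stop("support_times must be strictly increasing with m >= 2")
  if (!identical(mu, "estimate") &&
      (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)))
    stop("mu must be a finite number or \"estimate\"")
  if (is.null(extrapolation_margin))
    extrapolation_margin <- stats::median(diff(support_times))
  structure(list(kernel = kernel, support_times = support_times, mu = mu,
                 transform = transform, parameterization = parameterization,
                 nugget = nugget,
                 extrapolation_margin = extrapolation_margin),
            class = "movegp_latent")
}

#' @export
print.movegp_latent <- function(x, ...) {
  cat(sprintf("<latent GP: %d support points in [%g, %g], %s transform, %s kernel>\n",
              length(x$support_times), min(x$support_times), max(x$support_times),
              x$transform, x$kernel$type))
  invisible(x)
}

# Core realization. `coef` is the sampled coordinate vector: the whitened
# vector w (support values f = mu + R w) under the whitened
# parameterization, or the support values f themselves under the centered
# one. Returns s (untransformed values at eval_times), value (transformed),
# and optionally the Jacobian B = ds/dcoef together with rowSums(A) needed
# for the mean chain in the centered case.
realize_latent_core <- function(latent, coef, eval_times, mu, hyper = NULL,
                                jacobian = FALSE, warn_extrapolation = TRUE) {
  kern <- if (length(hyper)) fill_kernel(latent$kernel, as.list(hyper)) else latent$kernel
  st <- latent$support_times
  m <- length(st)
  if (length(coef) != m) stop("coefficient vector length must equal the number of support points")
  if (warn_extrapolation && !kern$type %in% c("periodic")) {
    out <- eval_times < min(st) - latent$extrapolation_margin |
           eval_times > max(st) + latent$extrapolation_margin
    if (any(out))
      warning(sum(out), " evaluation times lie outside the support range; ",
              "values are GP extrapolations", call. = FALSE)
  }
  Kss <- kernel_matrix(kern, st)
  if (latent$nugget > 0) diag(Kss) <- diag(Kss) + latent$nugget
  f <- chol_with_jitter(Kss)                # Kss + nugget + jit = U'U
  Kes <- kernel_matrix(kern, eval_times, st)
  A1 <- NULL
  if (latent$parameterization == "centered") {
    # s = mu + A (f - mu) with A = Kes (Kss+jit)^{-1}
    if (jacobian) {
      B <- Kes %*% chol2inv(f$U)
      A1 <- rowSums(B)
      s <- as.numeric(mu + B %*% (coef - mu))
    } else {
      B <- NULL
      s <- as.numeric(mu + Kes %*%
        backsolve(f$U, forwardsolve(t(f$U), coef - mu)))
    }
  } else {
    # with R = U' lower, (Kss+jit)^{-1} R = U^{-1}, so B = Kes U^{-1}
    if (jacobian) {
      B <- Kes %*% backsolve(f$U, diag(m))
      s <- as.numeric(mu + B %*% coef)
    } else {
      B <- NULL
      s <- as.numeric(mu + Kes %*% backsolve(f$U, coef))
    }
  }
  value <- if (latent$transform == "exponential") exp(s) else s
  list(s = s, value = value, B = B, A1 = A1)
}

# GP prior log density (and gradients) of a centered latent's support
# values: f ~ N(mu 1, Kss + jit I). Hyperparameter gradients are analytic
# via dK/dlog(theta).
centered_latent_prior <- function(latent, coef, mu, hyper, grad = TRUE) {
  kern <- if (length(hyper)) fill_kernel(latent$kernel, as.list(hyper)) else latent$kernel
  st <- latent$support_times
  m <- length(st)
  Kss0 <- kernel_matrix(kern, st)
  Kss <- Kss0
  if (latent$nugget > 0) diag(Kss) <- diag(Kss) + latent$nugget
  f <- chol_with_jitter(Kss)
  r <- coef - mu
  Kinv_r <- backsolve(f$U, forwardsolve(t(f$U), r))
  lp <- -0.5 * m * log(2 * pi) - 0.5 * f$logdet - 0.5 * sum(r * Kinv_r)
  if (!grad) return(list(lp = lp))
  Kinv <- chol2inv(f$U)
  ghyper <- numeric(0)
  if (length(hyper)) {
    ghyper <- vapply(names(hyper), function(h) {
      Kd <- kernel_dlog(kern, h, st, K = Kss0)
      # the relative jitter (not the nugget) scales with the kernel amplitude
      if (h %in% c("a", "sigma_k")) Kd <- Kd + f$jitter * diag(m)
      0.5 * sum(Kinv_r * (Kd %*% Kinv_r)) - 0.5 * sum(Kinv * Kd)
    }, 0)
  }
  list(lp = lp, gf = -Kinv_r, gmu = sum(Kinv_r), ghyper = ghyper)
}

#' Realize a latent function at evaluation times
#'
#' Deterministically maps a whitened vector `w` to latent-function values:
#' support values `mu + R w` (with `R` the lower Cholesky factor of the
#' jittered support kernel matrix), conditional-mean interpolation to
#' `eval_times`, then the latent's transform. At the support times
#' themselves the interpolant reproduces the support values (up to jitter).
#'
#' @param latent A [latent_gp()].
#' @param w Sampled coordinate vector of length `m`: the whitened vector
#'   under the whitened parameterization, the support values under the
#'   centered one.
#' @param eval_times Times at which to evaluate.
#' @param mu Prior mean value; required if the latent declares
#'   `mu = "estimate"`.
#' @param hyper Named list/vector of values for kernel parameters declared
#'   `"estimate"`, on their natural (positive) scale.
#' @return Numeric vector of latent-function values at `eval_times`.
#' @export
realize_latent <- function(latent, w, eval_times, mu = NULL, hyper = NULL) {
  stopifnot(inherits(latent, "movegp_latent"))
  if (is.null(mu)) {
    if (identical(latent$mu, "estimate"))
      stop("latent has mu = \"estimate\"; supply mu")
    mu <- latent$mu
  }
  need <- estimated_params(latent$kernel)
  if (!all(need %in% names(hyper)))
    stop("missing hyperparameter value(s): ",
         paste(setdiff(need, names(hyper)), collapse = ", "))
  realize_latent_core(latent, w, check_times(eval_times), mu, hyper)$value
}

# realize several coefficient vectors (columns of coef_mat) that share one
# latent, kernel and evaluation grid: the kernel matrices and factorization
# are built once. Used by the finite-difference hyperparameter chain.
realize_latent_multi <- function(latent, coef_mat, eval_times, mu, hyper = NULL) {
  kern <- if (length(hyper)) fill_kernel(latent$kernel, as.list(hyper)) else latent$kernel
  st <- latent$support_times
  Kss <- kernel_matrix(kern, st)
  if (latent$nugget > 0) diag(Kss) <- diag(Kss) + latent$nugget
  f <- chol_with_jitter(Kss)
  Kes <- kernel_matrix(kern, eval_times, st)
  s <- if (latent$parameterization == "centered")
    mu + Kes %*% backsolve(f$U, forwardsolve(t(f$U), coef_mat - mu))
  else
    mu + Kes %*% backsolve(f$U, coef_mat)
  if (latent$transform == "exponential") exp(s) else s
}
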