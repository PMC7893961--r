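#' Covariance kernels for movement Gaussian processes
#'
#' Constructors for the covariance kernels used throughout the hierarchy:
#' the stationary Matern 1/2 (exponential) kernel equivalent to an
#' Ornstein-Uhlenbeck process, a strictly periodic kernel for daily or
#' annual cycles, and a quasi-periodic kernel (periodic times squared
#' exponential) for periodic patterns that drift over long timescales.
#'
#' Kernel hyperparameters may be given as positive numbers (fixed) or as the
#' string `"estimate"`, in which case they are sampled (on the log scale)
#' or optimized when the kernel is used inside a [movement_model()]. The
#' period `P` must always be fixed.
#'
#' @param sigma_k Kernel amplitude: the zero-lag variance of the process.
#' @param L Correlation lengthscale, in time units.
#' @param a Kernel amplitude (variance scale of the latent function).
#' @param l Dimensionless periodic lengthscale controlling within-period
#'   smoothness.
#' @param P Period, in time units (e.g. 24 for a daily cycle in hours, 1 for
#'   an annual cycle in years).
#' @param lambda Squared-exponential lengthscale (time units) over which the
#'   periodic pattern may drift.
#'
#' @return An object of class `movegp_kernel`.
#' @seealso [kernel_matrix()], [nonstationary_matern12_cov()]
#' @examples
#' k <- periodic_kernel(a = 1, l = 1, P = 24)
#' kernel_matrix(k, 0:3, 0:3)
#' @name kernels
NULL

new_kernel <- function(type, params, fixed = character()) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (identical(p, "estimate")) {
      if (nm %in% fixed)
        stop("kernel parameter '", nm, "' must be a fixed positive number")
      next
    }
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
      stop("kernel parameter '", nm, "' must be a positive finite number or \"estimate\"")
  }
  structure(list(type = type, params = params),
            class = c(paste0(type, "_kernel"), "movegp_kernel"))
}

#' @rdname kernels
#' @export
matern12_kernel <- function(sigma_k, L) {
  new_kernel("matern12", list(sigma_k = sigma_k, L = L))
}

#' @rdname kernels
#' @export
periodic_kernel <- function(a, l, P) {
  new_kernel("periodic", list(a = a, l = l, P = P), fixed = "P")
}

#' @rdname kernels
#' @export
quasiperiodic_kernel <- function(a, lambda, l, P) {
  new_kernel("quasiperiodic", list(a = a, lambda = lambda, l = l, P = P),
             fixed = c("P", "lambda"))
}

#' @export
print.movegp_kernel <- function(x, ...) {
  ps <- vapply(x$params, function(p)
    if (identical(p, "estimate")) "estimate" else format(p, digits = 4), "")
  cat("<", x$type, " kernel: ", paste(names(ps), ps, sep = "=", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

# names of hyperparameters flagged "estimate"
estimated_params <- function(kernel) {
  names(kernel$params)[vapply(kernel$params, identical, TRUE, y = "estimate")]
}

# kernel with "estimate" slots replaced by values from a named vector
fill_kernel <- function(kernel, values) {
  for (nm in names(values)) kernel$params[[nm]] <- unname(values[[nm]])
  kernel
}

# dK / d log(param) for a fully specified kernel: K times an elementwise
# factor, used by the centered-latent prior gradient
kernel_dlog <- function(kernel, param, times, K = kernel_matrix(kernel, times)) {
  p <- kernel$params
  d <- abs(outer(times, times, "-"))
  fac <- switch(paste(kernel$type, param, sep = "."),
    matern12.sigma_k = 1,
    matern12.L = d / p$L,
    periodic.a = 1,
    periodic.l = 4 * sin(pi * d / p$P)^2 / p$l^2,
    quasiperiodic.a = 1,
    quasiperiodic.l = 4 * sin(pi * d / p$P)^2 / p$l^2,
    quasiperiodic.lambda = d^2 / p$lambda^2,
    stop("no derivative rule for ", kernel$type, " parameter ", param))
  K * fac
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times)))
    stop("times must be a non-empty finite numeric vector")
  as.numeric(times)
}

#' Evaluate a covariance kernel on two sets of times
#'
#' @param kernel A [matern12_kernel()], [periodic_kernel()] or
#'   [quasiperiodic_kernel()] with all parameters fixed.
#' @param times_a,times_b Numeric time vectors.
#' @return A `length(times_a)` by `length(times_b)` covariance matrix.
#' @export
kernel_matrix <- function(kernel, times_a, times_b = times_a) {
  if (length(estimated_params(kernel)) > 0L)
    stop("kernel has unresolved \"estimate\" parameters")
  p <- kernel$params
  switch(kernel$type,
    matern12 = matern12_cov(times_a, times_b, p$sigma_k, p$L),
    periodic = periodic_cov(times_a, times_b, p$a, p$l, p$P),
    quasiperiodic = quasiperiodic_cov(times_a, times_b, p$a, p$lambda, p$l, p$P),
    stop("unknown kernel type: ", kernel$type))
}

#' Stationary Matern 1/2 (exponential) covariance
#'
#' `K(t, t') = sigma_k * exp(-|t - t'| / L)`, the covariance function of a
#' stationary Ornstein-Uhlenbeck process. `sigma_k` is the zero-lag
#' variance.
#'
#' @inheritParams kernels
#' @param times_a,times_b Numeric time vectors.
#' @return Covariance matrix of dimension `length(times_a)` x `length(times_b)`.
#' @export
matern12_cov <- function(times_a, times_b, sigma_k, L) {
  ta <- check_times(times_a); tb <- check_times(times_b)
  stopifnot(sigma_k > 0, L > 0)
  d <- abs(outer(ta, tb, "-"))
  sigma_k * exp(-d / L)
}

#' Bundle inputs for the non-stationary Matern 1/2 kernel
#'
#' @param times Evaluation times.
#' @param sigma Kernel amplitude sigma(t) at `times` (standard-deviation
#'   scale: the diagonal of the covariance is `sigma^2`).
#' @param L Correlation lengthscale L(t) at `times`.
#' @return A list of class `nonstationary_inputs`.
#' @export
nonstationary_inputs <- function(times, sigma, L) {
  times <- check_times(times)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(times))
  if (length(L) == 1L) L <- rep(L, length(times))
  if (length(sigma) != length(times) || length(L) != length(times))
    stop("times, sigma and L must have equal length")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be strictly positive")
  if (any(!is.finite(L)) || any(L <= 0)) stop("L must be strictly positive")
  structure(list(times = times, sigma = as.numeric(sigma), L = as.numeric(L)),
            class = "nonstationary_inputs")
}

#' Non-stationary Matern 1/2 covariance
#'
#' Generalization of the exponential kernel in which both the amplitude
#' sigma(t) and the lengthscale L(t) vary over time:
#' \deqn{K(t,t') = \sqrt{\frac{2\sigma^2(t)\sigma^2(t')L(t)L(t')}{L(t)^2+L(t')^2}}
#'   \exp\left(-\sqrt{\frac{2(t-t')^2}{L(t)^2+L(t')^2}}\right)}
#' The diagonal equals `sigma(t)^2`, and with constant inputs the kernel
#' reduces exactly to [matern12_cov()] with `sigma_k = sigma^2`.
#'
#' @param inputs_a,inputs_b [nonstationary_inputs()] objects.
#' @return Covariance matrix.
#' @export
nonstationary_matern12_cov <- function(inputs_a, inputs_b = inputs_a) {
  if (!inherits(inputs_a, "nonstationary_inputs")) inputs_a <- do.call(nonstationary_inputs, inputs_a)
  if (!inherits(inputs_b, "nonstationary_inputs")) inputs_b <- do.call(nonstationary_inputs, inputs_b)
  La <- inputs_a$L; Lb <- inputs_b$L
  u <- outer(La^2, Lb^2, "+")                       # L(t)^2 + L(t')^2
  d2 <- outer(inputs_a$times, inputs_b$times, "-")^2
  pref <- sqrt(2 * outer(inputs_a$sigma^2 * La, inputs_b$sigma^2 * Lb) / u)
  pref * exp(-sqrt(2 * d2 / u))
}

#' Periodic covariance kernel
#'
#' `K(t, t') = a * exp(-2 sin^2(pi |t - t'| / P) / l^2)`; exactly periodic in
#' the lag with period `P`.
#'
#' @inheritParams matern12_cov
#' @inheritParams kernels
#' @export
periodic_cov <- function(times_a, times_b, a, l, P) {
  ta <- check_times(times_a); tb <- check_times(times_b)
  stopifnot(a > 0, l > 0, P > 0)
  d <- abs(outer(ta, tb, "-"))
  a * exp(-2 * sin(pi * d / P)^2 / l^2)
}

#' Quasi-periodic covariance kernel
#'
#' Product of a squared-exponential kernel with lengthscale `lambda` and a
#' periodic kernel with period `P`: a periodic pattern whose shape drifts
#' slowly over timescale `lambda`.
#'
#' @inheritParams periodic_cov
#' @inheritParams kernels
#' @export
quasiperiodic_cov <- function(times_a, times_b, a, lambda, l, P) {
  ta <- check_times(times_a); tb <- check_times(times_b)
  stopifnot(a > 0, lambda > 0, l > 0, P > 0)
  d <- abs(outer(ta, tb, "-"))
  a * exp(-d^2 / (2 * lambda^2) - 2 * sin(pi * d / P)^2 / l^2)
}

#' Map Ornstein-Uhlenbeck parameters to Matern 1/2 kernel parameters
#'
#' For the OU process `dx = -nu (x - m) dt + eta dW`, the stationary process
#' has exponential covariance with lengthscale `L = 1/nu` and zero-lag
#' variance `sigma_k = eta^2 / (2 nu)`.
#'
#' @param nu Mean-reversion rate (1/time).
#' @param eta Noise amplitude of the SDE.
#' @return A list with elements `sigma_k` and `L`.
#' @export
ou_to_kernel <- function(nu, eta) {
  stopifnot(is.numeric(nu), is.numeric(eta), nu > 0, eta >= 0)
  list(sigma_k = eta^2 / (2 * nu), L = 1 / nu)
}

#' Map Matern 1/2 kernel parameters to Ornstein-Uhlenbeck parameters
#'
#' Inverse of [ou_to_kernel()]: `nu = 1/L`, `eta = sqrt(2 nu sigma_k)`. The
#' OU mean is not determined by the kernel and is returned as `NA`.
#'
#' @inheritParams kernels
#' @return A list with elements `nu`, `eta` and `m` (`NA`).
#' @export
kernel_to_ou <- function(sigma_k, L) {
  stopifnot(sigma_k > 0, L > 0)
  nu <- 1 / L
  list(nu = nu, eta = sqrt(2 * nu * sigma_k), m = NA_real_)
}

#' Add diagonal jitter until a matrix admits a Cholesky factorization
#'
#' Adds `jitter * I`, doubling the jitter up to `max_retries` times if the
#' Cholesky factorization still fails. The default jitter is `1e-6` times
#' the mean diagonal element.
#'
#' @param K A square (near-)positive-semidefinite matrix.
#' @param jitter Initial jitter; default `1e-6 * mean(diag(K))` (absolute
#'   `1e-6` for an all-zero diagonal).
#' @param max_retries Number of times the jitter is doubled before giving up.
#' @return The jittered matrix, with the jitter actually used stored in
#'   attribute `"jitter"`.
#' @export
add_jitter <- function(K, jitter = NULL, max_retries = 3L) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  f <- chol_with_jitter(K, jitter, max_retries)
  out <- K + f$jitter * diag(nrow(K))
  attr(out, "jitter") <- f$jitter
  out
}

# Cholesky (upper factor) with retried jitter; errors after max_retries.
# Returns list(U, jitter, logdet).
chol_with_jitter <- function(K, jitter = NULL, max_retries = 3L) {
  n <- nrow(K)
  if (is.null(jitter)) {
    md <- mean(diag(K))
    jitter <- if (md > 0) 1e-6 * md else 1e-6
  }
  eps <- jitter
  for (i in seq_len(max_retries + 1L)) {
    U <- tryCatch(chol(K + eps * diag(n)), error = function(e) NULL)
    if (!is.null(U))
      return(list(U = U, jitter = eps, logdet = 2 * sum(log(diag(U)))))
    eps <- 2 * eps
  }
  stop("matrix is not positive definite after ", max_retries, " jitter retries")
}
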