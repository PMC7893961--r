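#' Posterior draws of a latent movement-parameter function
#'
#' Realizes a fitted latent function at arbitrary times for every retained
#' posterior draw, assembling the whitened/centered coordinates, prior mean
#' and kernel hyperparameters from the sample array automatically.
#'
#' @param samples A `movegp_samples` object from [run_chains()].
#' @param model The [movement_model()] that was fitted.
#' @param component `"sigma"`, `"L"`, `"mean_x"` or `"mean_y"`.
#' @param eval_times Times at which to evaluate the latent function.
#' @param max_draws Cap on the number of pooled draws used (evenly
#'   subsampled); `Inf` uses all.
#' @return A draws x `length(eval_times)` matrix of latent-function values
#'   (on the natural scale, after any exponential transform).
#' @export
posterior_latent_draws <- function(samples, model, component, eval_times,
                                   max_draws = Inf) {
  comp_name <- if (component %in% c("mean_x", "mean_y")) "mean" else component
  comp <- model[[comp_name]]
  if (is.null(comp) || comp$type != "latent")
    stop(component, " is not a latent component of this model")
  lat <- comp$latent
  pre <- if (lat$parameterization == "centered") "f_" else "w_"
  block <- paste0(pre, if (comp_name == "mean") component else component)
  m <- length(lat$support_times)
  pool <- extract_draws(samples, ".")
  take <- seq_len(nrow(pool))
  if (nrow(pool) > max_draws)
    take <- unique(round(seq(1, nrow(pool), length.out = max_draws)))
  cidx <- grep(paste0("^", block, "\\["), colnames(pool))
  if (length(cidx) != m) stop("could not locate the ", block, " block in the draws")
  mu_col <- paste0("mu_", comp_name)
  hn <- estimated_params(lat$kernel)
  out <- matrix(NA_real_, length(take), length(eval_times))
  for (r in seq_along(take)) {
    row <- pool[take[r], ]
    mu <- if (identical(lat$mu, "estimate")) row[[mu_col]] else lat$mu
    hyper <- stats::setNames(
      vapply(hn, function(h) exp(row[[paste0("log_", h, "_", comp_name)]]), 0), hn)
    out[r, ] <- realize_latent_core(lat, row[cidx], eval_times, mu, hyper,
                                    warn_extrapolation = FALSE)$value
  }
  out
}
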