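#' Read trajectories from a delimited text file
#'
#' Parses a UTF-8 comma-delimited file with header `id,time,x,y`, groups
#' rows by individual, and sorts each individual's fixes by time. Malformed
#' rows (non-numeric time or coordinates) and duplicate `(id, time)` pairs
#' are errors reported with their line numbers.
#'
#' @param path Path to the file.
#' @param kind `"position"` (default) or `"velocity"`.
#' @return A named list of [trajectory()] objects, one per individual.
#' @export
read_trajectories <- function(path, kind = "position") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  need <- c("id", "time", "x", "y")
  if (!all(need %in% names(df)))
    stop("header must contain columns: ", paste(need, collapse = ","))
  num <- lapply(df[c("time", "x", "y")], function(col)
    suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  df$time <- num$time; df$x <- num$x; df$y <- num$y
  dup <- duplicated(df[c("id", "time")])
  if (any(dup))
    stop("duplicate (id, time) at line(s): ",
         paste(utils::head(which(dup) + 1L, 10), collapse = ", "))
  out <- lapply(split(df, df$id), function(dd) {
    dd <- dd[order(dd$time), ]
    trajectory(dd$id[1L], dd$time, cbind(dd$x, dd$y), kind = kind)
  })
  out[order(names(out))]
}

#' Write trajectories to a delimited text file
#'
#' Inverse of [read_trajectories()]: writes `id,time,x,y` rows. An optional
#' YAML sidecar (`<path>.yml`) records generator metadata and seeds when
#' present on the trajectories.
#'
#' @param trajs A [trajectory()] or list of trajectories.
#' @param path Output path.
#' @param sidecar Write the metadata sidecar if metadata is present?
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, sidecar = TRUE) {
  if (inherits(trajs, "movegp_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(id = tr$id, time = tr$times, x = tr$values[, 1],
               y = tr$values[, 2])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- Filter(Negate(is.null), lapply(trajs, attr, "generator"))
  if (sidecar && length(meta)) {
    names(meta) <- vapply(trajs, `[[`, "", "id")[seq_along(meta)]
    yaml::write_yaml(meta, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Persist posterior samples as text
#'
#' Writes the draws to `<path>.csv` (columns `chain`, `draw`, then one per
#' parameter) and a `<path>.yml` sidecar holding the sampler configuration,
#' seeds and acceptance rates, so a stored run is fully re-runnable.
#'
#' @param samples A `movegp_samples` object.
#' @param path Output path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "movegp_samples"))
  dm <- dim(samples$draws)
  flat <- matrix(aperm(samples$draws, c(2, 1, 3)), dm[1] * dm[2], dm[3])
  df <- data.frame(chain = rep(seq_len(dm[1]), each = dm[2]),
                   draw = rep(seq_len(dm[2]), dm[1]))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- samples$param_names
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(config = unclass(samples$config),
                        seed = samples$seed,
                        chain_seeds = as.integer(samples$chain_seeds),
                        acceptance = samples$acceptance,
                        step_size = samples$step_size,
                        parameters = samples$param_names),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read posterior samples written by [write_samples()]
#'
#' @param path Path stem used in [write_samples()].
#' @return A `movegp_samples` object.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pn <- as.character(meta$parameters)
  n_chain <- max(df$chain); n_draw <- max(df$draw)
  draws <- array(NA_real_, c(n_chain, n_draw, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(n_chain)) {
    sel <- df$chain == ch
    draws[ch, df$draw[sel], ] <- as.matrix(df[sel, pn, drop = FALSE])
  }
  cfg <- meta$config
  structure(list(draws = draws,
                 acceptance = as.numeric(meta$acceptance),
                 step_size = as.numeric(meta$step_size),
                 step_trace = NULL,
                 config = do.call(sampler_config, cfg[names(cfg) != ""]),
                 seed = meta$seed, chain_seeds = meta$chain_seeds,
                 param_names = pn),
            class = "movegp_samples")
}

#' Build a movement model from a structured configuration
#'
#' Accepts a YAML file path or an equivalent nested list describing the
#' model: which parameters are dynamic, their kernels (with `estimate`
#' markers), support-point placement, and priors. Example:
#' \preformatted{
#' sigma:
#'   kernel: {type: periodic, a: estimate, l: estimate, P: 24}
#'   support: {from: 0, to: 24, count: 40, periodic: true}
#'   mu: estimate
#' L: estimate
#' sigma_m: 0
#' prior_sd: 2
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return A [movement_model()].
#' @export
model_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  build_kernel <- function(k) {
    k <- lapply(k, function(v) if (identical(v, "estimate")) "estimate" else v)
    switch(k$type,
      matern12 = matern12_kernel(k$sigma_k, k$L),
      periodic = periodic_kernel(k$a, k$l, k$P),
      quasiperiodic = quasiperiodic_kernel(k$a, k$lambda, k$l, k$P),
      stop("unknown kernel type in config: ", k$type))
  }
  build_comp <- function(x, role) {
    if (is.null(x)) return(NULL)
    if (identical(x, "estimate")) return("estimate")
    if (is.numeric(x)) return(x)
    sup <- do.call(place_support_points, x$support)
    latent_gp(build_kernel(x$kernel), sup,
              mu = if (role == "mean") 0 else x$mu %||% "estimate",
              transform = if (role == "mean") "identity" else "exponential")
  }
  movement_model(sigma = build_comp(config$sigma, "sigma"),
                 L = build_comp(config$L, "L"),
                 mean = build_comp(config$mean, "mean"),
                 sigma_m = config$sigma_m %||% 0,
                 prior_sd = config$prior_sd %||% 2)
}
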