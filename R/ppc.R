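#' Discretize a trajectory into step lengths and turn angles
#'
#' Resamples a position trajectory at regular window boundaries (taking the
#' nearest fix within a tolerance of each boundary; a boundary with no fix
#' close enough breaks the sequence into separate blocks), then computes
#' the Euclidean displacement between consecutive resampled positions
#' (step lengths) and the signed angle between consecutive displacement
#' vectors (turn angles, in `(-pi, pi]`). Within each contiguous block
#' there is one fewer turn than steps.
#'
#' @param traj A position [trajectory()].
#' @param window Step duration, in the trajectory's time units; should be
#'   at least twice the median fix interval.
#' @param tol Matching tolerance for the nearest fix; default 10% of
#'   `window`.
#' @return A list of class `movegp_stepturn` with elements `window`,
#'   `step_lengths`, `turn_angles` and `n_blocks`.
#' @export
steps_and_turns <- function(traj, window, tol = 0.1 * window) {
  stopifnot(inherits(traj, "movegp_trajectory"))
  if (traj$kind != "position") stop("steps and turns need a position trajectory")
  med_dt <- stats::median(diff(traj$times))
  if (window < 2 * med_dt)
    stop("window must be at least twice the median fix interval")
  bounds <- seq(traj$times[1L], traj$times[length(traj$times)], by = window)
  nearest <- findInterval(bounds, traj$times, all.inside = TRUE)
  idx <- vapply(seq_along(bounds), function(i) {
    cand <- c(nearest[i], min(nearest[i] + 1L, length(traj$times)))
    cand[which.min(abs(traj$times[cand] - bounds[i]))]
  }, 0L)
  ok <- abs(traj$times[idx] - bounds) <= tol
  if (sum(ok) < 3L) stop("fewer than 3 resampled points; widen tol or window")
  # split into contiguous runs of matched boundaries
  run <- cumsum(!ok)[ok]
  pts <- idx[ok]
  steps <- numeric(0); turns <- numeric(0); n_blocks <- 0L
  for (r in unique(run)) {
    p <- pts[run == r]
    if (length(p) < 2L) next
    n_blocks <- n_blocks + 1L
    dxy <- diff(traj$values[p, , drop = FALSE])
    steps <- c(steps, unname(sqrt(rowSums(dxy^2))))
    if (nrow(dxy) >= 2L) {
      v1 <- dxy[-nrow(dxy), , drop = FALSE]
      v2 <- dxy[-1L, , drop = FALSE]
      cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
      dot <- rowSums(v1 * v2)
      ang <- unname(atan2(cross, dot))
      ang[ang <= -pi] <- pi                  # signed angles in (-pi, pi]
      turns <- c(turns, ang)
    }
  }
  structure(list(window = window, step_lengths = steps, turn_angles = turns,
                 n_blocks = n_blocks),
            class = "movegp_stepturn")
}

#' @export
print.movegp_stepturn <- function(x, ...) {
  cat(sprintf("<step/turn summary: window %g, %d steps, %d turns, %d block(s)>\n",
              x$window, length(x$step_lengths), length(x$turn_angles), x$n_blocks))
  invisible(x)
}

two_sample_ks <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  F1 <- stats::ecdf(a)(pooled)
  F2 <- stats::ecdf(b)(pooled)
  max(abs(F1 - F2))
}

#' Compare step/turn distributions between two trajectories
#'
#' Posterior-predictive-style comparison of two [steps_and_turns()]
#' summaries (e.g. empirical vs model-simulated): step-length quantiles and
#' two-sample Kolmogorov-Smirnov distance, and a circular-histogram
#' divergence (total variation distance between binned turn-angle
#' frequencies). The report carries the KS critical values at conventional
#' levels for reference but renders no verdict.
#'
#' @param real,sim `movegp_stepturn` summaries with equal windows.
#' @param n_bins Number of turn-angle bins on `(-pi, pi]`.
#' @return A list of class `movegp_ppc_report`.
#' @export
compare_distributions <- function(real, sim, n_bins = 24) {
  stopifnot(inherits(real, "movegp_stepturn"), inherits(sim, "movegp_stepturn"))
  if (!length(real$step_lengths) || !length(sim$step_lengths))
    stop("both summaries must be non-empty")
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  qtab <- rbind(real = stats::quantile(real$step_lengths, probs),
                sim = stats::quantile(sim$step_lengths, probs))
  ks <- two_sample_ks(real$step_lengths, sim$step_lengths)
  n1 <- length(real$step_lengths); n2 <- length(sim$step_lengths)
  scale <- sqrt((n1 + n2) / (n1 * n2))
  ks_critical <- c("0.05" = 1.358, "0.01" = 1.628) * scale
  brk <- seq(-pi, pi, length.out = n_bins + 1L)
  h1 <- tabulate(cut(real$turn_angles, brk, include.lowest = TRUE), n_bins)
  h2 <- tabulate(cut(sim$turn_angles, brk, include.lowest = TRUE), n_bins)
  tv <- 0.5 * sum(abs(h1 / max(1, sum(h1)) - h2 / max(1, sum(h2))))
  structure(list(window = real$window, step_quantiles = qtab,
                 ks_distance = ks, ks_critical = ks_critical,
                 n_steps = c(real = n1, sim = n2),
                 turn_divergence = tv),
            class = "movegp_ppc_report")
}

#' @export
print.movegp_ppc_report <- function(x, ...) {
  cat(sprintf("<step/turn comparison, window %g>\n", x$window))
  cat(sprintf("  steps: n_real=%d n_sim=%d, KS distance %.4f (crit 1%%: %.4f)\n",
              x$n_steps["real"], x$n_steps["sim"], x$ks_distance,
              x$ks_critical["0.01"]))
  cat(sprintf("  turn-angle histogram TV divergence: %.4f\n", x$turn_divergence))
  print(round(x$step_quantiles, 4))
  invisible(x)
}
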