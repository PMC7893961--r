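#' Construct a telemetry trajectory
#'
#' A trajectory holds one individual's timestamped 2-D observations: either
#' positions (GPS fixes) or velocities (e.g. finite differences of fixes).
#' Times must be strictly increasing; units (hours, years, ...) are the
#' caller's choice but must be consistent with the kernels used.
#'
#' @param id Individual identifier (coerced to character).
#' @param times Strictly increasing numeric time vector.
#' @param values `n` x 2 numeric matrix (columns x, y) of positions or
#'   velocities.
#' @param kind `"position"` or `"velocity"`.
#' @return An object of class `movegp_trajectory`.
#' @export
trajectory <- function(id, times, values, kind = c("position", "velocity")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (is.null(dim(values)) || ncol(values) != 2L)
    stop("values must be an n x 2 matrix")
  storage.mode(values) <- "double"
  n <- length(times)
  if (n < 1L) stop("a trajectory needs at least 1 observation")
  if (nrow(values) != n) stop("times and values disagree in length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("trajectory contains non-finite entries")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  colnames(values) <- c("x", "y")
  structure(list(id = as.character(id)[1L], times = times, values = values,
                 kind = kind),
            class = "movegp_trajectory")
}

#' @export
print.movegp_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d %s fixes, t in [%g, %g]>\n",
              x$id, length(x$times), x$kind, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.movegp_trajectory <- function(x) length(x$times)

#' Finite-difference velocities from a position trajectory
#'
#' Computes forward differences `v_i = (x_{i+1} - x_i) / (t_{i+1} - t_i)`,
#' assigned to the left timestamp `t_i`, so the output has `n - 1` rows and
#' `kind = "velocity"`.
#'
#' @param traj A position [trajectory()].
#' @return A velocity trajectory.
#' @export
finite_difference_velocity <- function(traj) {
  stopifnot(inherits(traj, "movegp_trajectory"))
  if (traj$kind != "position") stop("input must be a position trajectory")
  dt <- diff(traj$times)
  if (any(dt == 0)) stop("duplicate timestamps")
  v <- diff(traj$values) / dt
  trajectory(traj$id, traj$times[-length(traj$times)], v, kind = "velocity")
}

#' Split a trajectory into consecutive segments
#'
#' Segments a long trajectory into conditionally independent local blocks of
#' `j` points for the local-GP-experts likelihood approximation. Segments
#' preserve order and timestamps exactly, so concatenating them reproduces
#' the input.
#'
#' @param traj A [trajectory()].
#' @param j Points per segment (`>= 2`).
#' @param tail Policy for a final block shorter than `j`:
#'   `"keep-short-tail"` keeps it as its own segment (a final block of one
#'   point is merged into the previous segment, as a single point has no
#'   covariance structure); `"merge-into-last"` appends it to the previous
#'   segment.
#' @return A list of trajectories.
#' @export
segment_trajectory <- function(traj, j, tail = c("keep-short-tail", "merge-into-last")) {
  stopifnot(inherits(traj, "movegp_trajectory"))
  tail <- match.arg(tail)
  j <- as.integer(j)
  if (j < 2L) stop("segment length j must be >= 2")
  n <- length(traj$times)
  if (n <= j) {
    if (n < j) message("trajectory shorter than one segment; returning it unsplit")
    return(list(traj))
  }
  starts <- seq(1L, n, by = j)
  ends <- pmin(starts + j - 1L, n)
  k <- length(starts)
  if (k > 1L) {
    short <- ends[k] - starts[k] + 1L < j
    if (short && (tail == "merge-into-last" || ends[k] == starts[k])) {
      ends[k - 1L] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]
    }
  }
  mapply(function(s, e)
    trajectory(traj$id, traj$times[s:e], traj$values[s:e, , drop = FALSE],
               kind = traj$kind),
    starts, ends, SIMPLIFY = FALSE)
}

#' Evenly spaced support points for a latent function
#'
#' Support points are the small set of times at which latent movement
#' parameters are represented; values elsewhere come from GP conditional
#' interpolation. On a non-periodic interval the points include both
#' endpoints; on a periodic domain of period `P` the points are spaced
#' `P / count` apart starting at the interval's left edge, with no duplicate
#' at the wrap point.
#'
#' @param from,to Domain endpoints (for a periodic domain, one period, e.g.
#'   `from = 0, to = 24`).
#' @param count Number of support points (used if `spacing` is `NULL`).
#' @param spacing Desired spacing; converted to a count covering the domain.
#' @param periodic Is the domain periodic (period `to - from`)?
#' @return Numeric vector of support times.
#' @export
place_support_points <- function(from, to, count = NULL, spacing = NULL,
                                 periodic = FALSE) {
  extent <- to - from
  if (!is.finite(extent) || extent <= 0) stop("domain must have positive extent")
  if (is.null(count)) {
    if (is.null(spacing)) stop("give either count or spacing")
    if (spacing > extent) stop("spacing exceeds the domain extent")
    count <- if (periodic) ceiling(extent / spacing)
             else ceiling(extent / spacing) + 1L
  }
  count <- as.integer(count)
  if (count < 2L) stop("need at least 2 support points")
  if (periodic) seq(from, to, length.out = count + 1L)[-(count + 1L)]
  else seq(from, to, length.out = count)
}
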