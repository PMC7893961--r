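#' Simulate a 2-D Ornstein-Uhlenbeck trajectory with time-varying parameters
#'
#' Simulates `dx = -nu(t) (x - m(t)) dt + eta(t) dW` by the exact OU
#' transition over each step, with the parameters held at their values at
#' the step's left endpoint:
#' `x_{k+1} = m_k + (x_k - m_k) exp(-nu_k dt) + N(0, eta_k^2 (1 - exp(-2 nu_k dt)) / (2 nu_k))`
#' per coordinate. For constant parameters this is exact for any step size;
#' for time-varying parameters the bias is negligible when the parameters
#' vary slowly relative to the step.
#'
#' @param t_grid Strictly increasing simulation times.
#' @param nu Mean-reversion rate: positive scalar or function of time.
#' @param eta Noise amplitude: non-negative scalar or function of time.
#' @param mean Mean location: length-2 vector, or function of a time vector
#'   returning an `n` x 2 matrix.
#' @param x0 Initial position (length 2). Default: the mean at `t_grid[1]`.
#' @param id Identifier for the output trajectory.
#' @param seed Optional integer seed for reproducibility.
#' @return A position [trajectory()] on `t_grid`.
#' @export
simulate_ou_2d <- function(t_grid, nu, eta, mean = c(0, 0), x0 = NULL,
                           id = "sim", seed = NULL) {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with length >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- length(t_grid)
  nu_t <- if (is.function(nu)) vapply(t_grid, nu, 0) else rep(as.numeric(nu), n)
  eta_t <- if (is.function(eta)) vapply(t_grid, eta, 0) else rep(as.numeric(eta), n)
  if (any(nu_t <= 0)) stop("nu must be strictly positive")
  if (any(eta_t < 0)) stop("eta must be non-negative")
  m_t <- if (is.function(mean)) {
    mm <- mean(t_grid)
    if (is.null(dim(mm))) mm <- matrix(mm, n, 2)
    as.matrix(mm)
  } else matrix(as.numeric(mean), n, 2, byrow = TRUE)
  dt <- diff(t_grid)
  if (any(dt * nu_t[-n] > 10))
    warning("some steps exceed 10 / nu; parameter freezing may bias the path")
  x <- matrix(0, n, 2)
  x[1L, ] <- if (is.null(x0)) m_t[1L, ] else as.numeric(x0)
  decay <- exp(-nu_t[-n] * dt)
  sd_step <- sqrt(eta_t[-n]^2 * (1 - decay^2) / (2 * nu_t[-n]))
  noise <- matrix(stats::rnorm(2L * (n - 1L)), n - 1L, 2) * sd_step
  for (k in seq_len(n - 1L)) {
    x[k + 1L, ] <- m_t[k, ] + (x[k, ] - m_t[k, ]) * decay[k] + noise[k, ]
  }
  trajectory(id, t_grid, x, kind = "position")
}

#' Smoothed-sawtooth daily activity amplitude
#'
#' Builds the diurnal noise-amplitude driver used by the daily-activity
#' simulation: a sawtooth with a 1-day period that sits at `base` overnight,
#' rises linearly from `rise_time` to `peak` at `drop_time`, drops sharply
#' back to `base`, and is then passed through a circular Gaussian smoother
#' to give a realistic activity profile. The result is exactly periodic
#' with period `period`.
#'
#' @param times Absolute times (same unit as `period`); only `times %%
#'   period` matters.
#' @param base,peak Amplitude levels outside and at the top of the active
#'   period; both must be positive.
#' @param rise_time,drop_time Start of the linear rise and time of the sharp
#'   drop, within `[0, period)`. Defaults: 5h and 17h (5am and 5pm).
#' @param smooth_width Standard deviation of the circular Gaussian smoother
#'   (same unit as `period`); `0` returns the raw sawtooth.
#' @param period Period of the cycle (default 24 hours).
#' @return Positive amplitude vector, one value per element of `times`.
#' @export
daily_activity_amplitude <- function(times, base = 0.5, peak = 3.0,
                                     rise_time = 5, drop_time = 17,
                                     smooth_width = 1, period = 24) {
  if (base <= 0 || peak <= 0) stop("base and peak levels must be positive")
  if (!(rise_time >= 0 && drop_time > rise_time && drop_time < period))
    stop("need 0 <= rise_time < drop_time < period")
  tod <- as.numeric(times) %% period
  raw <- function(h) {
    up <- h >= rise_time & h < drop_time
    out <- rep(base, length(h))
    out[up] <- base + (peak - base) * (h[up] - rise_time) / (drop_time - rise_time)
    out
  }
  if (smooth_width <= 0) return(raw(tod))
  # circular convolution on a fine grid with a normalized Gaussian kernel
  ng <- 1440L
  grid <- seq(0, period, length.out = ng + 1L)[-(ng + 1L)]
  dg <- period / ng
  lag <- grid
  lag[lag > period / 2] <- lag[lag > period / 2] - period
  w <- exp(-lag^2 / (2 * smooth_width^2))
  w <- w / sum(w)
  sm <- Re(stats::fft(stats::fft(raw(grid)) * stats::fft(w), inverse = TRUE)) / ng
  # periodic linear interpolation back to the requested times
  idx <- tod / dg
  i0 <- floor(idx)
  frac <- idx - i0
  i0 <- as.integer(i0 %% ng) + 1L
  i1 <- i0 %% ng + 1L
  sm[i0] * (1 - frac) + sm[i1] * frac
}

#' Mean location of the synthetic shifting seasonal migration
#'
#' North-south oscillation between a wintering area at `y = 0` and a
#' northern range that slowly shifts further north over the years:
#' \deqn{g(t) = 1 + \cos(2\pi t)\sqrt{(1+b^2)/(1+b^2\cos^2(2\pi t))}}
#' \deqn{m^y_t = (5 - e^{-t/3})\, g(t), \qquad m^x_t = 0}
#' with `t` in years. At integer years the individual is at its northern
#' endpoint, which rises from 8 at `t = 0` towards 10 as `t` grows; at
#' half-integer years it is at the southern endpoint `y = 0`.
#'
#' @param t Time(s) in years, `t >= 0`.
#' @param b Smoothness of the transition between endpoints (default 5).
#' @return A `length(t)` x 2 matrix of mean locations (columns x, y).
#' @export
migration_mean <- function(t, b = 5) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be non-negative")
  if (b < 0) stop("b must be non-negative")
  ct <- cos(2 * pi * t)
  g <- 1 + ct * sqrt((1 + b^2) / (1 + b^2 * ct^2))
  cbind(x = 0, y = (5 - exp(-t / 3)) * g)
}

#' Add Gaussian measurement noise to a trajectory
#'
#' Adds iid `N(0, sigma_m^2)` noise to each coordinate of each fix, the
#' white observation-error term of the data model.
#'
#' @param traj A [trajectory()].
#' @param sigma_m Measurement-noise standard deviation (`>= 0`).
#' @param seed Optional integer seed.
#' @return The noisy trajectory.
#' @export
add_measurement_noise <- function(traj, sigma_m, seed = NULL) {
  stopifnot(inherits(traj, "movegp_trajectory"), sigma_m >= 0)
  if (sigma_m == 0) return(traj)
  if (!is.null(seed)) set.seed(seed)
  traj$values <- traj$values + matrix(stats::rnorm(2L * length(traj$times), 0, sigma_m),
                                      ncol = 2)
  traj
}

#' Simulate the daily-activity study trajectory
#'
#' The home-ranging random walker with a diurnal activity cycle: a 2-D OU
#' position process with fixed mean at the origin and fixed mean-reversion
#' rate `nu`, whose SDE noise amplitude follows the smoothed-sawtooth daily
#' profile of [daily_activity_amplitude()]. Time is in hours. The process
#' is simulated on a fine grid (`sim_minutes`) and downsampled to the GPS
#' fix schedule (`fix_minutes`), with optional measurement noise.
#'
#' @param n_days Days simulated.
#' @param fix_minutes Fix interval of the collar schedule, minutes.
#' @param nu Mean-reversion rate, per hour.
#' @param sigma_m Measurement-noise sd added to the fixes.
#' @param sim_minutes Simulation step, minutes.
#' @param seed Integer seed.
#' @param ... Passed on to [daily_activity_amplitude()].
#' @return A position trajectory with times in hours, plus an attribute
#'   `"generator"` recording every parameter and the seed.
#' @export
simulate_daily_activity <- function(n_days = 10, fix_minutes = 10, nu = 12,
                                    sigma_m = 0, sim_minutes = 1, seed = 1, ...) {
  amp_args <- list(...)
  eta_fun <- function(t) do.call(daily_activity_amplitude, c(list(times = t), amp_args))
  # half-open grid [0, 24 n_days): exactly n_days full days of fixes
  t_sim <- (seq_len(n_days * 24 * 60 / sim_minutes) - 1L) * (sim_minutes / 60)
  traj <- simulate_ou_2d(t_sim, nu = nu, eta = eta_fun, mean = c(0, 0),
                         id = "daily-activity", seed = seed)
  keep <- seq(1L, length(t_sim), by = as.integer(round(fix_minutes / sim_minutes)))
  traj <- trajectory(traj$id, traj$times[keep], traj$values[keep, , drop = FALSE],
                     kind = "position")
  if (sigma_m > 0) traj <- add_measurement_noise(traj, sigma_m)
  attr(traj, "generator") <- c(list(n_days = n_days, fix_minutes = fix_minutes,
                                    nu = nu, sigma_m = sigma_m,
                                    sim_minutes = sim_minutes, seed = seed),
                               amp_args)
  traj
}

#' Simulate the shifting seasonal migration study trajectory
#'
#' A single random walker following an annual north-south migration whose
#' northern range slowly shifts: a 2-D OU position process with constant
#' `nu` and `eta` around the [migration_mean()] route. Time is in years.
#' Simulated on a daily grid and downsampled to the fix schedule.
#'
#' @param years Years simulated.
#' @param fix_days Fix interval, days.
#' @param nu Mean-reversion rate, per year.
#' @param eta SDE noise amplitude (position units per sqrt(year)).
#' @param b Transition-smoothness parameter of the migration mean.
#' @param sigma_m Measurement-noise sd.
#' @param seed Integer seed.
#' @return A position trajectory with times in years, with a `"generator"`
#'   attribute recording the configuration.
#' @export
simulate_migration <- function(years = 3, fix_days = 7, nu = 26, eta = 3.6,
                               b = 5, sigma_m = 0, seed = 1) {
  t_sim <- seq(0, years, by = 1 / 365)
  traj <- simulate_ou_2d(t_sim, nu = nu, eta = eta,
                         mean = function(t) migration_mean(t, b = b),
                         id = "migration", seed = seed)
  keep <- seq(1L, length(t_sim), by = as.integer(fix_days))
  traj <- trajectory(traj$id, traj$times[keep], traj$values[keep, , drop = FALSE],
                     kind = "position")
  if (sigma_m > 0) traj <- add_measurement_noise(traj, sigma_m)
  attr(traj, "generator") <- list(years = years, fix_days = fix_days, nu = nu,
                                  eta = eta, b = b, sigma_m = sigma_m, seed = seed)
  traj
}

#' Simulate movement from posterior draws of daily latent functions
#'
#' Generates a position trajectory from an inferred velocity model: for each
#' simulated day one posterior draw of the latent amplitude and lengthscale
#' functions is selected, velocity follows an OU process with mean zero,
#' mean-reversion `1/L(t)` and stationary amplitude `sigma(t)` (so SDE noise
#' `eta(t) = sigma(t) sqrt(2 / L(t))`), velocities are integrated to
#' positions, and the positions are downsampled to the collar fix schedule.
#'
#' @param sigma_draws,L_draws Matrices of posterior draws (rows = draws,
#'   columns = values at `draw_times`) of the positive latent functions.
#' @param draw_times Times-of-day (hours in `[0, 24)`) at which the draws
#'   are tabulated.
#' @param n_days Days to simulate.
#' @param fix_minutes Collar schedule, minutes; must be a multiple of
#'   `sim_minutes`.
#' @param sim_minutes Simulation step for the velocity process, minutes.
#' @param seed Integer seed (selects the per-day draws and the noise).
#' @return A position trajectory with times in hours.
#' @export
simulate_from_latents <- function(sigma_draws, L_draws, draw_times,
                                  n_days = 30, fix_minutes = 10,
                                  sim_minutes = 1, seed = 1) {
  sigma_draws <- as.matrix(sigma_draws); L_draws <- as.matrix(L_draws)
  if (nrow(sigma_draws) == 0L) stop("need at least one posterior draw")
  if (!all(dim(sigma_draws) == dim(L_draws)))
    stop("sigma_draws and L_draws must have matching dimensions")
  if (ncol(sigma_draws) != length(draw_times))
    stop("draw_times must match the draw matrices' columns")
  step <- fix_minutes / sim_minutes
  if (abs(step - round(step)) > 1e-8)
    stop("fix_minutes must be a multiple of sim_minutes")
  set.seed(seed)
  dt <- sim_minutes / 60
  per_day <- as.integer(round(24 / dt))
  n <- n_days * per_day + 1L
  t_sim <- (seq_len(n) - 1L) * dt
  day_of <- pmin(floor(t_sim / 24), n_days - 1L)
  draw_idx <- sample.int(nrow(sigma_draws), n_days, replace = TRUE)
  # periodic linear interpolation of each day's drawn functions at time-of-day
  interp_day <- function(mat_row, tod) {
    ot <- order(draw_times); dtms <- draw_times[ot]; vals <- mat_row[ot]
    stats::approx(x = c(dtms, dtms[1L] + 24), y = c(vals, vals[1L]),
                  xout = tod %% 24, rule = 2)$y
  }
  sig_t <- numeric(n); L_t <- numeric(n)
  for (d in seq_len(n_days)) {
    sel <- which(day_of == d - 1L)
    sig_t[sel] <- interp_day(sigma_draws[draw_idx[d], ], t_sim[sel])
    L_t[sel] <- interp_day(L_draws[draw_idx[d], ], t_sim[sel])
  }
  nu_t <- 1 / L_t
  decay <- exp(-nu_t[-n] * dt)
  sd_step <- sqrt(sig_t[-n]^2 * (1 - decay^2))   # stationary sd sigma(t)
  v <- matrix(0, n, 2)
  noise <- matrix(stats::rnorm(2L * (n - 1L)), n - 1L, 2) * sd_step
  for (k in seq_len(n - 1L)) v[k + 1L, ] <- v[k, ] * decay[k] + noise[k, ]
  x <- apply(v[-n, , drop = FALSE] * dt, 2, cumsum)
  x <- rbind(c(0, 0), x)
  keep <- seq(1L, n, by = as.integer(round(step)))
  trajectory("ppc-sim", t_sim[keep], x[keep, , drop = FALSE], kind = "position")
}
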