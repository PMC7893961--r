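test_that("exact OU discretization has the closed-form one-step moments", {
  # noiseless process decays to the mean at the exact exponential rate
  nu <- 1.7; m <- c(2, -1); x0 <- c(5, 3)
  tr <- simulate_ou_2d(c(0, 0.4, 1.1), nu, eta = 0, mean = m, x0 = x0, seed = 1)
  expect_equal(unname(tr$values[2, ]), m + (x0 - m) * exp(-nu * 0.4), tolerance = 1e-12)
  expect_equal(unname(tr$values[3, ]), m + (x0 - m) * exp(-nu * 1.1), tolerance = 1e-12)
  # eta = 0 started at the mean stays there
  tr0 <- simulate_ou_2d(0:10, nu = 2, eta = 0, mean = c(1, 1), seed = 1)
  expect_true(all(tr0$values == 1))
})

test_that("long-run OU moments match the stationary law", {
  set.seed(11)
  tr <- simulate_ou_2d(seq(0, 10000, by = 0.05), nu = 2, eta = 1, seed = 42)
  v <- as.numeric(tr$values)
  expect_equal(mean(v), 0, tolerance = 0.02)
  expect_equal(var(v), 0.25, tolerance = 0.015)
  # empirical lag covariance matches the exponential kernel under the map
  th <- ou_to_kernel(2, 1)
  x <- tr$values[, 1]
  for (lag_t in c(0.25, 0.5)) {
    k <- as.integer(lag_t / 0.05)
    emp <- mean(x[seq_len(length(x) - k)] * x[-seq_len(k)])
    expect_lt(abs(emp - matern12_cov(0, lag_t, th$sigma_k, th$L)[1, 1]), 0.0075)
  }
})

test_that("OU simulation is reproducible and warns on coarse steps", {
  a <- simulate_ou_2d(0:20, 1, 1, seed = 5)
  b <- simulate_ou_2d(0:20, 1, 1, seed = 5)
  expect_identical(a$values, b$values)
  expect_warning(simulate_ou_2d(c(0, 100), nu = 1, eta = 1, seed = 1), "10 / nu")
})

test_that("daily activity amplitude is a smoothed, periodic, mean-preserving sawtooth", {
  h <- seq(0, 24, by = 1 / 60)[-1441]
  raw <- daily_activity_amplitude(h, smooth_width = 0)
  # raw sawtooth: flat base overnight, linear rise 5am-5pm, sharp drop
  expect_equal(raw[h == 2], 0.5)
  expect_equal(raw[h == 17 - 1 / 60], 3.0, tolerance = 0.01)
  expect_equal(raw[h == 18], 0.5)
  expect_equal(raw[h == 11], 0.5 + 2.5 * 0.5)
  sm <- daily_activity_amplitude(h, smooth_width = 1)
  expect_true(all(sm > 0))
  # periodicity is exact
  expect_equal(daily_activity_amplitude(h + 48), daily_activity_amplitude(h),
               tolerance = 1e-12)
  # circular smoothing preserves the mean level
  expect_equal(mean(sm), mean(raw), tolerance = 1e-10)
  # away from the kinks (> 3 smoothing widths) the ramp is preserved
  expect_lt(max(abs(sm - raw)[h > 9 & h < 14]), 0.02)
  expect_error(daily_activity_amplitude(h, base = -1), "positive")
})

test_that("migration mean follows the shifting-route equations", {
  m0 <- migration_mean(0)
  expect_equal(unname(m0[1, ]), c(0, 8))
  # cos term vanishes at quarter years: g = 1
  expect_equal(unname(migration_mean(0.25)[1, 2]), (5 - exp(-0.25 / 3)) * 1)
  # southern endpoint: g = 0
  expect_equal(unname(migration_mean(0.5)[1, 2]), 0, tolerance = 1e-12)
  # northern endpoint drifts towards 10 at integer years
  expect_equal(unname(migration_mean(100)[1, 2]), 10, tolerance = 1e-6)
  yrs <- 0:8
  ys <- migration_mean(yrs)[, 2]
  expect_true(all(diff(ys) > 0))
  expect_error(migration_mean(-1), "non-negative")
})

test_that("measurement noise has the right scale and seed determinism", {
  tr <- toy_trajectory(50)
  expect_identical(add_measurement_noise(tr, 0), tr)
  big <- trajectory("n", seq_len(1e5), matrix(0, 1e5, 2))
  noisy <- add_measurement_noise(big, 0.3, seed = 8)
  expect_equal(sd(noisy$values), 0.3, tolerance = 0.01)
  n1 <- add_measurement_noise(tr, 0.5, seed = 3)
  n2 <- add_measurement_noise(tr, 0.5, seed = 3)
  expect_identical(n1$values, n2$values)
})

test_that("simulating from latent draws is self-consistent", {
  tod <- seq(0, 23, by = 1)
  # constant latents: velocities must be a stationary OU with sd sigma
  sig <- 0.4; Lc <- 0.5
  traj <- simulate_from_latents(matrix(sig, 1, 24), matrix(Lc, 1, 24), tod,
                                n_days = 40, fix_minutes = 1, sim_minutes = 1,
                                seed = 2)
  v <- finite_difference_velocity(traj)
  expect_equal(sd(v$values), sig, tolerance = 0.08)
  vx <- v$values[, 1]
  rho <- cor(vx[-1], vx[-length(vx)])
  expect_equal(rho, exp(-(1 / 60) / Lc), tolerance = 0.02)
  # near-zero amplitude keeps the position essentially stationary
  still <- simulate_from_latents(matrix(1e-8, 1, 24), matrix(Lc, 1, 24), tod,
                                 n_days = 2, fix_minutes = 10, seed = 2)
  expect_lt(max(abs(still$values)), 1e-5)
  # determinism
  t2 <- simulate_from_latents(matrix(sig, 1, 24), matrix(Lc, 1, 24), tod,
                              n_days = 2, fix_minutes = 10, seed = 9)
  t3 <- simulate_from_latents(matrix(sig, 1, 24), matrix(Lc, 1, 24), tod,
                              n_days = 2, fix_minutes = 10, seed = 9)
  expect_identical(t2$values, t3$values)
})

test_that("study-condition generators emit the documented schedules and metadata", {
  tr <- simulate_daily_activity(n_days = 2, fix_minutes = 10, seed = 4)
  expect_length(tr$times, 2 * 144)
  expect_equal(diff(tr$times)[1], 1 / 6)
  expect_equal(attr(tr, "generator")$nu, 12)
  trm <- simulate_migration(years = 2, seed = 4)
  expect_equal(diff(trm$times)[1], 7 / 365)
  # trajectories concentrate around the migration mean
  mid <- abs(trm$times - 1) < 0.05
  expect_lt(mean(abs(trm$values[mid, 2] - migration_mean(trm$times[mid])[, 2])), 1.5)
})
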