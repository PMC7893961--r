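square_trajectory <- function(laps = 3) {
  # corners plus edge midpoints, half-unit time spacing: window-1 boundaries
  # land exactly on the corners
  lap <- matrix(c(0, 0, 0.5, 0, 1, 0, 1, 0.5, 1, 1, 0.5, 1, 0, 1, 0, 0.5),
                ncol = 2, byrow = TRUE)
  xy <- lap[rep(seq_len(8), laps), ]
  trajectory("sq", 0.5 * (seq_len(nrow(xy)) - 1L), xy)
}

test_that("steps and turns handle canonical geometries", {
  # collinear equal-spaced points: zero turns, constant steps
  tr <- trajectory("line", 0:10, cbind(2 * (0:10), 0:10))
  st <- steps_and_turns(tr, window = 2)
  expect_equal(st$turn_angles, rep(0, length(st$turn_angles)))
  expect_equal(st$step_lengths, rep(2 * sqrt(5), length(st$step_lengths)))
  expect_equal(length(st$turn_angles), length(st$step_lengths) - 1L)
  # exact reversal gives a turn of +pi
  tb <- trajectory("back", seq(0, 2, by = 0.5),
                   cbind(c(0, 0.5, 1, 0.5, 0), 0))
  expect_equal(steps_and_turns(tb, window = 1)$turn_angles, pi)
  # square traversal: unit steps, right-angle turns of one sign
  sq <- steps_and_turns(square_trajectory(), window = 1)
  expect_true(all(abs(sq$step_lengths - 1) < 1e-12))
  expect_true(all(abs(abs(sq$turn_angles) - pi / 2) < 1e-12))
  expect_error(steps_and_turns(tb, window = 0.5), "twice the median")
})

test_that("step lengths are rotation-invariant and turns flip under reflection", {
  set.seed(23)
  n <- 200
  xy <- apply(matrix(rnorm(2 * n, 0, 0.5), n, 2), 2, cumsum)
  tr <- trajectory("w", seq_len(n), xy)
  base <- steps_and_turns(tr, window = 4)
  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- trajectory("wr", seq_len(n), xy %*% Rm)
  rotated <- steps_and_turns(rot, window = 4)
  expect_equal(rotated$step_lengths, base$step_lengths, tolerance = 1e-10)
  expect_equal(rotated$turn_angles, base$turn_angles, tolerance = 1e-10)
  mir <- trajectory("wm", seq_len(n), cbind(xy[, 1], -xy[, 2]))
  mirrored <- steps_and_turns(mir, window = 4)
  expect_equal(mirrored$turn_angles, -base$turn_angles, tolerance = 1e-10)
})

test_that("distribution comparison reports KS distances and critical values", {
  mk <- function(steps, turns = rep(0, max(0, length(steps) - 1)))
    structure(list(window = 2, step_lengths = steps, turn_angles = turns,
                   n_blocks = 1L), class = "movegp_stepturn")
  a <- mk(c(1, 2, 3, 4, 5))
  expect_equal(compare_distributions(a, a)$ks_distance, 0)
  b <- mk(c(10, 11, 12, 13))
  expect_equal(compare_distributions(a, b)$ks_distance, 1)
  set.seed(3)
  big1 <- mk(rexp(600)); big2 <- mk(rexp(600))
  rep <- compare_distributions(big1, big2)
  expect_lt(rep$ks_distance, rep$ks_critical[["0.01"]])
  expect_error(compare_distributions(a, mk(numeric(0))), "non-empty")
})

test_that("model-simulated movement shows fewer reversals than reversal-laden movement", {
  set.seed(41)
  tod <- 0:23
  sig <- matrix(daily_activity_amplitude(tod) / sqrt(24), 1, 24)
  Lr <- matrix(1, 1, 24)
  sim <- simulate_from_latents(sig, Lr, tod, n_days = 30, fix_minutes = 60,
                               sim_minutes = 5, seed = 6)
  # reversal-laden comparator: a correlated walk on the same hourly schedule
  # whose heading flips by pi with probability 0.3 at each step
  n <- length(sim$times)
  turn_noise <- rnorm(n - 1L, 0, 0.3)
  flips <- pi * (runif(n - 1L) < 0.3)
  heading <- cumsum(turn_noise + flips)
  step_len <- abs(rnorm(n - 1L, 0.5, 0.1))
  rev_traj <- trajectory("rev", sim$times,
                         apply(rbind(c(0, 0),
                                     cbind(step_len * cos(heading),
                                           step_len * sin(heading))), 2, cumsum))
  near_pi <- function(tr) {
    st <- steps_and_turns(tr, window = 2)
    mean(abs(st$turn_angles) > 3 * pi / 4)
  }
  expect_gt(near_pi(rev_traj), near_pi(sim) + 0.1)
})

test_that("matched simulations from one model pass the KS check at both windows", {
  tod <- 0:23
  sig <- matrix(daily_activity_amplitude(tod) / sqrt(24), 1, 24)
  Lr <- matrix(0.5, 1, 24)
  s1 <- steps_and_turns(simulate_from_latents(sig, Lr, tod, n_days = 40,
                                              fix_minutes = 10, sim_minutes = 5,
                                              seed = 101), window = 2)
  s2 <- steps_and_turns(simulate_from_latents(sig, Lr, tod, n_days = 40,
                                              fix_minutes = 10, sim_minutes = 5,
                                              seed = 202), window = 2)
  rep2 <- compare_distributions(s1, s2)
  expect_lt(rep2$ks_distance, rep2$ks_critical[["0.01"]])
})
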