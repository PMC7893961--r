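test_that("data likelihood matches a direct multivariate-normal evaluation", {
  # oracle: generic MVN log density via solve() and determinant()
  set.seed(21)
  for (rep in 1:3) {
    n <- 12
    t <- sort(runif(n, 0, 5))
    sig <- runif(n, 0.5, 2)
    L <- runif(n, 0.5, 3)
    mean_t <- cbind(rnorm(n), rnorm(n))
    y <- cbind(rnorm(n), rnorm(n))
    sm <- 0.3
    C <- nonstationary_matern12_cov(nonstationary_inputs(t, sig, L)) +
      sm^2 * diag(n) + 1e-6 * mean(sig^2 + sm^2) * diag(n)
    oracle <- mvn_logpdf_direct(y[, 1], mean_t[, 1], C) +
      mvn_logpdf_direct(y[, 2], mean_t[, 2], C)
    ours <- log_data_likelihood(t, y, sig, L, mean_t, sigma_m = sm)
    expect_equal(ours, oracle, tolerance = 1e-7)
  }
})

test_that("single-point zero-mean unit-variance likelihood equals two standard normals", {
  val <- log_data_likelihood(times = 0, values = matrix(0, 1, 2),
                             sigma_t = 1, L_t = 1, sigma_m = 0)
  expect_equal(val, 2 * (-0.5 * log(2 * pi)), tolerance = 1e-5)
  # inflating the variance with sigma_m lowers the density at the mean
  with_noise <- log_data_likelihood(0, matrix(0, 1, 2), 1, 1, sigma_m = 0.5)
  expect_lt(with_noise, val)
})

test_that("log posterior is additive over independent identical segments", {
  mod <- make_constant_model()
  tr <- toy_trajectory(30, seed = 5)
  x <- initial_state(mod, list(log_sigma = 0.2, log_L = 0.1))
  lp1 <- log_posterior(x, mod, list(tr), grad = FALSE)
  lp2 <- log_posterior(x, mod, list(tr, tr), grad = FALSE)
  ll_seg <- log_data_likelihood(tr$times, tr$values,
                                sigma_t = exp(0.2), L_t = exp(0.1))
  expect_equal(lp2 - lp1, ll_seg, tolerance = 1e-6)
  # order of segments is irrelevant
  tr2 <- toy_trajectory(25, seed = 6)
  lp_ab <- log_posterior(x, mod, list(tr, tr2), grad = FALSE)
  lp_ba <- log_posterior(x, mod, list(tr2, tr), grad = FALSE)
  expect_equal(lp_ab, lp_ba, tolerance = 1e-10)
  expect_error(prepare_likelihood(mod, list()), "no trajectory data")
})

test_that("all-zero whitened vectors contribute the standard-normal prior constant", {
  mod <- make_daily_model(m = 8)
  tr <- simulate_daily_activity(n_days = 1, fix_minutes = 60, seed = 2)
  x <- initial_state(mod)
  lp <- log_posterior(x, mod, list(tr), grad = FALSE)
  # subtracting the data term and scalar priors leaves m_total * (-log(2 pi)/2)
  up_sig <- realize_latent(mod$sigma$latent, rep(0, 8), tr$times, mu = 0,
                           hyper = c(a = 1, l = 1))
  ll <- log_data_likelihood(tr$times, tr$values, up_sig, rep(1, length(tr$times)))
  scal <- sum(dnorm(rep(0, 4), 0, 2, log = TRUE))  # mu_sigma, log a, log l, log_L
  expect_equal(lp - ll - scal, 8 * (-0.5 * log(2 * pi)), tolerance = 1e-8)
})

test_that("whitened posterior equals the direct hierarchical evaluation up to a constant", {
  # direct oracle: realize sigma(t) from the support values f = mu + R w and
  # evaluate data likelihood x GP prior on f x scalar priors; the whitened
  # form must differ only by the (state-independent) Jacobian constant
  sup <- daily_support(6)
  kern <- periodic_kernel(a = 0.9, l = 1.3, P = 24)
  lat <- latent_gp(kern, sup, mu = "estimate", nugget = 0)
  mod <- movement_model(sigma = lat, L = 0.4)
  stopifnot(identical(state_names(mod)[7], "mu_sigma"))
  tr <- toy_trajectory(20, seed = 31, dt = 1.3)
  K <- periodic_cov(sup, sup, 0.9, 1.3, 24)
  jit <- 1e-6 * mean(diag(K))
  R <- t(chol(K + jit * diag(6)))
  diffs <- replicate(5, {
    x <- c(rnorm(6, 0, 0.7), rnorm(1, 0, 0.5))
    names(x) <- state_names(mod)
    w <- x[1:6]; mu <- x[7]
    ours <- log_posterior(x, mod, list(tr), grad = FALSE)
    f_sup <- mu + as.numeric(R %*% w)
    sig_t <- realize_latent(lat, w, tr$times, mu = mu)
    direct <- log_data_likelihood(tr$times, tr$values, sig_t, 0.4) +
      mvn_logpdf_direct(f_sup, rep(mu, 6), K + jit * diag(6)) +
      dnorm(mu, 0, 2, log = TRUE)
    ours - direct
  })
  expect_lt(diff(range(diffs)), 1e-8)
})

test_that("analytic gradients match central finite differences on random states", {
  mods <- list(
    list(mod = make_daily_model(m = 6),
         data = list(simulate_daily_activity(n_days = 1, fix_minutes = 60, seed = 3))),
    list(mod = movement_model(sigma = "estimate", L = "estimate",
                              sigma_m = "estimate",
                              mean = latent_gp(quasiperiodic_kernel("estimate", 5,
                                                                    "estimate", 1),
                                               place_support_points(0, 2, 5),
                                               mu = 0, transform = "identity")),
         data = list(trajectory("m", seq(0, 2, length.out = 25),
                                matrix(rnorm(50), 25, 2)))))
  for (case in mods) {
    plan <- prepare_likelihood(case$mod, case$data)
    set.seed(17)
    x <- initial_state(case$mod) + rnorm(case$mod$index$d, 0, 0.3)
    g <- attr(log_posterior(x, case$mod, plan), "gradient")
    h <- 1e-5
    fd <- vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (log_posterior(xp, case$mod, plan, grad = FALSE) -
         log_posterior(xm, case$mod, plan, grad = FALSE)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-4)
  }
})

test_that("state packing round-trips and model validation catches misuse", {
  mod <- make_migration_model(years = 2, m = 5)
  expect_equal(mod$index$d, 5 + 5 + 2 + 2)
  x <- initial_state(mod, list(log_sigma = -0.7, w_mean_x = rep(0.2, 5)))
  expect_equal(unname(x[grep("^w_mean_x", state_names(mod))]), rep(0.2, 5))
  expect_error(initial_state(mod, list(nope = 1)), "unknown state block")
  expect_error(movement_model(sigma = -2, L = 1), "positive")
  expect_error(movement_model(sigma = 1, L = 1,
                              mean = latent_gp(matern12_kernel(1, 1), 0:3)),
               "identity transform")
  expect_error(log_posterior(c(0, 0), mod, list(toy_trajectory(10))), "wrong length")
})
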