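# closed-form Gaussian targets for the sampler checks
gauss_target <- function(mu, Sigma) {
  Si <- solve(Sigma)
  function(x) {
    r <- x - mu
    lp <- -0.5 * sum(r * (Si %*% r))
    attr(lp, "gradient") <- as.numeric(-Si %*% r)
    lp
  }
}

test_that("a zero gradient reduces MALA to symmetric random-walk Metropolis", {
  flat <- function(x) { lp <- 0; attr(lp, "gradient") <- numeric(length(x)); lp }
  set.seed(2)
  st <- mala_step(c(0, 0), flat, step_size = 0.5)
  # flat target + symmetric proposal: always accepted with log ratio 0
  expect_true(st$accepted)
  expect_equal(st$log_ratio, 0)
})

test_that("MALA reproduces the moments of closed-form Gaussian targets", {
  set.seed(31)
  # 1-D standard normal
  lp <- gauss_target(0, matrix(1))
  x <- 0; cur <- NULL
  n <- 20000L
  draws <- numeric(n)
  for (k in seq_len(n)) {
    st <- mala_step(x, lp, step_size = 1.2, current = cur)
    x <- st$state; cur <- st$current
    draws[k] <- x
  }
  ess <- effective_sample_size(array(draws, c(1, n, 1)))$min
  expect_lt(abs(mean(draws)), 3 / sqrt(ess))
  expect_equal(var(draws), 1, tolerance = 0.1)
  # 2-D correlated Gaussian
  Sigma <- matrix(c(1, 0.8, 0.8, 2), 2)
  lp2 <- gauss_target(c(1, -1), Sigma)
  x <- c(1, -1); cur <- NULL
  d2 <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    st <- mala_step(x, lp2, step_size = 0.6, current = cur)
    x <- st$state; cur <- st$current
    d2[k, ] <- x
  }
  expect_equal(colMeans(d2), c(1, -1), tolerance = 0.1)
  expect_equal(cov(d2), Sigma, tolerance = 0.15)
})

test_that("mala_step rejects infeasible proposals and errors on a bad current state", {
  lp_bad <- function(x) { lp <- NaN; attr(lp, "gradient") <- rep(NaN, 2); lp }
  expect_error(mala_step(c(0, 0), lp_bad, 0.1), "non-finite")
  # a target that dies away from the origin: chain stays finite
  lp_wall <- function(x) {
    if (sum(x^2) > 0.5) return(-Inf)
    lp <- 0; attr(lp, "gradient") <- c(0, 0); lp
  }
  set.seed(4)
  st <- mala_step(c(0, 0), lp_wall, step_size = 5)
  expect_false(st$accepted)
  expect_identical(st$state, c(0, 0))
})

test_that("run_chains is deterministic, thins correctly and adapts acceptance", {
  mod <- make_constant_model()
  tr <- toy_trajectory(40, seed = 10)
  cfg <- sampler_config(n_steps = 1200, n_burnin = 400, thin = 4, n_chains = 2,
                        seed = 77)
  s1 <- run_chains(mod, tr, cfg, progress = FALSE)
  s2 <- run_chains(mod, tr, cfg, progress = FALSE)
  expect_identical(s1$draws, s2$draws)
  expect_equal(dim(s1$draws), c(2L, 200L, 2L))
  expect_true(all(is.finite(s1$draws)))
  # adapted acceptance lands near the MALA-optimal target
  expect_true(all(abs(s1$acceptance - cfg$target_acceptance) < 0.2))
  # chains are exchangeable but not identical, and mutually independent
  expect_false(identical(s1$draws[1, , ], s1$draws[2, , ]))
  expect_lt(abs(cor(s1$draws[1, , 1], s1$draws[2, , 1])), 0.35)
})

test_that("PSRF separates converged from divergent chain sets", {
  set.seed(12)
  n <- 10000L
  a <- array(rnorm(4 * n), c(4, n, 1))
  r <- psrf(a)
  expect_gt(r$max, 0.99)
  expect_lt(r$max, 1.02)
  b <- a
  b[1, , 1] <- b[1, , 1] + 100
  expect_gt(psrf(b)$max, 1.5)
  # two long chains from one distribution approach 1
  cc <- array(rnorm(2 * 50000L), c(2, 50000L, 1))
  expect_equal(psrf(cc)$max, 1, tolerance = 0.01)
  expect_error(psrf(a[, 1:5, , drop = FALSE]), "10 draws")
  expect_error(psrf(a[1, , , drop = FALSE]), "2 chains")
  degenerate <- array(1, c(2, 100, 1))
  expect_error(psrf(degenerate), "degenerate")
})

test_that("effective sample size matches the AR(1) oracle", {
  set.seed(13)
  n <- 40000L
  # iid draws: ESS is essentially the number of draws (capped there)
  iid <- array(rnorm(n), c(1, n, 1))
  expect_gt(effective_sample_size(iid)$min, 0.8 * n)
  expect_lte(effective_sample_size(iid)$min, n)
  # AR(1) with known autocorrelation: ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.7
  x <- as.numeric(arima.sim(list(ar = rho), n))
  ess <- effective_sample_size(array(x, c(1, n, 1)))$min
  expect_equal(ess, n * (1 - rho) / (1 + rho), tolerance = 0.15)
  # an almost perfectly correlated chain has a tiny ESS
  y <- as.numeric(arima.sim(list(ar = 0.995), n))
  expect_lt(effective_sample_size(array(y, c(1, n, 1)))$min, n / 100)
})

test_that("Adam optimization recovers stationary kernel parameters", {
  set.seed(14)
  sig_true <- 1.4; L_true <- 3
  th <- kernel_to_ou(sig_true^2, L_true)
  tr <- simulate_ou_2d(seq_len(500), nu = th$nu, eta = th$eta, seed = 15)
  mod <- make_constant_model()
  segs <- segment_trajectory(tr, 250)
  fit <- optimize_hyperparameters(mod, segs, n_iter = 400, lr = 0.05)
  expect_lt(abs(fit$theta[["sigma"]] - sig_true) / sig_true, 0.25)
  expect_lt(abs(fit$theta[["L"]] - L_true) / L_true, 0.25)
  # loss settles: the last stretch is no longer improving materially
  expect_lt(abs(mean(tail(fit$loss_trace, 20)) - min(fit$loss_trace)), 1)
  # restarting at the optimum does not move the loss upward
  fit2 <- optimize_hyperparameters(mod, segs, n_iter = 50, lr = 0.002,
                                   init = list(log_sigma = log(fit$theta[["sigma"]]),
                                               log_L = log(fit$theta[["L"]])))
  expect_lt(max(fit2$loss_trace) - min(fit2$loss_trace), 0.5)
  # 1-D problem: Adam lands on the same optimum as an exhaustive grid search
  set.seed(99)
  modq <- movement_model(sigma = "estimate", L = 1)
  trq <- trajectory("q", 1:60, matrix(rnorm(120), 60, 2))
  planq <- prepare_likelihood(modq, trq)
  grid <- seq(-1, 1, by = 0.001)
  loss_grid <- vapply(grid, function(v)
    -log_posterior(c(log_sigma = v), modq, planq, grad = FALSE), 0)
  fq <- optimize_hyperparameters(modq, planq, n_iter = 300, lr = 0.05)
  expect_lt(abs(log(fq$theta[["sigma"]]) - grid[which.min(loss_grid)]), 0.02)
})
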