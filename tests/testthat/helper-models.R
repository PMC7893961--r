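# small model/data builders shared across test files

daily_support <- function(m = 40) place_support_points(0, 24, m, periodic = TRUE)

make_daily_model <- function(m = 40, parameterization = "whitened") {
  movement_model(
    sigma = latent_gp(periodic_kernel(a = "estimate", l = "estimate", P = 24),
                      daily_support(m), parameterization = parameterization),
    L = "estimate")
}

make_migration_model <- function(years = 3, m = 36,
                                 parameterization = "whitened") {
  movement_model(
    sigma = "estimate", L = "estimate",
    mean = latent_gp(quasiperiodic_kernel(a = "estimate", lambda = 5,
                                          l = "estimate", P = 1),
                     place_support_points(0, years, m),
                     mu = 0, transform = "identity",
                     parameterization = parameterization))
}

# constant-parameter model (standard stationary OU fit)
make_constant_model <- function(sigma_m = 0) {
  movement_model(sigma = "estimate", L = "estimate", sigma_m = sigma_m)
}

# toy trajectory with given times and iid-ish values
toy_trajectory <- function(n = 20, seed = 1, dt = 1, kind = "position") {
  set.seed(seed)
  trajectory("toy", cumsum(rep(dt, n)), matrix(rnorm(2 * n), n, 2), kind = kind)
}

# direct multivariate-normal log density: independent oracle using solve()
# and determinant(), no Cholesky plumbing shared with the package internals
mvn_logpdf_direct <- function(y, mean, Sigma) {
  n <- length(y)
  r <- y - mean
  -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    0.5 * sum(r * solve(Sigma, r))
}

# independent evaluation of the non-stationary Matern 1/2 entry
ns_matern_entry_direct <- function(t1, t2, s1, s2, L1, L2) {
  sqrt(2 * s1^2 * s2^2 * L1 * L2 / (L1^2 + L2^2)) *
    exp(-sqrt(2 * (t1 - t2)^2 / (L1^2 + L2^2)))
}
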