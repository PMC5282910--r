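# Independent numerical oracles used to cross-check the simulator.

# Marginal survival of the event of interest, mortality ignored:
# S(t) = E_eps[ exp(-(t/scale)^shape * e^(eta0 + eps)) ], eps ~ N(0, sigma^2),
# by adaptive quadrature over the normal density.
marginal_survival_oracle <- function(t, scale, shape, sigma, eta0 = 0) {
  vapply(t, function(ti) {
    f <- function(e) exp(-(ti / scale)^shape * exp(eta0 + e)) * dnorm(e, 0, sigma)
    integrate(f, -8 * sigma - 1, 8 * sigma + 1, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Mean and SD of the ten-year risk over the frailty distribution, by
# quadrature (independent of the package's Monte-Carlo route).
risk_moments_oracle <- function(scale = 36, shape = 1.2, sigma = 0.7,
                                eta0 = 0, horizon = 10) {
  h <- (horizon / scale)^shape
  m1 <- integrate(function(e) (1 - exp(-h * exp(eta0 + e))) * dnorm(e, 0, sigma),
                  -10, 10, rel.tol = 1e-10)$value
  m2 <- integrate(function(e) (1 - exp(-h * exp(eta0 + e)))^2 * dnorm(e, 0, sigma),
                  -10, 10, rel.tol = 1e-10)$value
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Brute-force draw of observed control-arm data (no refusal machinery):
# straight Weibull draws plus independent mortality and administrative
# censoring, written independently of the package's samplers.
brute_force_control <- function(n, params, eps = NULL) {
  if (is.null(eps)) eps <- rnorm(n, 0, params$sigma)
  tc <- rweibull(n, shape = params$gamma_c,
                 scale = params$lambda_c * exp(-eps / params$gamma_c))
  tm <- rweibull(n, shape = params$gamma_m,
                 scale = params$lambda_m * exp(-eps / params$gamma_m))
  y <- pmin(tc, tm, params$t_max)
  data.frame(y = y, event = as.integer(tc < pmin(tm, params$t_max)))
}

quick_scenario <- function(p = 0, level = "zero", direction = "positive",
                           q = 0, n_obs = 1000, n_sim = 10, seed = 1)
  cmrct_scenario(refusal_spec(p = p, q = q, level = level, direction = direction),
                 n_obs = n_obs, n_sim = n_sim, seed = seed)
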