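test_that("frailty draws honour the variance, the seed, and degenerate sigma", {
  expect_identical(draw_frailties(5, 0, seed = 1), rep(0, 5))
  expect_identical(draw_frailties(3, 0.7, seed = 11), draw_frailties(3, 0.7, seed = 11))
  e <- draw_frailties(1e5, 0.7, seed = 2)
  expect_lt(abs(mean(e)), 0.01)
  expect_lt(abs(sd(e) - 0.7), 0.01)
  expect_error(draw_frailties(0, 0.7), "positive integer")
  expect_error(draw_frailties(5, -0.1), "non-negative")
})

test_that("cumulative hazard matches the closed form and is proportional in exp(eta)", {
  expect_equal(weibull_cum_hazard(36, 36, 1.2), 1.0)
  expect_equal(weibull_cum_hazard(0, 36, 1.2), 0)
  expect_equal(weibull_cum_hazard(10, 36, 1.2), (10 / 36)^1.2)
  expect_equal(round(weibull_cum_hazard(10, 36, 1.2), 4), 0.2150)
  t_grid <- c(0.5, 1, 2, 10, 36)
  expect_equal(weibull_cum_hazard(t_grid, 36, 1.2, eta = log(2)),
               2 * weibull_cum_hazard(t_grid, 36, 1.2))
  expect_true(all(diff(weibull_cum_hazard(t_grid, 36, 1.2)) > 0))
  expect_error(weibull_cum_hazard(-1, 36, 1.2), "non-negative")
})

test_that("event-time sampling follows the Weibull PH distribution", {
  tt <- sample_event_time(1e5, 36, 1.2, eta = 0, seed = 3)
  expect_true(all(tt > 0))
  # closed-form CDF at t = 10
  expect_lt(abs(mean(tt <= 10) - (1 - exp(-(10 / 36)^1.2))), 0.01)
  # exponential special case: shape 1 has mean equal to the scale
  expect_lt(abs(mean(sample_event_time(1e5, 36, 1, seed = 4)) / 36 - 1), 0.02)
  # monotone in eta for the same underlying uniforms
  t0 <- sample_event_time(100, 36, 1.2, eta = 0, seed = 5)
  t1 <- sample_event_time(100, 36, 1.2, eta = 1, seed = 5)
  expect_true(all(t1 < t0))
})

test_that("ten-year risk matches closed forms and is monotone in frailty and treatment", {
  p <- cmrct_params()
  expect_equal(round(ten_year_risk(0, p), 4), 0.1935)
  expect_equal(ten_year_risk(0, p, treated = 1),
               1 - exp(-(10 / 36)^1.2 * exp(-0.32)))
  expect_equal(round(ten_year_risk(0, p, treated = 1), 4), 0.1445)
  eps <- seq(-2, 2, by = 0.5)
  r <- ten_year_risk(eps, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(ten_year_risk(eps, p, treated = 1) < r))
  expect_true(all(r > 0 & r < 1))
})

test_that("population risk summary agrees with the quadrature oracle", {
  deg <- population_risk_summary(100, cmrct_params(sigma = 0), seed = 1)
  expect_equal(deg$sd, 0)
  expect_equal(round(deg$mean, 4), 0.1935)
  oracle <- risk_moments_oracle()
  mc <- population_risk_summary(1e5, seed = 6)
  expect_lt(abs(mc$mean - oracle$mean), 0.005)
  expect_lt(abs(mc$sd - oracle$sd), 0.005)
})

test_that("latent-time dependence: analytic log-scale value and Monte-Carlo agreement", {
  expect_equal(latent_time_log_correlation(0), 0)
  expect_equal(round(latent_time_log_correlation(0.7), 4), 0.2295)
  expect_gt(latent_time_log_correlation(50), 0.999)
  expect_error(latent_time_log_correlation(0.7, shape_c = 1.2, shape_m = 1),
               "equal Weibull shapes")
  mc <- latent_time_correlation(1e5, scale = "log", seed = 7)
  expect_lt(abs(mc - latent_time_log_correlation(0.7)), 0.01)
  # the shared frailty induces positive dependence on every scale
  expect_gt(latent_time_correlation(2e4, scale = "raw", seed = 8), 0.2)
  expect_gt(latent_time_correlation(2e4, scale = "rank", seed = 8), 0.2)
})

test_that("simulated control-arm survival matches the integrated marginal curve", {
  p <- cmrct_params()
  n <- 1e5
  set.seed(9)
  eps <- rnorm(n, 0, p$sigma)
  tt <- sample_event_time(n, p$lambda_c, p$gamma_c, eta = eps)
  s_emp <- sapply(1:3, function(t0) mean(tt > t0))
  s_orc <- marginal_survival_oracle(1:3, p$lambda_c, p$gamma_c, p$sigma)
  expect_true(all(abs(s_emp - s_orc) < 0.01))
})
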