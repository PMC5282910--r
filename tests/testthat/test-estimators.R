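test_that("the Cox workhorse recovers a null and is rank-invariant", {
  set.seed(1)
  n <- 4000
  grp <- rbinom(n, 1, 0.5)
  tm <- rexp(n)
  f <- fit_ph(tm, rep(1, n), cbind(g = grp))
  expect_lt(abs(f[1, "coef"]), 3 * f[1, "se"])
  f2 <- fit_ph(2 * tm, rep(1, n), cbind(g = grp))
  expect_equal(f2[1, "coef"], f[1, "coef"])
  expect_error(fit_ph(tm, rep(0, n), cbind(g = grp)), "no events")
  expect_error(fit_ph(tm, rep(1, n), cbind(g = rep(1, n))), "degenerate design")
})

test_that("ITT recovers the conditional effect when frailty and refusal are absent", {
  p <- cmrct_params(sigma = 0)
  tr <- simulate_trial(p, quick_scenario(n_obs = 20000, seed = 21))
  fit <- estimate_itt(tr)
  expect_lt(abs(fit$estimate - p$beta), 3 * fit$se)
  expect_equal(fit$n_used, 20000L)
})

test_that("all four estimators coincide under perfect compliance", {
  tr <- simulate_trial(cmrct_params(), quick_scenario(n_obs = 5000, seed = 31))
  expect_true(all(tr$x == tr$z))
  fit <- suppressWarnings(cmrct_analyze(tr))
  expect_equal(fit$uptake, 1)
  expect_true(all(abs(fit$fits$estimate - fit$fits$estimate[1]) < 1e-12))
  expect_true(all(abs(fit$fits$p_value - fit$fits$p_value[1]) < 1e-12))
  expect_warning(estimate_2sri(tr), "perfect compliance")
})

test_that("the first stage is the saturated (arm-mean) regression", {
  fs <- first_stage(c(0, 0, 1, 1, 1, 1, 1), c(0, 0, 1, 1, 1, 1, 0))
  expect_equal(fs$uptake, 0.8)
  expect_equal(fs$fitted, c(0, 0, rep(0.8, 5)))
  expect_equal(sum(fs$residuals[1:2]), 0)
  expect_equal(sum(fs$residuals[3:7]), 0)
  # full compliance: fitted = z, residuals identically zero
  fs2 <- first_stage(c(0, 1, 1), c(0, 1, 1))
  expect_equal(fs2$fitted, c(0, 1, 1))
  expect_true(all(fs2$residuals == 0))
  expect_error(first_stage(c(1, 1), c(1, 0)), "both arms")
})

test_that("2SPS is the ITT rescaled by uptake, with identical p-values", {
  p <- cmrct_params()
  for (s in 1:3) {
    scn <- quick_scenario(p = 0.2, level = c("zero", "low", "high")[s],
                          n_obs = 4000, seed = 40 + s)
    tr <- simulate_trial(p, scn)
    itt <- estimate_itt(tr)
    sps <- estimate_2sps(tr)
    uptake <- mean(tr$x[tr$z == 1])
    expect_equal(sps$estimate, itt$estimate / uptake, tolerance = 1e-10)
    expect_equal(sps$p_value, itt$p_value, tolerance = 1e-10)
    expect_equal(sps$se, itt$se / uptake, tolerance = 1e-10)
  }
})

test_that("per-protocol drops intervention-arm refusers and only them", {
  tr <- simulate_trial(cmrct_params(),
                       quick_scenario(p = 0.3, level = "high", n_obs = 5000, seed = 55))
  pp <- estimate_pp(tr)
  expect_equal(pp$n_used, nrow(tr) - sum(tr$z == 1 & tr$x == 0))
  # PP exclusion leaves x == z, so fitting on x equals fitting on z
  keep <- !(tr$z == 1 & tr$x == 0)
  expect_true(all(tr$x[keep] == tr$z[keep]))
})

test_that("2SRI includes the residual and keeps the x coefficient as the estimate", {
  tr <- simulate_trial(cmrct_params(),
                       quick_scenario(p = 0.2, level = "high", n_obs = 6000, seed = 66))
  sri <- estimate_2sri(tr)
  fs <- first_stage(tr$z, tr$x)
  direct <- fit_ph(tr$y, tr$event, cbind(x = tr$x, r = fs$residuals))
  expect_equal(sri$estimate, unname(direct["x", "coef"]))
  expect_equal(sri$se, unname(direct["x", "se"]))
})

test_that("IV standard errors are no smaller than ITT's on the same data", {
  p <- cmrct_params()
  ok <- logical(0)
  for (s in 1:5) {
    tr <- simulate_trial(p, quick_scenario(p = 0.2, level = "medium",
                                           n_obs = 4000, seed = 70 + s))
    fit <- cmrct_analyze(tr)$fits
    ok <- c(ok, fit$se[fit$method == "2SPS"] >= fit$se[fit$method == "ITT"],
            fit$se[fit$method == "2SRI"] >= fit$se[fit$method == "ITT"])
  }
  expect_true(all(ok))
})

test_that("analysis accepts generic censored-survival tables", {
  tr <- simulate_trial(cmrct_params(), quick_scenario(p = 0.2, level = "low",
                                                      n_obs = 2000, seed = 80))
  generic <- data.frame(time = tr$y, event = tr$event, z = tr$z, x = tr$x)
  f1 <- cmrct_analyze(generic, methods = c("ITT", "2SRI"))
  f2 <- cmrct_analyze(tr, methods = c("ITT", "2SRI"))
  expect_equal(f1$fits$estimate, f2$fits$estimate)
  expect_named(coef(f1), c("ITT", "2SRI"))
  ci <- confint(f2)
  expect_true(all(ci[, 1] < f2$fits$estimate & f2$fits$estimate < ci[, 2]))
})
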