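test_that("replicate summaries match hand-computed definitions", {
  f <- data.frame(method = "ITT", estimate = c(-0.2, -0.4), se = 0.1,
                  p_value = c(0.01, 0.20), n_used = 100L)
  s <- summarize_fits(f, beta_true = -0.32)
  expect_equal(s$mean_estimate, -0.3)
  expect_equal(s$rel_bias_pct, 100 * (-0.3 + 0.32) / (-0.32))  # -6.25
  expect_equal(s$rel_bias_pct, -6.25)
  expect_equal(s$power, 0.5)
  expect_equal(s$empirical_se, sd(c(-0.2, -0.4)))
  expect_equal(s$mc_se_of_mean, s$empirical_se / sqrt(2))
  # aggregation is order-invariant
  expect_equal(summarize_fits(f[2:1, ], beta_true = -0.32)[-1], s[-1])
  # p-values above the threshold can move without changing power
  f2 <- f; f2$p_value[2] <- 0.4
  expect_equal(summarize_fits(f2, -0.32)$power, 0.5)
  expect_error(summarize_fits(data.frame(method = c("ITT", "PP"),
                                         estimate = 1, se = 1, p_value = 0.5,
                                         n_used = 1L), -0.32), "single method")
})

test_that("simulated power is the type-I error rate under the null", {
  p0 <- cmrct_params(beta = 0)
  pw <- simulated_power(400, p0, quick_scenario(p = 0.2, level = "zero"),
                        method = "ITT", n_rep = 400, seed = 9)
  expect_lt(abs(pw - 0.05), 0.035)
})

test_that("sample sizing brackets the power target and inflates for refusal", {
  fast <- list(n_rep = 100, n_rep_final = 200, granularity = 500)
  ss_wo <- do.call(required_sample_size,
                   c(list(recruitment = "without_refusal", seed = 17), fast))
  ss_wi <- do.call(required_sample_size,
                   c(list(recruitment = "with_refusal",
                          assumed_refusal = c(p = 0.2, q = 0), seed = 17), fast))
  expect_gt(ss_wi$n_obs, ss_wo$n_obs)
  expect_true(ss_wo$n_obs >= 5000 && ss_wo$n_obs <= 25000)
  expect_gte(ss_wo$power, 0.8 - 2 * sqrt(0.8 * 0.2 / 200))
  # self-consistency with an independent replication seed
  pw <- simulated_power(ss_wo$n_obs, cmrct_params(), quick_scenario(),
                        method = "ITT", n_rep = 200, seed = 1234)
  expect_lt(abs(pw - 0.8), 2 * sqrt(0.8 * 0.2 / 200) + 0.02)
  # the trace records every evaluation and the report round-trips to CSV
  expect_true(all(c("n", "n_rep", "power", "stage") %in% names(ss_wo$trace)))
  path <- tempfile(fileext = ".csv")
  write_samplesize(ss_wo, path)
  expect_equal(nrow(read.csv(path)), nrow(ss_wo$trace))
})
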