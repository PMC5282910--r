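test_that("randomisation allocates exactly and reproducibly", {
  z <- randomize_allocation(100, seed = 1)
  expect_equal(sum(z), 20)
  expect_equal(sum(randomize_allocation(101, seed = 1)), 20)  # round(101/5)
  expect_equal(sum(randomize_allocation(103, seed = 1)), 21)  # round(103/5)
  expect_identical(randomize_allocation(100, seed = 5), randomize_allocation(100, seed = 5))
  expect_equal(sum(randomize_allocation(90, allocation = c(2L, 1L), seed = 1)), 30)
  expect_error(randomize_allocation(3), "at least")
})

test_that("simulated trials satisfy the observed-data invariants", {
  p <- cmrct_params()
  for (spec in list(c(0.2, 1), c(0.3, -1), c(0, 1))) {
    scn <- quick_scenario(p = spec[1],
                          level = if (spec[1] > 0) "high" else "zero",
                          direction = if (spec[2] > 0) "positive" else "negative",
                          n_obs = 4000, seed = 100 + spec[1] * 10)
    tr <- simulate_trial(p, scn, keep_latent = TRUE)
    expect_equal(tr$y, pmin(tr$t_c, tr$t_m, p$t_max))
    expect_equal(tr$c, as.integer(tr$t_c >= pmin(tr$t_m, p$t_max)))
    expect_equal(tr$event, 1L - tr$c)
    expect_true(all(tr$x <= tr$z))
    expect_true(all(tr$y > 0 & tr$y <= p$t_max))
    expect_lt(abs(mean(tr$p_i) - spec[1]), 1e-12)
    expect_equal(sum(tr$z), round(4000 / 5))
  }
})

test_that("intervention-arm uptake averages (1-p)(1-q) under flat refusal", {
  p <- cmrct_params()
  scn <- cmrct_scenario(refusal_spec(p = 0.2, q = 0.1, level = "zero"),
                        n_obs = 20000, seed = 42)
  tr <- simulate_trial(p, scn)
  expect_lt(abs(mean(tr$x[tr$z == 1]) - 0.8 * 0.9), 0.02)
})

test_that("a null trial with no refusal has equal event rates in both arms", {
  p0 <- cmrct_params(beta = 0)
  tr <- simulate_trial(p0, quick_scenario(n_obs = 50000, seed = 7))
  r <- tapply(tr$event, tr$z, mean)
  expect_lt(abs(r[["0"]] - r[["1"]]), 0.005)
})

test_that("with sigma = 0 and full uptake the observed data match a brute-force draw", {
  p <- cmrct_params(sigma = 0)
  tr <- simulate_trial(p, quick_scenario(n_obs = 20000, seed = 13))
  ctrl <- tr[tr$z == 0, ]
  set.seed(14)
  oracle <- brute_force_control(20000, p)
  expect_lt(abs(mean(ctrl$event) - mean(oracle$event)), 0.01)
  ks <- suppressWarnings(ks.test(ctrl$y[ctrl$event == 1], oracle$y[oracle$event == 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("trials round-trip through CSV with both censoring conventions", {
  tr <- simulate_trial(cmrct_params(), quick_scenario(p = 0.2, level = "high",
                                                      n_obs = 500, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(back$y, tr$y)
  expect_equal(back$event, tr$event)
  expect_equal(back$c, 1L - back$event)
  # a generic table with `time` + `event` only is also accepted
  gen <- as_cmrct_trial(data.frame(time = tr$y, event = tr$event, z = tr$z, x = tr$x))
  expect_s3_class(gen, "cmrct_trial")
  expect_error(as_cmrct_trial(data.frame(time = 1, event = 1, z = 0, x = 1)),
               "must be <= ")
})
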