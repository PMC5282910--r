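#' Aggregate replicate fits into bias / power / precision summaries
#'
#' Given the per-replicate fit results of one method in one scenario,
#' computes the Monte-Carlo performance measures: mean estimate
#' \eqn{\bar\beta}, relative bias \eqn{(\bar\beta - \beta)/\beta} (as a
#' percentage; for a protective \eqn{\beta < 0}, attenuation towards zero is
#' negative and overestimation positive), statistical power (fraction of
#' p-values below `alpha`), the empirical standard error (the SD of the
#' replicate estimates — the spread a single trial's estimate has), and the
#' Monte-Carlo standard error of the mean estimate (SD / sqrt(n_sim)).
#'
#' @param fits Data frame of fit results (rows from [estimate_itt()] etc.),
#'   all of the same method.
#' @param beta_true True log hazard ratio used to generate the data.
#' @param alpha Significance threshold for power.
#' @return One-row data frame: `method`, `n_sim`, `mean_estimate`,
#'   `rel_bias_pct`, `power`, `empirical_se`, `mc_se_of_mean`.
#' @examples
#' f <- data.frame(method = "ITT", estimate = c(-0.2, -0.4), se = 0.1,
#'                 p_value = c(0.01, 0.20), n_used = 100L)
#' summarize_fits(f, beta_true = -0.32)
#' @export
summarize_fits <- function(fits, beta_true, alpha = 0.05) {
  stop_unless(is.data.frame(fits) && nrow(fits) >= 2,
              "`fits` must be a data frame with at least two replicates")
  stop_unless(length(unique(fits$method)) == 1,
              "`fits` must contain a single method; summarise methods separately")
  stop_unless(is_scalar_num(beta_true), "`beta_true` must be a number")
  b <- fits$estimate
  m <- mean(b)
  emp_se <- stats::sd(b)
  data.frame(method = fits$method[1],
             n_sim = nrow(fits),
             mean_estimate = m,
             rel_bias_pct = 100 * (m - beta_true) / beta_true,
             power = mean(fits$p_value < alpha),
             empirical_se = emp_se,
             mc_se_of_mean = emp_se / sqrt(nrow(fits)),
             stringsAsFactors = FALSE)
}

#' Simulated statistical power at a given trial size
#'
#' Fraction of `n_rep` simulated trials of size `n_obs` whose chosen-method
#' Wald p-value falls below `alpha`. Replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param n_obs Trial size.
#' @param params A [cmrct_params()].
#' @param scenario A [cmrct_scenario()]; its `n_obs` is overridden by the
#'   `n_obs` argument.
#' @param method One of `"ITT"`, `"PP"`, `"2SPS"`, `"2SRI"`.
#' @param n_rep Number of replicate trials (>= 50 for a usable estimate).
#' @param alpha Significance threshold.
#' @param seed Master seed.
#' @return Power in \[0, 1\].
#' @export
simulated_power <- function(n_obs, params = cmrct_params(),
                            scenario = cmrct_scenario(), method = "ITT",
                            n_rep = 200, alpha = 0.05, seed = NULL) {
  stop_unless(is_scalar_num(n_rep) && n_rep >= 50, "`n_rep` must be >= 50")
  method <- match.arg(method, c("ITT", "PP", "2SPS", "2SRI"))
  scenario$n_obs <- as.integer(n_obs)
  if (is.null(seed)) seed <- if (is.null(scenario$seed)) 1L else scenario$seed
  hits <- vapply(seq_len(n_rep), function(j) {
    tr <- simulate_trial(params, scenario, seed = derive_seed(seed, "power", j))
    fit <- suppressWarnings(cmrct_analyze(tr, methods = method))
    fit$fits$p_value[1] < alpha
  }, logical(1))
  mean(hits)
}

sizing_scenario <- function(recruitment, assumed_refusal, allocation) {
  p <- unname(assumed_refusal[1]); q <- unname(assumed_refusal[2])
  if (recruitment == "without_refusal") { p <- 0; q <- 0 }
  # with-refusal sizing treats refusal as non-informative: level "zero"
  cmrct_scenario(refusal_spec(p = p, q = q, level = "zero"),
                 recruitment = recruitment, allocation = allocation, n_obs = 10L)
}

#' Simulation-based required sample size
#'
#' Finds the smallest trial size (to a granularity of `granularity`
#' individuals) whose simulated power for the chosen analysis method
#' reaches `target_power` at significance level `alpha`, for the design
#' effect `params$beta` and the given allocation ratio. Two recruitment
#' assumptions are supported: `"without_refusal"` sizes the trial as if
#' everyone offered the intervention takes it; `"with_refusal"` simulates
#' risk-independent refusal at the assumed average rates, inflating the
#' trial for the expected dilution (refusal is treated as non-informative
#' for sizing only).
#'
#' The search starts from a Schoenfeld-type analytic guess calibrated by a
#' single large pilot simulation (used only for initialisation), brackets
#' the target geometrically, bisects to the granularity using common random
#' numbers (the same seed for every candidate size, which makes the
#' estimated power monotone-stable in `n`), then confirms/adjusts the
#' candidate at the larger `n_rep_final`.
#'
#' @param params A [cmrct_params()].
#' @param recruitment `"without_refusal"` or `"with_refusal"`.
#' @param assumed_refusal Named vector `c(p = , q = )` of expected average
#'   refusal rates (used only when `recruitment = "with_refusal"`).
#' @param target_power Desired power (default 0.80).
#' @param alpha Type-I error rate (default 0.05).
#' @param allocation Allocation ratio `c(control, intervention)`.
#' @param method Analysis method driving the calculation (default ITT, the
#'   primary analysis in the trials this design emulates).
#' @param n_rep Replicates per power evaluation during the search.
#' @param n_rep_final Replicates for the confirmation at the candidate size.
#' @param granularity Step size of the returned `n`.
#' @param n_range Search bounds for `n`.
#' @param seed Master seed.
#' @return An object of class `cmrct_samplesize`: list with `n_obs`, the
#'   achieved `power` at `n_obs` (at `n_rep_final`), the settings, and a
#'   `trace` data frame of every power evaluation.
#' @examples
#' \dontrun{
#' required_sample_size(seed = 1)          # sizing without refusal
#' required_sample_size(recruitment = "with_refusal",
#'                      assumed_refusal = c(p = 0.2, q = 0), seed = 1)
#' }
#' @export
required_sample_size <- function(params = cmrct_params(),
                                 recruitment = c("without_refusal", "with_refusal"),
                                 assumed_refusal = c(p = 0, q = 0),
                                 target_power = 0.80, alpha = 0.05,
                                 allocation = c(4L, 1L), method = "ITT",
                                 n_rep = 200, n_rep_final = 1000,
                                 granularity = 50, n_range = c(100, 1e6),
                                 seed = NULL) {
  recruitment <- match.arg(recruitment)
  stop_unless(target_power > alpha && target_power < 1,
              "`target_power` must lie in (alpha, 1)")
  if (is.null(seed)) seed <- 1L
  scn <- sizing_scenario(recruitment, assumed_refusal, allocation)
  snap <- function(n) max(n_range[1], min(n_range[2], granularity * round(n / granularity)))

  trace <- list()
  eval_power <- function(n, reps, tag) {
    pw <- simulated_power(n, params, scn, method = method, n_rep = reps,
                          alpha = alpha, seed = derive_seed(seed, "size-eval"))
    trace[[length(trace) + 1]] <<- data.frame(n = n, n_rep = reps, power = pw,
                                              stage = tag)
    pw
  }

  # analytic initial guess from one large pilot trial (initialisation only)
  pilot_n <- 20000L
  scn_p <- scn; scn_p$n_obs <- pilot_n
  pilot <- simulate_trial(params, scn_p, seed = derive_seed(seed, "size-pilot"))
  pfit <- cmrct_analyze(pilot, methods = method)$fits
  b <- pfit$estimate[1]
  ev_rate <- mean(pilot$event)
  f_int <- allocation[2] / sum(allocation)
  d_needed <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power))^2 /
    (b^2 * f_int * (1 - f_int))
  n0 <- snap(d_needed / ev_rate)

  # geometric bracketing around the guess
  lo <- NA; hi <- NA
  n_cur <- n0
  pw <- eval_power(n_cur, n_rep, "bracket")
  if (pw >= target_power) {
    hi <- n_cur
    repeat {
      n_next <- snap(n_cur / 1.3)
      if (n_next >= n_cur || n_next <= n_range[1]) { lo <- n_range[1]; break }
      n_cur <- n_next
      if (eval_power(n_cur, n_rep, "bracket") < target_power) { lo <- n_cur; break }
      hi <- n_cur
    }
  } else {
    lo <- n_cur
    repeat {
      n_next <- snap(n_cur * 1.3)
      if (n_next <= n_cur) n_next <- n_cur + granularity
      if (n_next > n_range[2])
        stop("required sample size exceeds the search bound n_range[2]", call. = FALSE)
      n_cur <- n_next
      if (eval_power(n_cur, n_rep, "bracket") >= target_power) { hi <- n_cur; break }
      lo <- n_cur
    }
  }

  # bisection to granularity (common random numbers across candidates)
  while (hi - lo > granularity) {
    mid <- snap((lo + hi) / 2)
    if (mid <= lo || mid >= hi) break
    if (eval_power(mid, n_rep, "bisect") >= target_power) hi <- mid else lo <- mid
  }

  # confirmation at the candidate with the larger replicate count
  n_final <- hi
  pw_final <- eval_power(n_final, n_rep_final, "confirm")
  steps <- 0
  while (pw_final < target_power && steps < 20 && n_final + granularity <= n_range[2]) {
    n_final <- n_final + granularity
    pw_final <- eval_power(n_final, n_rep_final, "confirm")
    steps <- steps + 1
  }

  structure(list(n_obs = as.integer(n_final), power = pw_final,
                 recruitment = recruitment, assumed_refusal = assumed_refusal,
                 target_power = target_power, alpha = alpha,
                 allocation = allocation, method = method,
                 trace = do.call(rbind, trace), seed = seed),
            class = "cmrct_samplesize")
}

#' @export
print.cmrct_samplesize <- function(x, ...) {
  cat(sprintf("cmRCT required sample size (%s, method %s): n_obs = %d\n",
              x$recruitment, x$method, x$n_obs))
  cat(sprintf("  achieved power %.3f (target %.2f, alpha %.2f, allocation %d:%d",
              x$power, x$target_power, x$alpha, x$allocation[1], x$allocation[2]))
  if (x$recruitment == "with_refusal")
    cat(sprintf(", assumed refusal p = %g, q = %g",
                x$assumed_refusal[1], x$assumed_refusal[2]))
  cat(")\n")
  cat(sprintf("  search trace: %d power evaluations\n", nrow(x$trace)))
  invisible(x)
}

#' Write a sample-size report (result + search trace) as CSV
#'
#' @param x A `cmrct_samplesize`.
#' @param path File path.
#' @export
write_samplesize <- function(x, path) {
  stop_unless(inherits(x, "cmrct_samplesize"), "`x` must be a cmrct_samplesize")
  tr <- x$trace
  tr$chosen_n_obs <- x$n_obs
  tr$recruitment <- x$recruitment
  tr$method <- x$method
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
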