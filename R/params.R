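#' Generating-model parameters for a cmRCT survival simulation
#'
#' Constructs the parameter set of the data-generating model: Weibull
#' baseline hazards for the event of interest (a CVD event in the motivating
#' application) and for competing non-CVD mortality, a shared normal frailty
#' on the log-hazard scale, the intervention log hazard ratio, and the
#' administrative follow-up horizon.
#'
#' The individual hazard for the event of interest is
#' \deqn{h(t) = h_0(t)\, e^{\beta X_i + \varepsilon_i},\qquad
#'       H_0(t) = (t/\lambda_c)^{\gamma_c},}
#' and for mortality \eqn{h(t) = h_{0m}(t) e^{\varepsilon_i}} with
#' \eqn{H_{0m}(t) = (t/\lambda_m)^{\gamma_m}}. The scales \eqn{\lambda} are in
#' years. The same frailty \eqn{\varepsilon_i \sim N(0, \sigma^2)} enters both
#' hazards, inducing between-patient risk heterogeneity, correlation between
#' the two event processes, and hence informative censoring by death.
#'
#' The defaults describe a population at elevated cardiovascular risk
#' (untreated ten-year event risk averaging about 21\%) followed for three
#' years, with an intervention whose conditional log hazard ratio of -0.32
#' corresponds to an average 25\% relative reduction in ten-year risk.
#'
#' @param lambda_c Weibull scale (years) for the event of interest.
#' @param gamma_c Weibull shape for the event of interest.
#' @param lambda_m Weibull scale (years) for competing mortality.
#' @param gamma_m Weibull shape for competing mortality.
#' @param sigma Standard deviation of the shared individual frailty
#'   \eqn{\varepsilon_i} (log-hazard scale); `sigma = 0` removes all
#'   between-patient heterogeneity.
#' @param beta Conditional log hazard ratio of the intervention on the event
#'   of interest (negative = protective). The intervention has no effect on
#'   mortality.
#' @param t_max Administrative follow-up (years).
#'
#' @return An object of class `cmrct_params`: a named list of the seven
#'   parameters.
#' @examples
#' cmrct_params()
#' cmrct_params(sigma = 0)  # homogeneous cohort
#' @export
cmrct_params <- function(lambda_c = 36, gamma_c = 1.2,
                         lambda_m = 55, gamma_m = 1.2,
                         sigma = 0.7, beta = -0.32, t_max = 3) {
  stop_unless(is_scalar_num(lambda_c) && lambda_c > 0, "`lambda_c` must be a positive number")
  stop_unless(is_scalar_num(gamma_c) && gamma_c > 0, "`gamma_c` must be a positive number")
  stop_unless(is_scalar_num(lambda_m) && lambda_m > 0, "`lambda_m` must be a positive number")
  stop_unless(is_scalar_num(gamma_m) && gamma_m > 0, "`gamma_m` must be a positive number")
  stop_unless(is_scalar_num(sigma) && sigma >= 0, "`sigma` must be a non-negative number")
  stop_unless(is_scalar_num(beta), "`beta` must be a number")
  stop_unless(is_scalar_num(t_max) && t_max > 0, "`t_max` must be a positive number")
  structure(list(lambda_c = lambda_c, gamma_c = gamma_c,
                 lambda_m = lambda_m, gamma_m = gamma_m,
                 sigma = sigma, beta = beta, t_max = t_max),
            class = "cmrct_params")
}

#' @export
print.cmrct_params <- function(x, ...) {
  cat("cmRCT generating-model parameters\n")
  cat(sprintf("  event of interest : Weibull(scale = %g y, shape = %g)\n",
              x$lambda_c, x$gamma_c))
  cat(sprintf("  mortality         : Weibull(scale = %g y, shape = %g)\n",
              x$lambda_m, x$gamma_m))
  cat(sprintf("  frailty SD sigma  : %g\n", x$sigma))
  cat(sprintf("  log HR beta       : %g\n", x$beta))
  cat(sprintf("  follow-up t_max   : %g y\n", x$t_max))
  invisible(x)
}

#' Refusal structure of the intervention arm
#'
#' Describes how refusal probabilities are distributed across the cohort:
#' the average patient refusal probability `p`, the average clinician
#' refusal probability `q`, and, for each, how strongly individual refusal
#' probabilities are tied to underlying event risk.
#'
#' Individual probabilities are spread uniformly between a lower and an
#' upper limit determined by the correlation `level` (see
#' [refusal_limits()]) and assigned in order of the individual frailty:
#' with `direction = "positive"` the highest-risk individuals get the
#' highest refusal probabilities, with `"negative"` the lowest.
#'
#' @param p Average patient refusal probability, in \[0, 0.5\].
#' @param q Average clinician refusal probability, in \[0, 0.5\]. Clinician
#'   refusal defaults to being uncorrelated with risk (`q_level = "zero"`).
#' @param level,direction Correlation level (`"zero"`, `"low"`, `"medium"`,
#'   `"high"`) and direction (`"positive"`, `"negative"`) between patient
#'   refusal probability and risk.
#' @param q_level,q_direction The same, for clinician refusal.
#'
#' @return An object of class `cmrct_refusal`.
#' @examples
#' refusal_spec(p = 0.2, level = "high", direction = "positive")
#' @export
refusal_spec <- function(p = 0, q = 0,
                         level = c("zero", "low", "medium", "high"),
                         direction = c("positive", "negative"),
                         q_level = "zero",
                         q_direction = "positive") {
  level <- match.arg(level)
  direction <- match.arg(direction)
  q_level <- match.arg(q_level, c("zero", "low", "medium", "high"))
  q_direction <- match.arg(q_direction, c("positive", "negative"))
  stop_unless(is_scalar_num(p) && p >= 0 && p <= 0.5,
              "`p` must lie in [0, 0.5] so that the upper limit 2p stays below 1")
  stop_unless(is_scalar_num(q) && q >= 0 && q <= 0.5,
              "`q` must lie in [0, 0.5] so that the upper limit 2q stays below 1")
  structure(list(p = p, q = q, level = level, direction = direction,
                 q_level = q_level, q_direction = q_direction),
            class = "cmrct_refusal")
}

#' @export
print.cmrct_refusal <- function(x, ...) {
  cat(sprintf("cmRCT refusal: patient p = %g (%s, %s); clinician q = %g (%s, %s)\n",
              x$p, x$level, x$direction, x$q, x$q_level, x$q_direction))
  invisible(x)
}

#' Trial scenario: refusal, recruitment, allocation, replication
#'
#' Bundles everything that defines one simulated trial configuration:
#' the refusal structure, the recruitment assumption used to size the trial,
#' the (unequal) allocation ratio, the trial size, the number of simulation
#' replicates, and the master seed.
#'
#' @param refusal A [refusal_spec()].
#' @param recruitment `"without_refusal"` sizes the trial assuming full
#'   uptake; `"with_refusal"` inflates the sample size for the expected
#'   (risk-independent) refusal rate.
#' @param allocation Integer vector `c(control, intervention)` giving the
#'   randomisation ratio; the default 4:1 oversamples the inexpensive
#'   standard-of-care arm.
#' @param n_obs Trial size. May be `NULL`, in which case downstream code
#'   resolves it through [required_sample_size()].
#' @param n_sim Number of replicate trials for Monte-Carlo summaries.
#' @param seed Master seed for the scenario; replicate-level substreams are
#'   derived from it deterministically.
#'
#' @return An object of class `cmrct_scenario`.
#' @examples
#' cmrct_scenario(refusal_spec(p = 0.2, level = "high"), n_obs = 1000, seed = 1)
#' @export
cmrct_scenario <- function(refusal = refusal_spec(),
                           recruitment = c("without_refusal", "with_refusal"),
                           allocation = c(4L, 1L),
                           n_obs = NULL, n_sim = 1000L, seed = NULL) {
  recruitment <- match.arg(recruitment)
  stop_unless(inherits(refusal, "cmrct_refusal"), "`refusal` must be a refusal_spec()")
  stop_unless(length(allocation) == 2 && all(allocation == round(allocation)) &&
                all(allocation >= 1),
              "`allocation` must be two positive integers c(control, intervention)")
  if (!is.null(n_obs))
    stop_unless(is_scalar_num(n_obs) && n_obs >= sum(allocation),
                "`n_obs` must be at least the sum of the allocation parts")
  stop_unless(is_scalar_num(n_sim) && n_sim >= 1, "`n_sim` must be >= 1")
  structure(list(refusal = refusal, recruitment = recruitment,
                 allocation = as.integer(allocation),
                 n_obs = if (is.null(n_obs)) NULL else as.integer(n_obs),
                 n_sim = as.integer(n_sim),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cmrct_scenario")
}

#' @export
print.cmrct_scenario <- function(x, ...) {
  cat("cmRCT scenario\n")
  print(x$refusal)
  cat(sprintf("  recruitment %s; allocation %d:%d; n_obs %s; n_sim %d; seed %s\n",
              x$recruitment, x$allocation[1], x$allocation[2],
              if (is.null(x$n_obs)) "<to be sized>" else format(x$n_obs),
              x$n_sim, if (is.null(x$seed)) "<none>" else format(x$seed)))
  invisible(x)
}
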