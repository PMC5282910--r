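#' Cox proportional-hazards fit (workhorse for all four estimators)
#'
#' Thin wrapper around [survival::coxph()] with Efron tie handling that
#' validates the design (at least one event, no constant covariate) and
#' returns coefficients, standard errors and Wald p-values in a plain
#' matrix. All four analysis methods reduce to this fit with different
#' covariates.
#'
#' @param time Observed times.
#' @param event 0/1 event flags (1 = event).
#' @param covariates Numeric vector or one/two-column matrix or data frame.
#' @return Matrix with columns `coef`, `se`, `p`, one row per covariate.
#' @examples
#' set.seed(1)
#' tm <- rexp(200); gr <- rbinom(200, 1, 0.5)
#' fit_ph(tm, rep(1, 200), gr)
#' @export
fit_ph <- function(time, event, covariates) {
  x <- as.matrix(covariates)
  stop_unless(nrow(x) == length(time) && length(event) == length(time),
              "`time`, `event` and `covariates` must have matching lengths")
  if (sum(event) < 1) stop("no events: the partial likelihood is undefined", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate design: covariate(s) ", paste(which(sds == 0), collapse = ", "),
         " are constant", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  s <- summary(fit)$coefficients
  out <- cbind(coef = s[, "coef"], se = s[, "se(coef)"], p = s[, "Pr(>|z|)"])
  rownames(out) <- colnames(x)
  out
}

new_fit_result <- function(method, est, se, p, n_used) {
  data.frame(method = method, estimate = unname(est), se = unname(se),
             p_value = unname(p), n_used = as.integer(n_used),
             stringsAsFactors = FALSE)
}

#' Intention-to-treat estimator
#'
#' Cox regression of the observed outcome on randomised allocation `z`,
#' using every individual. Unbiased for the effect of *offering* the
#' intervention, but diluted towards the null as refusal grows.
#'
#' @param trial A `cmrct_trial` (or coercible data frame, see
#'   [as_cmrct_trial()]).
#' @return One-row data frame: `method`, `estimate` (log hazard ratio),
#'   `se`, `p_value`, `n_used`.
#' @export
estimate_itt <- function(trial) {
  trial <- as_cmrct_trial(trial)
  f <- fit_ph(trial$y, trial$event, cbind(z = trial$z))
  new_fit_result("ITT", f[1, 1], f[1, 2], f[1, 3], nrow(trial))
}

#' Per-protocol estimator
#'
#' Drops intervention-arm individuals who refused treatment (`z = 1`,
#' `x = 0`) and fits the Cox model on treatment received among the rest.
#' Unbiased only when refusal is unrelated to risk; risk-related refusal
#' selectively removes high- or low-risk patients from the intervention arm
#' and biases the estimate accordingly.
#'
#' @inheritParams estimate_itt
#' @return One-row fit-result data frame; `n_used` counts the rows kept.
#' @export
estimate_pp <- function(trial) {
  trial <- as_cmrct_trial(trial)
  keep <- !(trial$z == 1 & trial$x == 0)
  d <- trial[keep, ]
  if (!any(d$x == 1))
    stop("degenerate design: no intervention-arm individuals left after the per-protocol exclusion",
         call. = FALSE)
  f <- fit_ph(d$y, d$event, cbind(x = d$x))
  new_fit_result("PP", f[1, 1], f[1, 2], f[1, 3], nrow(d))
}

#' First stage of the instrumental-variable estimators
#'
#' Computes \eqn{\hat X = E(X \mid Z)} and the residual \eqn{R = X - \hat X}.
#' With a binary instrument the first-stage model is saturated, so the
#' fitted values are simply the arm-wise means of treatment received (and
#' linear or logistic first stages coincide). Residuals sum to zero within
#' each arm by construction.
#'
#' @param z 0/1 allocation vector (both arms must be present).
#' @param x 0/1 treatment-received vector.
#' @return List with `fitted`, `residuals`, and `uptake` (the
#'   intervention-arm mean of `x`, i.e. the first-stage strength of the
#'   instrument).
#' @examples
#' first_stage(c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 0))
#' @export
first_stage <- function(z, x) {
  stop_unless(length(z) == length(x), "`z` and `x` must have equal length")
  stop_unless(any(z == 0) && any(z == 1), "both arms must be present for the first stage")
  m0 <- mean(x[z == 0])
  m1 <- mean(x[z == 1])
  fitted <- ifelse(z == 1, m1, m0)
  list(fitted = fitted, residuals = x - fitted, uptake = m1)
}

#' Two-stage predictor substitution (2SPS) estimator
#'
#' Replaces treatment received by its first-stage prediction
#' \eqn{\hat X = E(X|Z)} in the Cox model. Because \eqn{\hat X} is just a
#' rescaling of `z` (control-arm uptake is zero by design), the 2SPS
#' coefficient equals the ITT coefficient divided by the intervention-arm
#' uptake rate and shares its p-value exactly.
#'
#' @inheritParams estimate_itt
#' @return One-row fit-result data frame.
#' @export
estimate_2sps <- function(trial) {
  trial <- as_cmrct_trial(trial)
  fs <- first_stage(trial$z, trial$x)
  if (stats::sd(fs$fitted) == 0)
    stop("weak instrument: first-stage fitted values are constant (zero uptake)",
         call. = FALSE)
  f <- fit_ph(trial$y, trial$event, cbind(xhat = fs$fitted))
  new_fit_result("2SPS", f[1, 1], f[1, 2], f[1, 3], nrow(trial))
}

#' Two-stage residual inclusion (2SRI) estimator
#'
#' Fits the Cox model on treatment received `x` together with the
#' first-stage residual \eqn{R = X - E(X|Z)}; the coefficient of `x` is the
#' instrumental-variable effect estimate. The residual term absorbs the
#' confounded part of treatment received. Under perfect compliance the
#' residual is identically zero; it is then dropped (with a warning) and
#' the fit reduces to the allocation-only model, so the estimator remains
#' defined across a whole scenario grid.
#'
#' @inheritParams estimate_itt
#' @return One-row fit-result data frame.
#' @export
estimate_2sri <- function(trial) {
  trial <- as_cmrct_trial(trial)
  fs <- first_stage(trial$z, trial$x)
  if (stats::sd(fs$residuals) == 0) {
    warning("first-stage residuals are constant (perfect compliance); ",
            "dropping the residual term", call. = FALSE)
    f <- fit_ph(trial$y, trial$event, cbind(x = trial$x))
    return(new_fit_result("2SRI", f[1, 1], f[1, 2], f[1, 3], nrow(trial)))
  }
  f <- fit_ph(trial$y, trial$event, cbind(x = trial$x, r = fs$residuals))
  new_fit_result("2SRI", f["x", 1], f["x", 2], f["x", 3], nrow(trial))
}

#' Analyse one trial by the four cmRCT methods
#'
#' The central fitting function of the package: applies intention-to-treat,
#' per-protocol and the two instrumental-variable estimators (2SPS, 2SRI)
#' to one censored-survival trial and returns a classed fit object with
#' `print`, `summary`, `coef` and `confint` methods. All four are Cox
#' proportional-hazards fits differing only in covariate construction and
#' row inclusion.
#'
#' @param trial A `cmrct_trial`, or any data frame [as_cmrct_trial()]
#'   accepts (columns `y`/`time`, `event` or `c`, `z`, `x`).
#' @param methods Subset of `c("ITT", "PP", "2SPS", "2SRI")`.
#' @return An object of class `cmrct_fit`: a list with `fits` (one row per
#'   method: `method`, `estimate`, `se`, `p_value`, `n_used`), `uptake`
#'   (intervention-arm uptake rate), `n`, and the call.
#' @examples
#' tr <- simulate_trial(cmrct_params(),
#'                      cmrct_scenario(refusal_spec(p = 0.2), n_obs = 2000),
#'                      seed = 7)
#' fit <- cmrct_analyze(tr)
#' fit
#' coef(fit)
#' @export
cmrct_analyze <- function(trial, methods = c("ITT", "PP", "2SPS", "2SRI")) {
  trial <- as_cmrct_trial(trial)
  methods <- match.arg(methods, several.ok = TRUE)
  fns <- list(ITT = estimate_itt, PP = estimate_pp,
              `2SPS` = estimate_2sps, `2SRI` = estimate_2sri)
  fits <- do.call(rbind, lapply(methods, function(m) fns[[m]](trial)))
  uptake <- if (any(trial$z == 1)) mean(trial$x[trial$z == 1]) else NA_real_
  structure(list(fits = fits, uptake = uptake, n = nrow(trial),
                 call = match.call()),
            class = "cmrct_fit")
}

#' @export
print.cmrct_fit <- function(x, digits = 4, ...) {
  cat(sprintf("cmRCT analysis of one trial (n = %d, intervention-arm uptake = %s)\n",
              x$n, formatC(x$uptake, digits = 3, format = "f")))
  df <- x$fits
  df$estimate <- round(df$estimate, digits)
  df$se <- round(df$se, digits)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cmrct_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- object$fits
  s$hr <- exp(s$estimate)
  s$hr_lower <- exp(s$estimate - z * s$se)
  s$hr_upper <- exp(s$estimate + z * s$se)
  structure(list(table = s, uptake = object$uptake, n = object$n,
                 conf_level = conf_level),
            class = "summary.cmrct_fit")
}

#' @export
print.summary.cmrct_fit <- function(x, ...) {
  cat(sprintf("cmRCT analysis (n = %d, uptake = %.3f); hazard ratios with %g%% CI\n",
              x$n, x$uptake, 100 * x$conf_level))
  df <- x$table
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cmrct_fit <- function(object, ...) {
  stats::setNames(object$fits$estimate, object$fits$method)
}

#' @export
confint.cmrct_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  f <- object$fits
  ci <- cbind(f$estimate - z * f$se, f$estimate + z * f$se)
  dimnames(ci) <- list(f$method,
                       sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.cmrct_fit <- function(x, true_beta = NULL, ...) {
  f <- x$fits
  ci <- confint.cmrct_fit(x)
  k <- nrow(f)
  graphics::plot(f$estimate, seq_len(k), xlim = range(ci, 0, true_beta),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "log hazard ratio", ylab = "",
                 pch = 19, panel.first = graphics::abline(v = 0, col = "grey"), ...)
  graphics::axis(2, at = seq_len(k), labels = f$method, las = 1)
  graphics::segments(ci[, 1], seq_len(k), ci[, 2], seq_len(k))
  if (!is.null(true_beta)) graphics::abline(v = true_beta, lty = 2)
  invisible(x)
}
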