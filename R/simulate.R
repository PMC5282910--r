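#' Exact unequal randomisation
#'
#' Allocates exactly `round(n * i/(c + i))` individuals to the intervention
#' for a `c:i` allocation ratio (20 of 100 at the default 4:1), positioned
#' by a uniformly random permutation. Exact allocation removes the binomial
#' noise in arm sizes that simple coin-flip randomisation would add.
#'
#' @param n Cohort size; must be at least `sum(allocation)`.
#' @param allocation Integer vector `c(control, intervention)`.
#' @param seed Optional seed.
#' @return Integer 0/1 vector of length `n` (1 = intervention).
#' @examples
#' table(randomize_allocation(100, seed = 1))
#' @export
randomize_allocation <- function(n, allocation = c(4L, 1L), seed = NULL) {
  stop_unless(is_scalar_num(n) && n == round(n) && n >= sum(allocation),
              "`n` must be an integer of at least sum(allocation)")
  stop_unless(length(allocation) == 2 && all(allocation >= 1),
              "`allocation` must be c(control, intervention), both >= 1")
  n_int <- round(n * allocation[2] / sum(allocation))
  z <- integer(n)
  z[with_seed(seed, sample.int(n, n_int))] <- 1L
  z
}

#' Simulate one trial within a cohort
#'
#' Runs the full generating procedure for a single trial: draw frailties;
#' assign patient and clinician refusal probabilities ordered by frailty;
#' randomise on the allocation ratio; realise treatment received;
#' draw latent event and mortality times from the frailty-adjusted Weibull
#' hazards; apply administrative censoring at `t_max` and censoring by
#' death. Mortality before the event of interest censors it
#' (informatively, through the shared frailty).
#'
#' @param params A [cmrct_params()].
#' @param scenario A [cmrct_scenario()] with `n_obs` set.
#' @param seed Optional seed (defaults to `scenario$seed`).
#' @param keep_latent Keep the latent columns `epsilon`, `t_c`, `t_m`,
#'   `p_i`, `q_i` for diagnostics? Off by default to keep memory small.
#' @return A `cmrct_trial` data frame with columns `id`, `y` (observed time
#'   in years, `min(t_c, t_m, t_max)`), `c` (censoring indicator, 1 =
#'   censored), `event` (`1 - c`, the conventional event flag), `z`
#'   (allocation) and `x` (treatment received).
#' @examples
#' tr <- simulate_trial(cmrct_params(),
#'                      cmrct_scenario(refusal_spec(p = 0.2), n_obs = 500),
#'                      seed = 1)
#' head(tr)
#' @export
simulate_trial <- function(params = cmrct_params(), scenario = cmrct_scenario(),
                           seed = NULL, keep_latent = FALSE) {
  stop_unless(inherits(params, "cmrct_params"), "`params` must be a cmrct_params()")
  stop_unless(inherits(scenario, "cmrct_scenario"), "`scenario` must be a cmrct_scenario()")
  stop_unless(!is.null(scenario$n_obs), "`scenario$n_obs` must be set (see required_sample_size())")
  if (is.null(seed)) seed <- scenario$seed
  n <- scenario$n_obs
  rf <- scenario$refusal
  with_seed(seed, {
    eps <- stats::rnorm(n, 0, params$sigma)
    p_i <- assign_refusal_probs(eps, rf$p, rf$level, rf$direction)
    q_i <- assign_refusal_probs(eps, rf$q, rf$q_level, rf$q_direction)
    z <- randomize_allocation(n, scenario$allocation)
    x <- realize_uptake(z, p_i, q_i)
    t_c <- sample_event_time(n, params$lambda_c, params$gamma_c,
                             eta = params$beta * x + eps)
    t_m <- sample_event_time(n, params$lambda_m, params$gamma_m, eta = eps)
    y <- pmin(t_c, t_m, params$t_max)
    cens <- as.integer(t_c >= pmin(t_m, params$t_max))
    out <- data.frame(id = seq_len(n), y = y, c = cens, event = 1L - cens,
                      z = z, x = x)
    if (keep_latent) {
      out$epsilon <- eps; out$t_c <- t_c; out$t_m <- t_m
      out$p_i <- p_i; out$q_i <- q_i
    }
    structure(out, class = c("cmrct_trial", "data.frame"),
              params = params, scenario = scenario)
  })
}

#' Coerce a generic censored-survival table to a trial object
#'
#' Accepts any data frame carrying an observed time, an event or censoring
#' flag, a randomised allocation and a treatment-received indicator, so the
#' estimators can be applied to real trial data as well as simulated ones.
#' Either `event` (1 = event) or `c` (1 = censored) may be supplied; the
#' other is filled in.
#'
#' @param x A data frame with columns `y` (or `time`), `z`, `x`, and one of
#'   `event` / `c`.
#' @return A `cmrct_trial` data frame.
#' @examples
#' as_cmrct_trial(data.frame(time = c(1, 2, 3), event = c(1, 0, 1),
#'                           z = c(0, 1, 1), x = c(0, 1, 0)))
#' @export
as_cmrct_trial <- function(x) {
  if (inherits(x, "cmrct_trial")) return(x)
  stop_unless(is.data.frame(x), "`x` must be a data frame")
  nm <- names(x)
  if (!"y" %in% nm && "time" %in% nm) x$y <- x$time
  stop_unless(all(c("y", "z", "x") %in% names(x)),
              "need columns `y` (or `time`), `z`, `x`")
  if (!"event" %in% nm && "c" %in% nm) x$event <- 1L - x$c
  stop_unless("event" %in% names(x), "need an `event` (1 = event) or `c` (1 = censored) column")
  if (!"c" %in% names(x)) x$c <- 1L - x$event
  if (!"id" %in% names(x)) x$id <- seq_len(nrow(x))
  stop_unless(all(x$y > 0), "observed times must be positive")
  stop_unless(all(x$z %in% c(0, 1)) && all(x$x %in% c(0, 1)), "`z` and `x` must be 0/1")
  stop_unless(all(x$event %in% c(0, 1)), "`event` must be 0/1")
  stop_unless(all(x$x <= x$z), "treatment received without allocation: `x` must be <= `z`")
  structure(as.data.frame(x), class = c("cmrct_trial", "data.frame"))
}

#' Write / read a simulated trial as CSV
#'
#' The CSV carries both the censoring indicator `c` (1 = censored) and the
#' conventional event flag `event` (1 = event) to avoid sign errors
#' downstream, plus any retained latent columns.
#'
#' @param trial A `cmrct_trial`.
#' @param path File path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   `cmrct_trial`.
#' @export
write_trial <- function(trial, path) {
  stop_unless(inherits(trial, "cmrct_trial"), "`trial` must be a cmrct_trial")
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  as_cmrct_trial(utils::read.csv(path))
}

#' @export
print.cmrct_trial <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("cmRCT trial: %d individuals, %d intervention-arm (%d took treatment), %d events\n",
              n, sum(x$z), sum(x$x), sum(x$event)))
  NextMethod()
}
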