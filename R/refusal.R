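#' Lower and upper limits of the refusal-probability spread
#'
#' For an average refusal probability `p`, the four correlation levels put
#' individual refusal probabilities uniformly between
#' `(p, p)`, `(2p/3, 4p/3)`, `(p/3, 5p/3)` and `(0, 2p)` for
#' zero/low/medium/high. The midpoint is always `p`, so the cohort mean is
#' preserved while the spread — and hence the strength of the association
#' with risk once the grid is ordered by frailty — widens.
#'
#' @param p Average refusal probability, in \[0, 0.5\].
#' @param level `"zero"`, `"low"`, `"medium"` or `"high"`.
#' @return Named numeric vector `c(LL, UL)`.
#' @examples
#' refusal_limits(0.3, "high")  # c(0, 0.6)
#' @export
refusal_limits <- function(p, level = c("zero", "low", "medium", "high")) {
  level <- match.arg(level)
  stop_unless(is_scalar_num(p) && p >= 0 && p <= 0.5,
              "`p` must lie in [0, 0.5]; larger means would push the upper limit past 1")
  lim <- switch(level,
                zero   = c(p, p),
                low    = c(2 * p / 3, 4 * p / 3),
                medium = c(p / 3, 5 * p / 3),
                high   = c(0, 2 * p))
  names(lim) <- c("LL", "UL")
  lim
}

#' Assign risk-ordered refusal probabilities
#'
#' Gives each individual a refusal probability on an equally spaced grid
#' between the limits for (`p`, `level`), assigned in order of the
#' individual frailty: with `direction = "positive"` the highest-frailty
#' (highest-risk) individual receives the highest probability, with
#' `"negative"` the lowest. The assignment is deterministic given the
#' frailties, the grid mean equals `p` exactly, and the rank correlation
#' between frailty and probability is +1 or -1 (0 at `level = "zero"`,
#' where the grid is flat). Ties in the frailties (measure-zero for
#' continuous draws) are broken by original index.
#'
#' @param epsilon Individual frailties.
#' @param p Average refusal probability.
#' @param level,direction Correlation level and direction (see
#'   [refusal_spec()]).
#' @return Numeric vector of refusal probabilities aligned with `epsilon`.
#' @examples
#' assign_refusal_probs(c(-1, 0, 2), p = 0.3, level = "high")  # 0, 0.3, 0.6
#' @export
assign_refusal_probs <- function(epsilon, p,
                                 level = c("zero", "low", "medium", "high"),
                                 direction = c("positive", "negative")) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  n <- length(epsilon)
  stop_unless(n >= 1 && all(is.finite(epsilon)), "`epsilon` must be finite and non-empty")
  lim <- refusal_limits(p, level)
  if (n == 1L) return(unname(p))
  grid <- seq(lim[["LL"]], lim[["UL"]], length.out = n)
  if (direction == "negative") grid <- rev(grid)
  out <- numeric(n)
  out[order(epsilon)] <- grid  # order() breaks ties by original index
  out
}

#' Realise treatment received from allocation and refusal
#'
#' Treatment actually received is
#' \eqn{X_i = \min\{\mathrm{Bern}(1-p_i), \mathrm{Bern}(1-q_i)\}} for
#' intervention-arm individuals — the patient and the clinician refuse
#' independently — and \eqn{X_i = 0} for everyone allocated to standard of
#' care, where refusal cannot be exercised.
#'
#' @param z 0/1 allocation vector.
#' @param p_i Patient refusal probabilities (same length as `z`).
#' @param q_i Clinician refusal probabilities (same length as `z`).
#' @param seed Optional seed.
#' @return Integer 0/1 vector of treatment received; `X <= Z` everywhere.
#' @examples
#' realize_uptake(c(0, 1, 1), p_i = rep(0, 3), q_i = rep(0, 3))
#' @export
realize_uptake <- function(z, p_i, q_i = rep(0, length(z)), seed = NULL) {
  n <- length(z)
  stop_unless(length(p_i) == n && length(q_i) == n,
              "`z`, `p_i` and `q_i` must have equal length")
  stop_unless(all(z %in% c(0, 1)), "`z` must be 0/1")
  stop_unless(all(p_i >= 0 & p_i <= 1) && all(q_i >= 0 & q_i <= 1),
              "refusal probabilities must lie in [0, 1]")
  with_seed(seed, {
    accept_p <- stats::runif(n) >= p_i
    accept_q <- stats::runif(n) >= q_i
    as.integer(z == 1 & accept_p & accept_q)
  })
}
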