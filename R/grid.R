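#' Run one scenario: replicate trials, all methods, aggregated summaries
#'
#' Simulates `scenario$n_sim` replicate trials and analyses *the same*
#' simulated dataset with every requested method, so method comparisons
#' within a scenario are paired. Replicate seeds are derived from the
#' scenario seed; a different scenario seed gives an independent set of
#' datasets.
#'
#' @param params A [cmrct_params()].
#' @param scenario A [cmrct_scenario()] with `n_obs` and `seed` set.
#' @param methods Methods to run (default all four).
#' @param keep_fits Return the per-replicate estimates table as well?
#' @return An object of class `cmrct_scenario_result`: list with `summary`
#'   (one row per method, see [summarize_fits()]), `fits` (per-replicate
#'   estimates, if kept), `failures` (count of replicates where a method's
#'   fit signalled an error; failed fits are counted, never silently
#'   dropped), and the scenario.
#' @examples
#' scn <- cmrct_scenario(refusal_spec(p = 0.2, level = "high"),
#'                       n_obs = 1500, n_sim = 20, seed = 3)
#' run_scenario(cmrct_params(), scn)$summary
#' @export
run_scenario <- function(params = cmrct_params(), scenario,
                         methods = c("ITT", "PP", "2SPS", "2SRI"),
                         keep_fits = TRUE) {
  stop_unless(inherits(scenario, "cmrct_scenario"), "`scenario` must be a cmrct_scenario()")
  stop_unless(!is.null(scenario$n_obs), "`scenario$n_obs` must be resolved before running")
  seed <- if (is.null(scenario$seed)) 1L else scenario$seed
  methods <- match.arg(methods, several.ok = TRUE)
  fns <- list(ITT = estimate_itt, PP = estimate_pp,
              `2SPS` = estimate_2sps, `2SRI` = estimate_2sri)
  failures <- stats::setNames(integer(length(methods)), methods)
  rows <- vector("list", scenario$n_sim)
  for (j in seq_len(scenario$n_sim)) {
    tr <- simulate_trial(params, scenario, seed = derive_seed(seed, "rep", j))
    fit_j <- lapply(methods, function(m) {
      res <- tryCatch(suppressWarnings(fns[[m]](tr)), error = function(e) NULL)
      if (is.null(res)) failures[m] <<- failures[m] + 1L
      res
    })
    fit_j <- do.call(rbind, fit_j)
    if (!is.null(fit_j)) fit_j$replicate <- j
    rows[[j]] <- fit_j
  }
  fits <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(methods, function(m) {
    fm <- fits[fits$method == m, , drop = FALSE]
    if (nrow(fm) < 2) return(NULL)
    s <- summarize_fits(fm, beta_true = params$beta)
    s$n_failed <- failures[[m]]
    s
  }))
  structure(list(summary = summary,
                 fits = if (keep_fits) fits else NULL,
                 failures = failures, scenario = scenario, params = params),
            class = "cmrct_scenario_result")
}

#' @export
print.cmrct_scenario_result <- function(x, ...) {
  rf <- x$scenario$refusal
  cat(sprintf("cmRCT scenario result: p = %g (%s, %s), q = %g, %s, n_obs = %d, n_sim = %d\n",
              rf$p, rf$level, rf$direction, rf$q, x$scenario$recruitment,
              x$scenario$n_obs, x$scenario$n_sim))
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  if (any(x$failures > 0))
    cat("failed fits:", paste(names(x$failures), x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Configuration for a scenario grid
#'
#' Describes a full factorial grid of refusal scenarios: refusal means,
#' correlation levels and directions, and recruitment methods. Trial sizes
#' are resolved once per distinct (recruitment, p, q) combination through
#' [required_sample_size()] unless `n_obs` is supplied.
#'
#' @param p,q Vectors of average patient / clinician refusal probabilities.
#' @param levels Correlation levels to cross.
#' @param directions Correlation directions to cross.
#' @param recruitments Recruitment methods to cross.
#' @param n_sim Replicates per cell.
#' @param seed Master seed (required: every cell derives its own stream).
#' @param params A [cmrct_params()].
#' @param n_obs Optional fixed trial size (skips the sizing step).
#' @param methods Methods to run per cell.
#' @param sizing_args Extra arguments passed to [required_sample_size()]
#'   (e.g. `n_rep`, `n_rep_final`, `granularity`).
#' @return An object of class `cmrct_grid_config`.
#' @examples
#' grid_config(p = 0.2, levels = "high", n_sim = 10, seed = 1, n_obs = 1000)
#' @export
grid_config <- function(p = c(0.1, 0.2, 0.3), q = 0,
                        levels = c("zero", "low", "medium", "high"),
                        directions = c("positive", "negative"),
                        recruitments = c("without_refusal", "with_refusal"),
                        n_sim = 1000, seed, params = cmrct_params(),
                        n_obs = NULL, methods = c("ITT", "PP", "2SPS", "2SRI"),
                        sizing_args = list()) {
  stop_unless(!missing(seed) && is_scalar_num(seed),
              "`seed` is required for a reproducible grid")
  levels <- match.arg(levels, several.ok = TRUE)
  directions <- match.arg(directions, several.ok = TRUE)
  recruitments <- match.arg(recruitments, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- expand.grid(p = p, q = q, level = levels, direction = directions,
                       recruitment = recruitments,
                       stringsAsFactors = FALSE)
  # a flat grid has no correlation direction to vary
  cells <- unique(within(cells, direction[level == "zero"] <- directions[1]))
  structure(list(cells = cells, n_sim = as.integer(n_sim),
                 seed = as.integer(seed), params = params,
                 n_obs = n_obs, methods = methods, sizing_args = sizing_args),
            class = "cmrct_grid_config")
}

cell_key <- function(cell)
  sprintf("p%g_q%g_%s_%s_%s", cell$p, cell$q, cell$level, cell$direction,
          cell$recruitment)

#' Run a scenario grid
#'
#' Executes every cell of a [grid_config()] and returns (and optionally
#' writes) a long-format results table, one row per cell and method. When
#' `out` points to an existing results CSV, cells already present there are
#' skipped and the new rows appended, so interrupted grids can be resumed.
#' Per-cell progress, resolved trial sizes and failed-fit counts go to
#' `log_file` (one line per cell) so degenerate fits cannot pass silently.
#'
#' @param config A [grid_config()].
#' @param out Optional path of the results CSV.
#' @param log_file Optional path of a line-per-cell progress log (default:
#'   messages).
#' @return Data frame keyed by `p`, `q`, `level`, `direction`,
#'   `recruitment`, `method` with the [summarize_fits()] columns, `n_obs`
#'   and `cell_seed`.
#' @examples
#' cfg <- grid_config(p = 0.2, levels = c("zero", "high"),
#'                    directions = "positive", recruitments = "without_refusal",
#'                    n_sim = 10, seed = 1, n_obs = 800)
#' run_grid(cfg)
#' @export
run_grid <- function(config, out = NULL, log_file = NULL) {
  stop_unless(inherits(config, "cmrct_grid_config"), "`config` must be a grid_config()")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    if (is.null(log_file)) message(line) else cat(line, "\n", file = log_file,
                                                  append = TRUE, sep = "")
  }
  prev <- NULL
  if (!is.null(out) && file.exists(out)) {
    prev <- utils::read.csv(out, stringsAsFactors = FALSE)
    logf("resuming: %d rows already in %s", nrow(prev), out)
  }
  done_keys <- if (is.null(prev)) character(0) else
    unique(cell_key(prev[c("p", "q", "level", "direction", "recruitment")]))

  size_cache <- new.env(parent = emptyenv())
  resolve_n <- function(cell) {
    if (!is.null(config$n_obs)) return(as.integer(config$n_obs))
    key <- sprintf("%s_p%g_q%g", cell$recruitment, cell$p, cell$q)
    if (is.null(size_cache[[key]])) {
      args <- c(list(params = config$params, recruitment = cell$recruitment,
                     assumed_refusal = c(p = cell$p, q = cell$q),
                     seed = derive_seed(config$seed, "sizing", key)),
                config$sizing_args)
      size_cache[[key]] <- do.call(required_sample_size, args)$n_obs
      logf("sized %s -> n_obs = %d", key, size_cache[[key]])
    }
    size_cache[[key]]
  }

  rows <- list()
  for (i in seq_len(nrow(config$cells))) {
    cell <- config$cells[i, ]
    key <- cell_key(cell)
    if (key %in% done_keys) { logf("skip %s (already in output)", key); next }
    n_obs <- resolve_n(cell)
    cell_seed <- derive_seed(config$seed, "cell", key)
    scn <- cmrct_scenario(refusal_spec(p = cell$p, q = cell$q,
                                       level = cell$level,
                                       direction = cell$direction),
                          recruitment = cell$recruitment,
                          n_obs = n_obs, n_sim = config$n_sim,
                          seed = cell_seed)
    res <- run_scenario(config$params, scn, methods = config$methods,
                        keep_fits = FALSE)
    s <- res$summary
    row <- cbind(cell[rep(1, nrow(s)), , drop = FALSE], s,
                 n_obs = n_obs, cell_seed = cell_seed, row.names = NULL)
    rows[[key]] <- row
    logf("cell %s: n_obs = %d, seed = %d, failed fits = %d",
         key, n_obs, cell_seed, sum(res$failures))
  }
  new <- do.call(rbind, rows)
  result <- rbind(prev, new)
  rownames(result) <- NULL
  if (!is.null(out) && !is.null(new))
    utils::write.csv(result, out, row.names = FALSE)
  result
}
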