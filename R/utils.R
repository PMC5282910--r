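# internal helpers: argument checks and seed discipline

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Derive a reproducible child seed
#'
#' Deterministically mixes a master seed with one or more integer or
#' character keys (a replicate index, a scenario label, ...) into a new seed
#' in \[1, 2^31 - 2\]. Used so that every replicate and every grid cell gets
#' its own reproducible random stream from a single master seed.
#'
#' @param seed Master seed (integer).
#' @param ... Integer or character keys identifying the substream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "scenario", 7)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; 48271 * m < 2^53 so the
  a <- 48271       # Lehmer step below is exact in double precision
  s <- as.numeric(seed) %% m
  for (key in list(...)) {
    ks <- if (is.character(key)) {
      cp <- utf8ToInt(paste(key, collapse = "\r"))
      sum(cp * (seq_along(cp) %% 97 + 1)) %% m
    } else as.numeric(key) %% m
    s <- (s * a + ks + 1) %% m
  }
  s <- (s * a + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
# A NULL seed leaves the session stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
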