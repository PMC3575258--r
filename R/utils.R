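# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards, so that seeded generators are
#' reproducible without clobbering the caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a classed condition so callers can test error classes
stop_hdemg <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "hdemg_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_hdemg("invalid_argument", sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

# sub-seed derivation: distinct, deterministic, < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009) %% 2147483587)
}
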