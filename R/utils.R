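# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without clobbering the caller's
# stream. All exported generators funnel their `seed` argument through here.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_invalid <- function(...) {
  stop(simpleError(paste0(...)))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invalid(msg)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), .Machine$double.eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
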