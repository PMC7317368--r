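# Internal helpers shared across modules.

# Signal a classed validation error so callers can distinguish failure modes
# (e.g. monotonicity vs. span violations) without string matching.
rv_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rvdeform_error"), call = call))
}

rv_assert <- function(cond, class, msg) {
  if (!isTRUE(cond)) rv_error(class, msg, call = sys.call(-1))
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs the global stream.
with_rng_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
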