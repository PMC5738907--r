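# Internal helpers shared across modules.

# Deterministic child seed for a pipeline stage. One master seed is supplied
# by the caller; stages draw from fixed offsets so that adding a stage never
# perturbs the streams of existing ones. Kept strictly below 2^31 - 1.
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) + 1013 * as.double(offset)) %% 2147483646) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_proportion <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || !hi_ok) {
    stop(sprintf("`%s` must be a proportion in [0,%s]", name, if (allow_one) "1" else "1)"),
         call. = FALSE)
  }
  invisible(as.double(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
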