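# internal helpers

# Evaluate expr with R's RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("`%s` must be a single value in [0, 1], got %s", name,
               paste(format(x), collapse = ","))
  x
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_param("`%s` must be a positive number", name)
  x
}

# full-precision numeric formatting for lossless text round trips
fmt_num <- function(x) sprintf("%.17g", x)
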