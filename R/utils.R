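# internal helpers shared across modules

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically split a master seed into `n` child seeds (one RNG stream
# per nucleus) so each nucleus is independently reproducible.
split_seed <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_local_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

ball_volume <- function(radius) 4 / 3 * pi * radius^3
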