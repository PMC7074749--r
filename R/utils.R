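# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seeds derived from a master seed by fixed offsets,
# kept inside 32-bit integer range.
seed_offset <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * k) %% .Machine$integer.max)
}

# population standard deviation (divisor n, not n-1)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NaN)
  sqrt(sum((x - mean(x))^2) / n)
}
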