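# Internal helpers: classed error conditions, local RNG scope, sub-seed
# derivation.

abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "phonrsa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("ConfigError", sprintf("'%s' must be a finite number", name))
  x
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. All stochastic operations in the package require an explicit
# seed so that every analysis is reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("SeedError", "an integer 'seed' is required for reproducibility")
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named pipeline stage. A polynomial string
# hash keeps stages independent: inserting a stage never perturbs the
# stream any other stage sees. Result is in [0, 2^31 - 2].
sub_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# Closed-interval index of time points (ms) falling inside a window.
window_index <- function(time, window, what = "window") {
  if (length(window) != 2L || !is.numeric(window) || window[1] > window[2])
    abort("WindowError", sprintf("invalid %s: need c(lo, hi) with lo <= hi", what))
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  if (!length(idx))
    abort("WindowError",
          sprintf("%s [%g, %g] ms contains no samples", what, window[1], window[2]))
  idx
}
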