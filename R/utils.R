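# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb the
# global stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministically combine a top-level seed with stream indices (well,
# electrode, phase, ...) into a sub-seed below 2^31.  Plain multiplicative
# hashing; streams with distinct indices get distinct, reproducible seeds.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483629L)
  for (i in idx) {
    h <- (h * 48271 + as.double(i) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

stop_config <- function(...) {
  stop(structure(
    class = c("hmnr_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_schema <- function(...) {
  stop(structure(
    class = c("hmnr_schema_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_config(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_config(name, " must be >= ", lower)
  if (x > upper)
    stop_config(name, " must be <= ", upper)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
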