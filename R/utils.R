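# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish metadata/data/IO/config
# failures programmatically.
dwisr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("dwisr_", class, "_error"),
                                     "dwisr_error", "error", "condition")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded internals never perturb the user's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    dwisr_stop(sprintf("`%s` must be a single finite number", name), "config")
  if (positive && x <= 0)
    dwisr_stop(sprintf("`%s` must be positive", name), "config")
  invisible(x)
}
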