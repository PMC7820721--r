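# Internal helpers: seeded RNG scoping and child-seed derivation.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# All generator functions route their randomness through this so identical
# seeds give byte-identical output regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic child seed from a parent seed and a stage index; stays below
# 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + k * 1299721) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number")
  invisible(x)
}
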