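#' @keywords internal
"_PACKAGE"

# Round half away from zero. This is the single rounding rule used when
# exporting real-valued intensities to 8-bit images; R's round() rounds
# half to even, which is not what image software does.
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All fixture generators funnel
# through this so they are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ..., class = "aminoblot_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "aminoblot_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
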