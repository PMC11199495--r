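# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations never perturb the global random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# Percent formatted comparisons occur all over; keep rounding explicit.
round2 <- function(x) round(x, 2)
round1 <- function(x) round(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
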