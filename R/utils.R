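# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so simulation helpers do not
#' perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seed from (seed, index, stream tag), kept < 2^31.
# Plain integer mixing; streams for the same animal are decoupled so that
# trace and event generation can be called independently yet consistently.
mix_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) %% 2147483647)
  s <- (s * 48271 + as.double(index) * 16807 + as.double(stream) * 69621) %%
    2147483629
  as.integer(s + 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

# sample standard deviation that returns 0 (not NA) for n = 1
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
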