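# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. A NULL seed leaves the stream alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap an angle to (-pi, pi].
.wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

# Unwrap a phase sequence: add the multiple of 2*pi to each element that
# brings it closest to its predecessor.
.unwrap <- function(phase) {
  if (length(phase) < 2L) return(phase)
  out <- phase
  for (i in 2:length(out)) {
    out[i] <- out[i] + 2 * pi * round((out[i - 1] - out[i]) / (2 * pi))
  }
  out
}

# Linear interpolation with endpoint hold, tolerant of a length-1 table.
.interp_hold <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, rule = 2)$y
}
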