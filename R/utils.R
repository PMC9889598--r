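# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` runs the code as-is.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stage label; stays < 2^31.
childSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)))
  invisible(x)
}

# Cumulative trapezoidal integral of y over x (same length as x, starts 0).
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
}

# Linear interpolation with constant extrapolation at the ends.
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}
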