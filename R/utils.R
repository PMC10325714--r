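#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif pt qt pf sd var setNames
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators are pure given their seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 1))
}

assert_same_dim <- function(a, b, what = "image and mask") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: %s must have identical dims", what), call. = FALSE)
  invisible(TRUE)
}

# Centred moving average; window shrinks symmetrically near the ends so the
# first/last values are never extrapolated. `window` must be odd.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

# Arc length of a polyline given step along the axis and the transverse
# coordinate at each step.
polyline_length <- function(axis_pos, transverse) {
  if (length(axis_pos) < 2L) return(0)
  sum(sqrt(diff(axis_pos)^2 + diff(transverse)^2))
}
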