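#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.05 -> 0.1 and
#' -0.05 -> -0.1), the convention used when reporting detection metrics to
#' one decimal. Base `round()` rounds ties to even, which would report
#' e.g. 87.45 as 87.4.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Centered rolling mean with edges truncated to the available samples.
# Window w is in samples; for even w the window extends one sample further
# to the left. Implemented with cumulative sums, O(n).
rolling_mean <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w == 1L || n == 1L) return(x)
  h_right <- (w - 1L) %/% 2L
  h_left <- w - 1L - h_right
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h_left, 1L)
  hi <- pmin(i + h_right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package route their
# randomness through this helper so that equal seeds give identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
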