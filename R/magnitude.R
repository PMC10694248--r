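#' Sample impact magnitudes from a skewed law fixed by median and IQR
#'
#' On-field head-impact magnitudes are strongly right-skewed, and field studies
#' report them as a median with an interquartile range rather than a mean and
#' standard deviation. `sample_magnitude()` draws positive magnitudes from a
#' two-piece log-normal distribution whose median and both quartiles equal the
#' requested values exactly: below the median, `log(X/median)` is half-normal
#' with scale solved from the lower quartile; above it, from the upper
#' quartile. When the two log-quartile spreads agree this reduces to an
#' ordinary log-normal.
#'
#' @param n number of draws.
#' @param median target median of the distribution (must be positive).
#' @param iqr length-2 numeric, the target lower and upper quartiles
#'   `c(q25, q75)` with `0 < q25 < median < q75`.
#' @return numeric vector of `n` positive draws.
#' @examples
#' x <- sample_magnitude(1e4, median = 21.5, iqr = c(15.4, 33.9))
#' quantile(x, c(0.25, 0.5, 0.75))
#' @export
sample_magnitude <- function(n, median, iqr) {
  par <- magnitude_params(median, iqr)
  if (!is_count(n)) config_error("`n` must be a non-negative integer")
  q_magnitude(runif(n), par)
}

# Solve the two-piece log-normal scales from (median, q25, q75).
magnitude_params <- function(median, iqr) {
  if (!is_pos(median)) config_error("magnitude median must be a positive number")
  if (!is.numeric(iqr) || length(iqr) != 2L || !all(is.finite(iqr))) {
    config_error("`iqr` must be a finite numeric vector c(q25, q75)")
  }
  q25 <- iqr[[1L]]
  q75 <- iqr[[2L]]
  if (!(q25 > 0 && q25 < median && median < q75)) {
    config_error(
      "inconsistent quartiles: need 0 < q25 < median < q75, got (%g, %g, %g)",
      q25, median, q75
    )
  }
  z75 <- qnorm(0.75)
  list(
    median = median,
    sigma_lo = log(median / q25) / z75,
    sigma_hi = log(q75 / median) / z75
  )
}

# Quantile function of the two-piece log-normal; `p` may be a vector.
q_magnitude <- function(p, par) {
  z <- qnorm(p)
  par$median * exp(ifelse(z < 0, par$sigma_lo, par$sigma_hi) * z)
}

# CDF of the two-piece log-normal.
p_magnitude <- function(x, par) {
  lx <- log(x / par$median)
  pnorm(lx / ifelse(lx < 0, par$sigma_lo, par$sigma_hi))
}

# Draws conditioned to lie below (side = "below") or at/above (side = "above")
# a threshold; used to couple impact magnitudes to the capture indicator.
sample_magnitude_cond <- function(n, median, iqr, threshold, side) {
  par <- magnitude_params(median, iqr)
  pt <- p_magnitude(threshold, par)
  u <- runif(n)
  p <- switch(side,
    below = u * pt,
    above = pt + u * (1 - pt),
    config_error("unknown conditioning side '%s'", side)
  )
  q_magnitude(p, par)
}
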