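# Internal helpers shared across the simulation and signal-processing code.

# Standard gravity used for all g <-> m/s^2 conversions.
G_MS2 <- 9.80665

#' @noRd
stop_imgval <- function(fmt, ..., class = "imgval_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "imgval_error")))
}

config_error <- function(fmt, ...) {
  stop_imgval(fmt, ..., class = "imgval_config_error")
}

data_error <- function(fmt, ...) {
  stop_imgval(fmt, ..., class = "imgval_data_error")
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state so that
# seeded generators do not clobber the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Row-wise cross product of an n x 3 matrix with either another n x 3 matrix
# or a length-3 vector.
cross_rows <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = nrow(a), ncol = 3L, byrow = TRUE)
  cbind(
    a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
    a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
    a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  )
}

# Euclidean norm of each row of an n x 3 matrix.
resultant <- function(m) {
  sqrt(m[, 1L]^2 + m[, 2L]^2 + m[, 3L]^2)
}

# Uniform random unit vectors (rows).
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}
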