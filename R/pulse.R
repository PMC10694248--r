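#' Generate a single impact waveform pair
#'
#' Builds the canonical head-impact test pulse used by the synthetic session
#' generator: the linear channel is a haversine (raised-cosine) pulse whose
#' resultant peaks at exactly `pla`, the angular-velocity channel is a
#' haversine whose time derivative peaks at `pra`. The haversine is the
#' standard idealized impact shape in impact biomechanics; downstream
#' processing only depends on peak magnitudes and approximate bandwidth
#' (a pulse of duration T has most energy below ~2/T Hz).
#'
#' Both channels share their direction convention: directions are drawn
#' uniformly on the unit sphere from the current RNG stream, independently
#' for the linear and angular channels. The number of samples is chosen so
#' that the linear peak and the angular-acceleration peak both fall exactly
#' on grid samples.
#'
#' @param pla peak resultant linear acceleration (g), > 0.
#' @param pra peak resultant angular acceleration (rad/s2), > 0.
#' @param duration_ms pulse duration in milliseconds, within [2, 50].
#' @param rate_hz sampling rate (Hz).
#' @return list with `time` (s, starting at 0), `linear` (n x 3 matrix, g),
#'   `angular_velocity` (n x 3 matrix, rad/s), and the drawn unit
#'   `direction_linear` / `direction_angular`.
#' @examples
#' p <- generate_impact_pulse(20, 1500, 10, 3200)
#' max(sqrt(rowSums(p$linear^2)))  # == 20
#' @export
generate_impact_pulse <- function(pla, pra, duration_ms, rate_hz) {
  if (!is_pos(pla) || !is_pos(pra)) {
    config_error("pla and pra must be positive")
  }
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L ||
      duration_ms < 2 || duration_ms > 50) {
    config_error("duration_ms must lie in [2, 50] ms")
  }
  if (!is_pos(rate_hz)) config_error("rate_hz must be positive")
  # n - 1 intervals, multiple of 4: puts the haversine peak (t = T/2) and the
  # angular-acceleration peak (t = T/4) exactly on samples.
  n_int <- max(4L, 4L * round(duration_ms / 1000 * rate_hz / 4))
  n <- n_int + 1L
  tt <- (0:n_int) / rate_hz
  T_eff <- tt[n]
  u <- drop(runif_sphere(1L))
  v <- drop(runif_sphere(1L))
  hav <- 0.5 * (1 - cos(2 * pi * tt / T_eff))
  omega_peak <- pra * T_eff / pi
  list(
    time = tt,
    linear = outer(pla * hav, u),
    angular_velocity = outer(omega_peak * hav, v),
    direction_linear = u,
    direction_angular = v
  )
}

# Continuous-time evaluation of the same pulse model, used by the session
# generator to sample one physical event on each sensor's own jittered grid.
# Returns zero outside [t0 - T/2, t0 + T/2].
hav_pulse <- function(t, t0, duration_s) {
  x <- t - (t0 - duration_s / 2)
  ifelse(x >= 0 & x <= duration_s, 0.5 * (1 - cos(2 * pi * x / duration_s)), 0)
}

hav_pulse_deriv <- function(t, t0, duration_s) {
  x <- t - (t0 - duration_s / 2)
  ifelse(x >= 0 & x <= duration_s,
         (pi / duration_s) * sin(2 * pi * x / duration_s), 0)
}
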