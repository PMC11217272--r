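# Multi-band dynamic-range expansion of the amplitude envelopes.
#
# Static curve (per band, levels in dB):
#   threshold T = envelope RMS level + threshold_offset_db
#   below T:  output level = input level        (identity)
#   above T:  output level = T + r (input - T),  r = 1 + slope / 20 log10(2)
# so each octave (6.0206 dB) of input above threshold gains `slope` extra dB.
# The gain (in dB) is smoothed by one-pole attack/release ballistics: the
# attack constant applies while the target gain is rising.

DB_PER_OCTAVE <- 20 * log10(2)  # 6.0206 dB

#' Expand band envelopes
#'
#' Applies dynamic-range expansion independently to each band envelope. The
#' threshold is set per band relative to the RMS level of that band's whole
#' envelope (offline, per-stimulus processing), so expansion emphasises the
#' band's more intense portions -- e.g. formants -- and suppresses nothing
#' below threshold. An all-zero band (whose RMS level is undefined in dB) is
#' passed through unchanged. When `params$enabled` is `FALSE` the input is
#' returned untouched.
#'
#' @param env A [band_envelopes()] object.
#' @param params An [expansion_params()] object.
#' @return A `band_envelopes` object of the same dimensions.
#' @export
expand_envelopes <- function(env, params = expansion_params()) {
  stopifnot(inherits(env, "band_envelopes"))
  if (!params$enabled) return(env)
  r <- 1 + params$slope_db_per_octave / DB_PER_OCTAVE
  fs <- env$rate_hz
  out <- env$env
  for (i in seq_len(nrow(out))) {
    e <- out[i, ]
    if (all(e == 0)) next
    thresh_db <- amp_to_db(signal_rms(e)) + params$threshold_offset_db
    level_db <- ifelse(e > 0, amp_to_db(e), -Inf)
    target_gain <- pmax(0, (r - 1) * (level_db - thresh_db))
    target_gain[!is.finite(level_db)] <- 0
    g <- smooth_gain_db(target_gain, fs, params$attack_ms, params$release_ms)
    out[i, ] <- e * db_to_amp(g)
  }
  band_envelopes(out, fs)
}

# One-pole smoothing of the gain trajectory (in dB) with separate attack and
# release time constants. Initial state: unity gain (0 dB).
smooth_gain_db <- function(target, fs, attack_ms, release_ms) {
  ca <- exp(-1000 / (fs * attack_ms))
  cr <- exp(-1000 / (fs * release_ms))
  g <- numeric(length(target))
  s <- 0
  for (n in seq_along(target)) {
    cc <- if (target[n] > s) ca else cr
    s <- cc * s + (1 - cc) * target[n]
    g[n] <- s
  }
  g
}

#' Static expansion curve
#'
#' Closed-form input/output level mapping of the expander (no ballistics),
#' useful for checking steady-state behaviour.
#'
#' @param level_db Input level (dB).
#' @param threshold_db Expansion threshold (dB).
#' @param slope_db_per_octave Extra output dB per octave above threshold.
#' @return Output level (dB).
#' @export
expansion_static_curve <- function(level_db, threshold_db,
                                   slope_db_per_octave = 5) {
  r <- 1 + slope_db_per_octave / DB_PER_OCTAVE
  ifelse(level_db <= threshold_db, level_db,
         threshold_db + r * (level_db - threshold_db))
}
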