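# Amplitude-envelope extraction: band-pass -> Hilbert magnitude -> zero-phase
# low-pass at 23 Hz. The envelopes are the central intermediate
# representation of the vocoder (band_envelopes).

#' Band envelopes container
#'
#' @param env `num_bands x N` matrix of nonnegative envelope amplitudes.
#' @param rate_hz Sampling rate (Hz).
#' @return A `band_envelopes` object.
#' @export
band_envelopes <- function(env, rate_hz) {
  env <- as.matrix(env)
  if (!all(is.finite(env)) || any(env < 0)) {
    stop("band envelopes must be finite and nonnegative")
  }
  structure(list(env = env, rate_hz = rate_hz), class = "band_envelopes")
}

#' @export
print.band_envelopes <- function(x, ...) {
  cat(sprintf("<band_envelopes> %d bands x %d samples @ %g Hz\n",
              nrow(x$env), ncol(x$env), x$rate_hz))
  invisible(x)
}

# 6th-order Butterworth low-pass used zero-phase (filtfilt), giving an
# effective 12th-order magnitude response.
design_envelope_lpf <- function(config) {
  signal::butter(config$env_lpf_order,
                 config$env_lpf_corner_hz / (config$audio_rate_hz / 2))
}

#' Extract per-band amplitude envelopes
#'
#' For each band: band-pass filter the audio (delay-compensated linear-phase
#' FIR), take the magnitude of the analytic signal (Hilbert transform), and
#' smooth with a zero-phase (forward-backward) Butterworth low-pass at the
#' configured corner frequency. Small negative excursions introduced by the
#' low-pass are clamped to zero.
#'
#' @param audio An `audio_signal` at `config$audio_rate_hz`.
#' @param bank An `erb_filterbank` from [design_erb_filterbank()].
#' @param config A [vocoder_config()].
#' @return A [band_envelopes()] object (`num_bands x N`).
#' @export
extract_band_envelopes <- function(audio, bank = NULL,
                                   config = vocoder_config()) {
  audio <- as_audio(audio)
  if (audio$rate_hz != config$audio_rate_hz) {
    stop("audio must be at config$audio_rate_hz; resample first")
  }
  if (is.null(bank)) bank <- design_erb_filterbank(config)
  if (length(audio$samples) <= config$fir_order) {
    stop("audio shorter than the analysis filter transient (",
         config$fir_order, " samples)")
  }
  lpf <- design_envelope_lpf(config)
  env <- t(vapply(bank$taps, function(h) {
    bp <- apply_fir_aligned(audio$samples, h)
    e <- Mod(analytic_signal(bp))
    e <- as.numeric(signal::filtfilt(lpf, e))
    pmax(e, 0)
  }, numeric(length(audio$samples))))
  band_envelopes(env, config$audio_rate_hz)
}
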