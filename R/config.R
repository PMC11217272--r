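# Configuration objects: vocoder chain, envelope expander, stimulus assembly.

#' Envelope-expansion parameters
#'
#' Settings for the per-band dynamic-range expander applied to the amplitude
#' envelopes. Expansion increases output level faster than input level above
#' a threshold (the inverse of compression), so intense, spectrally focused
#' features such as formants are emphasised relative to their surroundings.
#'
#' @param enabled Apply expansion? When `FALSE`, [expand_envelopes()] is the
#'   identity.
#' @param attack_ms Gain-smoothing time constant (ms) used when the target
#'   gain is rising.
#' @param release_ms Time constant (ms) when the target gain is falling.
#' @param slope_db_per_octave Additional output gain (dB) per octave
#'   (6.0206 dB) of input level above threshold. The default 5 dB/octave
#'   gives an expansion ratio of 1 + 5/6.0206 (about 1.83).
#' @param threshold_offset_db Threshold relative to the RMS level of each
#'   band's envelope, in dB (default -5: threshold sits 5 dB below the
#'   envelope RMS).
#' @return An `expansion_params` object.
#' @export
expansion_params <- function(enabled = TRUE, attack_ms = 10,
                             release_ms = 100, slope_db_per_octave = 5,
                             threshold_offset_db = -5) {
  stopifnot(attack_ms > 0, release_ms > 0, slope_db_per_octave >= 0)
  structure(list(enabled = isTRUE(enabled), attack_ms = attack_ms,
                 release_ms = release_ms,
                 slope_db_per_octave = slope_db_per_octave,
                 threshold_offset_db = threshold_offset_db),
            class = "expansion_params")
}

#' Tactile vocoder configuration
#'
#' All numeric parameters of the audio-to-tactile conversion chain. Defaults
#' are the reference settings for wrist stimulation: eight bands equally
#' spaced on the ERB scale between 50 and 7000 Hz, envelopes low-passed at
#' 23 Hz, carriers centred on 170 Hz with gains compensating tactile
#' sensitivity across frequency, and stimuli calibrated to 141.5 dB re
#' 10^-6 m/s^2 (about 1.2 G) with an optional +/-3 dB level rove.
#'
#' @param audio_rate_hz Internal processing rate (Hz); input audio is
#'   resampled to this rate.
#' @param num_bands Number of analysis bands / tactile carriers.
#' @param band_lo_hz,band_hi_hz Filter-bank frequency limits (Hz).
#' @param fir_order Order of each analysis FIR band-pass filter.
#' @param env_lpf_corner_hz Corner frequency (Hz) of the envelope low-pass.
#' @param env_lpf_order Butterworth order of the envelope low-pass (applied
#'   forward-backward, so the magnitude response is squared).
#' @param carrier_freqs_hz Vibro-tactile carrier frequencies (Hz), strictly
#'   increasing, all below `audio_rate_hz / 2`.
#' @param carrier_gains_db Per-carrier fixed gains (dB) compensating for
#'   vibro-tactile detection-threshold differences across frequency.
#' @param nominal_level_db Calibration target: stimulus RMS acceleration in
#'   dB re 10^-6 m/s^2.
#' @param rove_halfwidth_db Half-width (dB) of the uniform level rove.
#' @param expansion An [expansion_params()] object.
#' @return A `vocoder_config` object.
#' @export
#' @examples
#' cfg <- vocoder_config()
#' cfg$carrier_freqs_hz
vocoder_config <- function(audio_rate_hz = 16000,
                           num_bands = 8,
                           band_lo_hz = 50,
                           band_hi_hz = 7000,
                           fir_order = 512,
                           env_lpf_corner_hz = 23,
                           env_lpf_order = 6,
                           carrier_freqs_hz = c(94.5, 116.5, 141.5, 170,
                                                202.5, 239, 280.5, 327.5),
                           carrier_gains_db = c(13.8, 12.1, 9.9, 6.4,
                                                1.6, 0, 1.7, 4),
                           nominal_level_db = 141.5,
                           rove_halfwidth_db = 3,
                           expansion = expansion_params()) {
  if (band_lo_hz >= band_hi_hz) stop("band_lo_hz must be below band_hi_hz")
  if (length(carrier_freqs_hz) != num_bands ||
      length(carrier_gains_db) != num_bands) {
    stop("carrier_freqs_hz and carrier_gains_db must have num_bands elements")
  }
  if (any(diff(carrier_freqs_hz) <= 0)) {
    stop("carrier_freqs_hz must be strictly increasing")
  }
  if (any(carrier_freqs_hz >= audio_rate_hz / 2)) {
    stop("carrier frequencies must be below the Nyquist frequency")
  }
  if (!inherits(expansion, "expansion_params")) {
    stop("expansion must be an expansion_params object")
  }
  structure(list(audio_rate_hz = audio_rate_hz, num_bands = num_bands,
                 band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 fir_order = fir_order,
                 env_lpf_corner_hz = env_lpf_corner_hz,
                 env_lpf_order = env_lpf_order,
                 carrier_freqs_hz = carrier_freqs_hz,
                 carrier_gains_db = carrier_gains_db,
                 nominal_level_db = nominal_level_db,
                 rove_halfwidth_db = rove_halfwidth_db,
                 expansion = expansion),
            class = "vocoder_config")
}

#' @export
print.vocoder_config <- function(x, ...) {
  cat(sprintf("<vocoder_config> %d bands %g-%g Hz (ERB-spaced), fs %g Hz\n",
              x$num_bands, x$band_lo_hz, x$band_hi_hz, x$audio_rate_hz))
  cat(sprintf("  carriers (Hz): %s\n", paste(x$carrier_freqs_hz, collapse = ", ")))
  cat(sprintf("  gains (dB):    %s\n", paste(x$carrier_gains_db, collapse = ", ")))
  cat(sprintf("  envelope LPF %g Hz (order %d, zero-phase); level %g dB re 1e-6 m/s^2; rove +/-%g dB\n",
              x$env_lpf_corner_hz, x$env_lpf_order,
              x$nominal_level_db, x$rove_halfwidth_db))
  cat(sprintf("  expansion: %s (attack %g ms, release %g ms, %g dB/octave, threshold RMS%+g dB)\n",
              if (x$expansion$enabled) "enabled" else "disabled",
              x$expansion$attack_ms, x$expansion$release_ms,
              x$expansion$slope_db_per_octave,
              x$expansion$threshold_offset_db))
  invisible(x)
}

#' Stimulus-assembly parameters
#'
#' Timing and level constants used when building speech-in-noise observation
#' intervals for the discrimination task.
#'
#' @param snr_db Signal-to-noise ratio (dB): silence-trimmed phoneme RMS
#'   minus noise-token RMS.
#' @param noise_pad_ms Noise token exceeds the longest phoneme of the trial
#'   by this duration (ms).
#' @param noise_ramp_ms Raised-cosine on/off ramp duration for the noise (ms).
#' @param phoneme_delay_ms Delay of phoneme onset after noise onset (ms).
#' @param match_ramp_ms Duration-matching fade-out ramp (ms).
#' @param dur_end_threshold_frac Fraction of maximum absolute amplitude
#'   defining a token's end point for duration matching.
#' @param snr_trim_threshold_frac Fraction of maximum absolute amplitude
#'   defining the silence-trimming endpoints used for SNR.
#' @param interval_gap_ms Gap between observation intervals (ms).
#' @return An `assembly_params` object.
#' @export
assembly_params <- function(snr_db = 5, noise_pad_ms = 400,
                            noise_ramp_ms = 50, phoneme_delay_ms = 200,
                            match_ramp_ms = 20,
                            dur_end_threshold_frac = 0.01,
                            snr_trim_threshold_frac = 0.10,
                            interval_gap_ms = 250) {
  stopifnot(noise_pad_ms > 0, noise_ramp_ms > 0, phoneme_delay_ms > 0,
            match_ramp_ms > 0, interval_gap_ms > 0,
            dur_end_threshold_frac > 0, dur_end_threshold_frac < 1,
            snr_trim_threshold_frac > 0, snr_trim_threshold_frac < 1)
  structure(list(snr_db = snr_db, noise_pad_ms = noise_pad_ms,
                 noise_ramp_ms = noise_ramp_ms,
                 phoneme_delay_ms = phoneme_delay_ms,
                 match_ramp_ms = match_ramp_ms,
                 dur_end_threshold_frac = dur_end_threshold_frac,
                 snr_trim_threshold_frac = snr_trim_threshold_frac,
                 interval_gap_ms = interval_gap_ms),
            class = "assembly_params")
}

#' Save a configuration as JSON
#'
#' Serialises a [vocoder_config()] (and optionally [assembly_params()]) to a
#' JSON file that mirrors the configuration field-for-field and round-trips
#' through [read_config()].
#'
#' @param config A `vocoder_config`.
#' @param path Output JSON path.
#' @param assembly Optional `assembly_params` stored alongside.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, assembly = NULL) {
  obj <- unclass(config)
  obj$expansion <- unclass(obj$expansion)
  out <- list(vocoder = obj)
  if (!is.null(assembly)) out$assembly <- unclass(assembly)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a configuration from JSON
#'
#' @param path JSON path written by [write_config()] (or hand-edited with the
#'   same fields; missing fields fall back to defaults).
#' @return A list with elements `vocoder` (a `vocoder_config`) and
#'   `assembly` (an `assembly_params`, or `NULL` when absent).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- raw$vocoder
  exp_args <- if (!is.null(v$expansion)) v$expansion else list()
  v$expansion <- NULL
  cfg <- do.call(vocoder_config,
                 c(v, list(expansion = do.call(expansion_params, exp_args))))
  asm <- if (!is.null(raw$assembly)) do.call(assembly_params, raw$assembly)
  list(vocoder = cfg, assembly = asm)
}

#' Hash a configuration
#'
#' MD5 digest of the canonical JSON form, recorded in stimulus sidecar
#' metadata so any output can be traced to the exact settings used.
#'
#' @param config A `vocoder_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
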