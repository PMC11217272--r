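# Carrier synthesis and calibration: band envelopes modulate fixed-phase
# vibro-tactile tones; the summed waveform is scaled to a nominal RMS
# acceleration with an optional uniform level rove.

TACTILE_REF_MS2 <- 1e-6  # reference acceleration for dB levels (m/s^2)

#' Tactile stimulus container
#'
#' Acceleration waveform (m/s^2) at the vocoder rate, with per-band
#' components retained so the waveform can be decomposed or re-examined.
#'
#' @param waveform Numeric acceleration waveform (m/s^2).
#' @param rate_hz Sampling rate (Hz).
#' @param per_band Optional `num_bands x N` matrix of band components whose
#'   column sums equal `waveform`.
#' @param applied_rove_db Level rove applied during calibration (dB; 0 when
#'   roving is off, `NA` before calibration).
#' @return A `tactile_stimulus` object.
#' @export
tactile_stimulus <- function(waveform, rate_hz, per_band = NULL,
                             applied_rove_db = NA_real_) {
  structure(list(waveform = as.numeric(waveform), rate_hz = rate_hz,
                 per_band = per_band, applied_rove_db = applied_rove_db),
            class = "tactile_stimulus")
}

#' @export
print.tactile_stimulus <- function(x, ...) {
  lev <- if (all(x$waveform == 0)) -Inf else
    amp_to_db(signal_rms(x$waveform) / TACTILE_REF_MS2)
  cat(sprintf("<tactile_stimulus> %d samples @ %g Hz, RMS %.1f dB re 1e-6 m/s^2",
              length(x$waveform), x$rate_hz, lev))
  if (is.finite(x$applied_rove_db)) {
    cat(sprintf(", rove %+.2f dB", x$applied_rove_db))
  }
  cat("\n")
  invisible(x)
}

#' Tactile stimulus level
#'
#' RMS acceleration of a stimulus expressed in dB re 10^-6 m/s^2.
#'
#' @param stim A `tactile_stimulus` or numeric waveform.
#' @return Level in dB.
#' @export
tactile_level_db <- function(stim) {
  w <- if (inherits(stim, "tactile_stimulus")) stim$waveform else stim
  amp_to_db(signal_rms(w) / TACTILE_REF_MS2)
}

#' Modulate vibro-tactile carriers with the band envelopes
#'
#' Band `i` contributes `env_i(t) * g_i * sin(2 pi f_i t)` with the fixed
#' per-carrier gain `g_i` (linear form of `carrier_gains_db[i]`) and carrier
#' phase zero at stimulus onset. The stimulus waveform is the sum across
#' bands; the individual components are retained.
#'
#' @param env A [band_envelopes()] object at `config$audio_rate_hz`.
#' @param config A [vocoder_config()].
#' @return An uncalibrated [tactile_stimulus()] (arbitrary amplitude scale;
#'   pass through [scale_and_rove()] to calibrate).
#' @export
synthesize_tactile <- function(env, config = vocoder_config()) {
  stopifnot(inherits(env, "band_envelopes"))
  if (nrow(env$env) != config$num_bands) {
    stop("envelope band count does not match config$num_bands")
  }
  if (env$rate_hz != config$audio_rate_hz) {
    stop("envelope rate does not match config$audio_rate_hz")
  }
  n <- ncol(env$env)
  t <- (seq_len(n) - 1) / config$audio_rate_hz
  per_band <- matrix(0, config$num_bands, n)
  for (i in seq_len(config$num_bands)) {
    per_band[i, ] <- env$env[i, ] *
      db_to_amp(config$carrier_gains_db[i]) *
      sin(2 * pi * config$carrier_freqs_hz[i] * t)
  }
  tactile_stimulus(colSums(per_band), config$audio_rate_hz, per_band)
}

#' Calibrate the stimulus level, with optional rove
#'
#' Scales the stimulus so its RMS acceleration sits at the nominal level
#' (`config$nominal_level_db`, dB re 10^-6 m/s^2). With roving enabled, a
#' per-stimulus offset drawn from U(-rove_halfwidth_db, +rove_halfwidth_db)
#' is added to the nominal level and recorded in `applied_rove_db`, so
#' absolute intensity carries no information about stimulus identity.
#'
#' Uses the current R random-number stream; call `set.seed()` beforehand for
#' reproducible roves.
#'
#' @param stim A `tactile_stimulus` with nonzero waveform.
#' @param config A [vocoder_config()].
#' @param rove_enabled Draw and apply a level rove?
#' @return The calibrated `tactile_stimulus`.
#' @export
scale_and_rove <- function(stim, config = vocoder_config(),
                           rove_enabled = FALSE) {
  stopifnot(inherits(stim, "tactile_stimulus"))
  if (all(stim$waveform == 0)) {
    stop("cannot calibrate an all-zero stimulus")
  }
  rove <- if (rove_enabled) {
    stats::runif(1, -config$rove_halfwidth_db, config$rove_halfwidth_db)
  } else 0
  target_rms <- TACTILE_REF_MS2 * db_to_amp(config$nominal_level_db + rove)
  k <- target_rms / signal_rms(stim$waveform)
  stim$waveform <- stim$waveform * k
  if (!is.null(stim$per_band)) stim$per_band <- stim$per_band * k
  stim$applied_rove_db <- rove
  stim
}

#' Run the full audio-to-tactile conversion chain
#'
#' Normalises the input's active speech level, resamples to the vocoder
#' rate, analyses it with the ERB filter bank, extracts and (optionally)
#' expands the band envelopes, modulates the vibro-tactile carriers, and
#' calibrates the result. This is the complete processing chain applied to
#' every stimulus.
#'
#' @param audio An `audio_signal` at any rate.
#' @param config A [vocoder_config()].
#' @param expansion_on Apply multi-band envelope expansion?
#' @param rove_enabled Apply a random level rove at calibration (uses the
#'   current RNG stream).
#' @param bank Optional pre-designed filter bank (saves repeated design).
#' @param normalize Normalise the active speech level first (default TRUE).
#' @return A calibrated [tactile_stimulus()] with extra elements
#'   `envelopes` (post-expansion `band_envelopes`) and `envelopes_raw`
#'   (pre-expansion).
#' @export
#' @examples
#' tone <- audio_signal(sin(2 * pi * 1000 * (0:7999) / 16000), 16000)
#' stim <- vocode(tone, expansion_on = FALSE)
#' tactile_level_db(stim)
vocode <- function(audio, config = vocoder_config(), expansion_on = TRUE,
                   rove_enabled = FALSE, bank = NULL, normalize = TRUE) {
  audio <- as_audio(audio)
  if (normalize) audio <- normalize_active_level(audio)
  audio <- resample_audio(audio, config$audio_rate_hz)
  if (is.null(bank)) bank <- design_erb_filterbank(config)
  env_raw <- extract_band_envelopes(audio, bank, config)
  env <- if (expansion_on) {
    pars <- config$expansion
    pars$enabled <- TRUE
    expand_envelopes(env_raw, pars)
  } else env_raw
  stim <- synthesize_tactile(env, config)
  stim <- scale_and_rove(stim, config, rove_enabled)
  stim$envelopes <- env
  stim$envelopes_raw <- env_raw
  stim
}
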