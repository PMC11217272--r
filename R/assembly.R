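# Stimulus assembly: silence-endpoint detection, duration matching with the
# exemption list, SNR mixing on silence-trimmed RMS, and the timing of noise
# observation intervals.

#' Detect silence-trimming endpoints
#'
#' The start is the first sample whose absolute amplitude reaches
#' `threshold_frac` of the waveform's maximum absolute amplitude; the end is
#' the last such sample. Endpoints are invariant to overall gain.
#'
#' @param audio An `audio_signal` or numeric vector.
#' @param threshold_frac Fraction of max absolute amplitude (default 0.10).
#' @return Integer vector `c(start, end)` (1-based, inclusive).
#' @export
detect_endpoints <- function(audio, threshold_frac = 0.10) {
  x <- if (inherits(audio, "audio_signal")) audio$samples else audio
  if (all(x == 0)) stop("endpoints undefined for an all-zero signal")
  above <- which(abs(x) >= threshold_frac * max(abs(x)))
  c(start = above[1], end = above[length(above)])
}

#' Silence-trimmed RMS
#'
#' RMS of the waveform between its `threshold_frac` endpoints -- the level
#' definition used on the speech side of the SNR.
#'
#' @inheritParams detect_endpoints
#' @return RMS value (linear units).
#' @export
trimmed_rms <- function(audio, threshold_frac = 0.10) {
  x <- if (inherits(audio, "audio_signal")) audio$samples else audio
  ep <- detect_endpoints(x, threshold_frac)
  signal_rms(x[ep[1]:ep[2]])
}

#' Duration-matching exemption list
#'
#' Phoneme labels exempt from duration matching: all diphthongs, plus the
#' consonants /g, d, l, r, v, w, j/, whose isolated productions differ
#' acoustically from running speech so truncating them would distort the
#' token.
#'
#' @return Character vector of exempt labels.
#' @export
duration_match_exceptions <- function() {
  ph <- phoneme_inventory()
  c(ph$label[ph$class == "diphthong"],
    "g", "d", "l", "r", "v", "w", "j")
}

#' Match the durations of a phoneme pair
#'
#' Unless either label is exempt (see [duration_match_exceptions()]), both
#' tokens are faded out with a raised-cosine ramp of `match_ramp_ms` that
#' reaches zero at the end point of the shorter token (the point where its
#' amplitude drops below `dur_end_threshold_frac` of maximum); all later
#' samples are zeroed. This removes duration as a discrimination cue.
#'
#' @param tok_a,tok_b `audio_signal` tokens at the same rate.
#' @param label_a,label_b Phoneme labels of the two tokens.
#' @param params An [assembly_params()].
#' @return List with elements `a`, `b` (processed tokens) and `matched`
#'   (logical; `FALSE` when the pair was exempt).
#' @export
match_durations <- function(tok_a, tok_b, label_a, label_b,
                            params = assembly_params()) {
  tok_a <- as_audio(tok_a); tok_b <- as_audio(tok_b)
  stopifnot(tok_a$rate_hz == tok_b$rate_hz)
  exempt <- duration_match_exceptions()
  if (label_a %in% exempt || label_b %in% exempt) {
    return(list(a = tok_a, b = tok_b, matched = FALSE))
  }
  fs <- tok_a$rate_hz
  end_a <- detect_endpoints(tok_a, params$dur_end_threshold_frac)["end"]
  end_b <- detect_endpoints(tok_b, params$dur_end_threshold_frac)["end"]
  fade_end <- min(end_a, end_b)
  ramp_len <- round(params$match_ramp_ms / 1000 * fs)
  ramp_start <- fade_end - ramp_len + 1L
  if (ramp_start < 1L) {
    warning("token shorter than the matching ramp; ramp truncated")
    ramp_start <- 1L
    ramp_len <- fade_end
  }
  fade <- function(tok) {
    x <- tok$samples
    k <- ramp_start:min(fade_end, length(x))
    # half-Hann fade: 1 at ramp_start, 0 at fade_end
    x[k] <- x[k] * 0.5 * (1 + cos(pi * (k - ramp_start) / (ramp_len - 1)))
    if (fade_end < length(x)) x[(fade_end + 1L):length(x)] <- 0
    audio_signal(x, fs)
  }
  list(a = fade(tok_a), b = fade(tok_b), matched = TRUE)
}

#' Mix a phoneme with noise at a target SNR
#'
#' The noise gain is chosen so that the noise RMS (over the full noise
#' token) sits `params$snr_db` below the phoneme's silence-trimmed RMS
#' (10% endpoints). Leading or trailing silence in the phoneme therefore
#' does not affect the mix. The output is the time-aligned sum (phoneme at
#' sample 1).
#'
#' @param phoneme,noise `audio_signal`s at the same rate.
#' @param params An [assembly_params()].
#' @return The mixture `audio_signal`, with the applied noise gain in
#'   attribute `"noise_gain"`.
#' @export
mix_at_snr <- function(phoneme, noise, params = assembly_params()) {
  phoneme <- as_audio(phoneme); noise <- as_audio(noise)
  stopifnot(phoneme$rate_hz == noise$rate_hz)
  if (all(noise$samples == 0)) stop("noise is all zero")
  target_noise_rms <- trimmed_rms(phoneme, params$snr_trim_threshold_frac) *
    db_to_amp(-params$snr_db)
  gain <- target_noise_rms / signal_rms(noise$samples)
  n <- max(length(phoneme$samples), length(noise$samples))
  mix <- numeric(n)
  mix[seq_along(noise$samples)] <- noise$samples * gain
  mix[seq_along(phoneme$samples)] <-
    mix[seq_along(phoneme$samples)] + phoneme$samples
  out <- audio_signal(mix, phoneme$rate_hz)
  attr(out, "noise_gain") <- gain
  out
}

#' Re-measure the SNR of an assembled interval
#'
#' Independent check of the assembly: silence-trimmed RMS level of the
#' phoneme component minus the RMS level of the noise component, in dB.
#'
#' @param phoneme_component,noise_component Numeric waveforms or
#'   `audio_signal`s (e.g. the `components` attribute of
#'   [assemble_noise_interval()]).
#' @param threshold_frac Trimming threshold for the phoneme side.
#' @return SNR in dB.
#' @export
measure_interval_snr <- function(phoneme_component, noise_component,
                                 threshold_frac = 0.10) {
  amp_to_db(trimmed_rms(phoneme_component, threshold_frac)) -
    amp_to_db(signal_rms(noise_component))
}

#' Assemble one noise observation interval
#'
#' Excises a noise token of duration `longest_ms + noise_pad_ms` from the
#' long speech-shaped noise at a random start point (so every interval of a
#' trial carries a different noise token), applies raised-cosine on/off
#' ramps of `noise_ramp_ms`, sets the noise level from the phoneme's
#' silence-trimmed RMS at `snr_db`, and adds the phoneme starting
#' `phoneme_delay_ms` after noise onset. Because the noise token outlasts
#' the longest phoneme of the trial by `noise_pad_ms` (400 ms) and the
#' phoneme starts 200 ms in, at least 200 ms of noise always remains after
#' the phoneme ends.
#'
#' Uses the current RNG stream for the excision point; seed beforehand for
#' reproducibility.
#'
#' @param phoneme The phoneme token (`audio_signal`).
#' @param noise_src Long speech-shaped noise (`audio_signal`).
#' @param longest_ms Duration (ms) of the longest phoneme in the trial; must
#'   be at least this phoneme's duration.
#' @param params An [assembly_params()].
#' @param start_frac Optional excision point as a fraction in `[0, 1)` of
#'   the admissible range (e.g. a pre-drawn value from a trial schedule);
#'   when `NULL` a uniform draw from the current RNG stream is used.
#' @return The interval `audio_signal`, with attributes `components` (list
#'   of `phoneme` and `noise` waveforms summing to the interval) and
#'   `noise_start` (excision index into `noise_src`).
#' @export
assemble_noise_interval <- function(phoneme, noise_src, longest_ms,
                                    params = assembly_params(),
                                    start_frac = NULL) {
  phoneme <- as_audio(phoneme); noise_src <- as_audio(noise_src)
  stopifnot(phoneme$rate_hz == noise_src$rate_hz)
  fs <- phoneme$rate_hz
  n_ph <- length(phoneme$samples)
  if (n_ph > round(longest_ms / 1000 * fs)) {
    stop("longest_ms is shorter than the phoneme itself")
  }
  n_tok <- round((longest_ms + params$noise_pad_ms) / 1000 * fs)
  n_src <- length(noise_src$samples)
  if (n_src < n_tok) stop("noise source too short for excision")
  start <- if (is.null(start_frac)) {
    sample.int(n_src - n_tok + 1L, 1L)
  } else {
    1L + floor(start_frac * (n_src - n_tok))
  }
  tok <- noise_src$samples[start:(start + n_tok - 1L)]
  tok <- apply_raised_cosine(tok, round(params$noise_ramp_ms / 1000 * fs))
  gain <- trimmed_rms(phoneme, params$snr_trim_threshold_frac) *
    db_to_amp(-params$snr_db) / signal_rms(tok)
  noise_comp <- tok * gain
  delay <- round(params$phoneme_delay_ms / 1000 * fs)
  ph_comp <- numeric(n_tok)
  ph_comp[(delay + 1L):(delay + n_ph)] <- phoneme$samples
  out <- audio_signal(noise_comp + ph_comp, fs)
  attr(out, "components") <- list(phoneme = ph_comp, noise = noise_comp)
  attr(out, "noise_start") <- start
  out
}
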