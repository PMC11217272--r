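# Active speech level measurement and normalisation (ITU-T P.56 method B
# style). The active level is the RMS level computed over speech-active
# samples only, so tokens with long pauses are not under-levelled.

#' Measure the active speech level
#'
#' Estimates the active speech level of a waveform in the manner of ITU-T
#' P.56 method B: a two-stage exponentially smoothed envelope (time constant
#' 30 ms) is compared against a descending ladder of thresholds, activity at
#' each threshold is extended by a 200-ms hangover, and the active level is
#' the point where the level-over-threshold difference crosses the 15.9-dB
#' margin (linear interpolation between ladder steps).
#'
#' @param audio An `audio_signal` (or numeric vector with `rate_hz`).
#' @param rate_hz Sampling rate when `audio` is a bare vector.
#' @param margin_db Margin between active level and threshold (dB).
#' @param time_constant_s Envelope smoothing time constant (s).
#' @param hangover_s Hangover time (s).
#' @return A list: `active_level_db` (dB re full scale), `activity_factor`
#'   (fraction of samples active), `rms_db` (overall RMS, dB re full scale).
#' @export
active_speech_level <- function(audio, rate_hz = NULL, margin_db = 15.9,
                                time_constant_s = 0.03, hangover_s = 0.2) {
  audio <- as_audio(audio, rate_hz)
  x <- audio$samples
  fs <- audio$rate_hz
  if (all(x == 0)) stop("active level undefined for an all-zero signal")

  g <- exp(-1 / (fs * time_constant_s))
  p <- as.numeric(stats::filter((1 - g) * abs(x), g, method = "recursive"))
  q <- as.numeric(stats::filter((1 - g) * p, g, method = "recursive"))

  sq <- sum(x^2)
  n <- length(x)
  rms_db <- 10 * log10(sq / n)
  hang <- round(hangover_s * fs)

  # Ascending threshold ladder, 0.5-dB steps over 100 dB below the envelope
  # peak. As the threshold rises the activity shrinks and the difference
  # (active level - threshold) falls; the active level is read where that
  # difference crosses the margin.
  peak_db <- amp_to_db(max(q))
  thr_db <- seq(peak_db - 100, peak_db, by = 0.5)
  idx <- seq_len(n)
  prev <- NULL
  for (j in seq_along(thr_db)) {
    b <- q >= db_to_amp(thr_db[j])
    last_true <- cummax(ifelse(b, idx, 0L))
    a <- sum(last_true > 0L & (idx - last_true) <= hang)
    if (a == 0L) break
    lvl <- 10 * log10(sq / a)
    d <- lvl - thr_db[j]
    cur <- list(lvl = lvl, act = a / n, diff = d)
    if (d < margin_db) {
      if (is.null(prev)) {
        warning("activity margin below ladder; using overall RMS level")
        return(list(active_level_db = rms_db, activity_factor = 1,
                    rms_db = rms_db))
      }
      w <- (prev$diff - margin_db) / (prev$diff - d)
      return(list(active_level_db = prev$lvl + w * (lvl - prev$lvl),
                  activity_factor = prev$act + w * (cur$act - prev$act),
                  rms_db = rms_db))
    }
    prev <- cur
  }
  # difference stayed above the margin up to the highest active threshold
  list(active_level_db = prev$lvl, activity_factor = prev$act,
       rms_db = rms_db)
}

#' Normalise audio to a target active speech level
#'
#' Pure rescaling: the waveform shape is unchanged and only an overall gain
#' is applied so that the active speech level equals `target_db`.
#'
#' @param audio An `audio_signal`.
#' @param target_db Target active level in dB re full scale (dBov). The
#'   default -26 dBov is the customary operating level for speech-processing
#'   chains.
#' @param ... Passed to [active_speech_level()].
#' @return The rescaled `audio_signal`, with the applied gain (dB) in
#'   attribute `"gain_db"`.
#' @export
normalize_active_level <- function(audio, target_db = -26, ...) {
  audio <- as_audio(audio)
  lev <- active_speech_level(audio, ...)
  gain_db <- target_db - lev$active_level_db
  out <- audio_signal(audio$samples * db_to_amp(gain_db), audio$rate_hz)
  attr(out, "gain_db") <- gain_db
  out
}
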