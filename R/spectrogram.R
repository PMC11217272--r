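# Spectrogram-style visualisation of input audio and tactile envelopes.

#' Render a spectrogram of audio or of tactile envelopes
#'
#' Audio style: short-time Fourier magnitude with an 8-ms Hann window
#' zero-padded to 8192 points, displayed in dB relative to the maximum
#' magnitude. Tactile style: the band-envelope matrix itself (one row per
#' vocoder band), in dB relative to the maximum envelope amplitude.
#'
#' @param x An `audio_signal` (audio style), or a `band_envelopes` /
#'   `tactile_stimulus` (tactile style).
#' @param style `"audio"` or `"tactile"`; inferred from the class of `x`
#'   when missing.
#' @param window_s Analysis window length in seconds (audio style).
#' @param nfft Zero-padded FFT length (audio style).
#' @param hop Hop size in samples (audio style). The reference rendering
#'   uses hop 1; the default `NULL` picks the smallest hop giving at most
#'   `max_frames` frames so long signals stay tractable.
#' @param max_frames Frame cap used when `hop` is `NULL`.
#' @param floor_db Display floor (dB re maximum).
#' @return A `tactile_spectrogram`: list with `db` (frequency/band x time
#'   matrix), `time_s`, `freq_hz` (or `band`), `style`.
#' @export
render_tactile_spectrogram <- function(x, style = NULL, window_s = 0.008,
                                       nfft = 8192, hop = NULL,
                                       max_frames = 1000, floor_db = -80) {
  if (is.null(style)) {
    style <- if (inherits(x, c("band_envelopes", "tactile_stimulus")))
      "tactile" else "audio"
  }
  style <- match.arg(style, c("audio", "tactile"))
  if (style == "tactile") {
    env <- if (inherits(x, "tactile_stimulus")) x$envelopes else x
    stopifnot(inherits(env, "band_envelopes"))
    m <- env$env
    peak <- max(m)
    db <- if (peak == 0) matrix(floor_db, nrow(m), ncol(m)) else
      pmax(amp_to_db(m / peak), floor_db)
    db[!is.finite(db)] <- floor_db
    out <- list(db = db, band = seq_len(nrow(m)),
                time_s = (seq_len(ncol(m)) - 1) / env$rate_hz,
                style = "tactile")
  } else {
    x <- as_audio(x)
    fs <- x$rate_hz
    w_len <- round(window_s * fs)
    win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w_len) - 1) / (w_len - 1))
    n <- length(x$samples)
    if (n < w_len) stop("signal shorter than the analysis window")
    if (is.null(hop)) hop <- max(1L, ceiling((n - w_len + 1) / max_frames))
    starts <- seq(1L, n - w_len + 1L, by = hop)
    frames <- vapply(starts, function(s) {
      seg <- x$samples[s:(s + w_len - 1L)] * win
      M <- Mod(stats::fft(c(seg, numeric(nfft - w_len))))
      M[1:(nfft %/% 2 + 1)]
    }, numeric(nfft %/% 2 + 1))
    peak <- max(frames)
    db <- if (peak == 0) matrix(floor_db, nrow(frames), ncol(frames)) else
      pmax(amp_to_db(frames / peak), floor_db)
    db[!is.finite(db)] <- floor_db
    out <- list(db = db, freq_hz = (0:(nfft %/% 2)) * fs / nfft,
                time_s = (starts - 1) / fs, style = "audio")
  }
  structure(out, class = "tactile_spectrogram")
}

#' @export
plot.tactile_spectrogram <- function(x, ylim = NULL, main = NULL, ...) {
  yvals <- if (x$style == "audio") x$freq_hz else x$band
  graphics::image(x$time_s, yvals, t(x$db),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "Time (s)",
                  ylab = if (x$style == "audio") "Frequency (Hz)" else "Band",
                  ylim = ylim,
                  main = if (is.null(main)) x$style else main, ...)
  invisible(x)
}
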