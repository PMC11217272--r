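# Speech-shaped masking noise: estimate the corpus long-term average speech
# spectrum (LTASS), fit a linear-phase FIR shaping filter to it, and filter
# white Gaussian noise.

#' Estimate the long-term average speech spectrum
#'
#' Averages short-time Fourier magnitude spectra (Hann window, 50% overlap,
#' window length `window_len`) across all frames of all tokens, after
#' removing silent frames. A frame counts as silent when its RMS falls below
#' `silence_frac` of the token's peak frame RMS, mirroring the 10% silence
#' convention used elsewhere for endpoint trimming.
#'
#' @param corpus List of `audio_signal` tokens, all at the same rate.
#' @param window_len STFT window length in samples.
#' @param silence_frac Silence criterion as a fraction of peak frame RMS.
#' @return An `ltass` object: `freq_hz` (length `window_len/2 + 1`),
#'   `magnitude` (mean one-sided magnitude), `window_len`, `rate_hz`,
#'   `n_frames`.
#' @export
estimate_ltass <- function(corpus, window_len = 4096, silence_frac = 0.10) {
  if (length(corpus) == 0L) stop("empty corpus")
  corpus <- lapply(corpus, as_audio)
  rate <- corpus[[1]]$rate_hz
  if (any(vapply(corpus, function(a) a$rate_hz, 0) != rate)) {
    stop("all corpus tokens must share one sampling rate")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window_len) - 1) / (window_len - 1))
  hop <- window_len %/% 2
  acc <- numeric(window_len %/% 2 + 1)
  n_frames <- 0L
  for (tok in corpus) {
    x <- tok$samples
    if (length(x) < window_len) x <- c(x, numeric(window_len - length(x)))
    starts <- seq(1L, length(x) - window_len + 1L, by = hop)
    frames <- vapply(starts, function(s) x[s:(s + window_len - 1L)],
                     numeric(window_len))
    frame_rms <- sqrt(colMeans(frames^2))
    keep <- frame_rms >= silence_frac * max(frame_rms)
    if (!any(keep)) next
    for (k in which(keep)) {
      M <- Mod(stats::fft(frames[, k] * w))
      acc <- acc + M[1:(window_len %/% 2 + 1)]
      n_frames <- n_frames + 1L
    }
  }
  if (n_frames == 0L) stop("corpus contains no active (non-silent) frames")
  structure(list(freq_hz = (0:(window_len %/% 2)) * rate / window_len,
                 magnitude = acc / n_frames,
                 window_len = window_len, rate_hz = rate,
                 n_frames = n_frames),
            class = "ltass")
}

#' @export
print.ltass <- function(x, ...) {
  cat(sprintf("<ltass> %d bins to %g Hz (window %d), %d frames averaged\n",
              length(x$magnitude), max(x$freq_hz), x$window_len, x$n_frames))
  invisible(x)
}

#' Fit a linear-phase FIR noise-shaping filter to an LTASS
#'
#' Least-squares fit on the LTASS bin grid: the symmetric (linear-phase)
#' `n_taps`-tap filter minimising the summed squared magnitude error over
#' the DFT grid is the centred, truncated inverse DFT of the target
#' magnitude. The residual (summed squared magnitude error over the bins) is
#' reported; it is non-increasing in `n_taps`.
#'
#' @param ltass An `ltass` object.
#' @param n_taps Number of filter taps (odd; default 2049 for a 4096-point
#'   analysis grid).
#' @return A `noise_filter` object: `taps`, `residual`, `rate_hz`,
#'   `group_delay` (samples).
#' @export
fit_noise_filter <- function(ltass, n_taps = 2049) {
  stopifnot(inherits(ltass, "ltass"), n_taps %% 2 == 1)
  nfft <- ltass$window_len
  if (n_taps > nfft) stop("n_taps cannot exceed the analysis grid length")
  m <- ltass$magnitude
  full <- c(m, rev(m[2:(length(m) - 1)]))  # even-symmetric real spectrum
  h0 <- Re(stats::fft(full, inverse = TRUE)) / nfft
  half <- (n_taps - 1) %/% 2
  taps <- c(h0[(nfft - half + 1):nfft], h0[1:(half + 1)])
  H <- stats::fft(c(taps, numeric(nfft - n_taps)))
  residual <- sum((Mod(H)[1:length(m)] - m)^2)
  structure(list(taps = taps, residual = residual,
                 rate_hz = ltass$rate_hz, group_delay = half),
            class = "noise_filter")
}

#' Generate speech-shaped noise
#'
#' Filters white Gaussian noise through the fitted shaping filter
#' (delay-compensated), so the long-run spectrum of the output matches the
#' LTASS shape.
#'
#' @param filt A `noise_filter` from [fit_noise_filter()].
#' @param duration_s Duration of noise to generate (seconds). The reference
#'   masker is 5 minutes long (300 s).
#' @param seed Optional integer seed for a reproducible draw.
#' @return An `audio_signal` of `round(duration_s * rate)` samples.
#' @export
generate_speech_shaped_noise <- function(filt, duration_s = 300,
                                         seed = NULL) {
  stopifnot(inherits(filt, "noise_filter"), duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * filt$rate_hz)
  white <- stats::rnorm(n + length(filt$taps))
  y <- signal::fftfilt(filt$taps, white)
  audio_signal(as.numeric(y[(filt$group_delay + 1):(filt$group_delay + n)]),
               filt$rate_hz)
}
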