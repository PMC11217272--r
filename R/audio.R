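# Audio container and WAV I/O.
#
# Waveforms are plain numeric vectors wrapped with a sampling rate. Speech
# audio is dimensionless (full scale = 1); tactile waveforms carry units of
# m/s^2 and are handled by the tactile_stimulus class instead.

#' Create a mono audio signal
#'
#' Lightweight container pairing a finite numeric waveform with its sampling
#' rate. All processing functions in the package take and return
#' `audio_signal` objects.
#'
#' @param samples Numeric vector of finite sample values (mono).
#' @param rate_hz Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate_hz`.
#' @export
#' @examples
#' tone <- audio_signal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
audio_signal <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio_signal: empty waveform")
  if (!all(is.finite(samples))) stop("audio_signal: samples must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("audio_signal: rate_hz must be a positive scalar")
  }
  structure(list(samples = samples, rate_hz = rate_hz), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, signal_rms(x$samples)))
  invisible(x)
}

as_audio <- function(x, rate_hz = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(rate_hz)) stop("rate_hz required for bare numeric input")
  audio_signal(x, rate_hz)
}

#' Root-mean-square amplitude
#'
#' @param x Numeric vector or `audio_signal`.
#' @return RMS value (linear units).
#' @export
signal_rms <- function(x) {
  if (inherits(x, "audio_signal")) x <- x$samples
  sqrt(mean(x^2))
}

# dB conversions used throughout: amplitude ratios, 20 log10.
amp_to_db <- function(a) 20 * log10(a)
db_to_amp <- function(db) 10^(db / 20)

#' Resample audio to a new rate
#'
#' Polyphase anti-aliased resampling (via [signal::resample()]) using the
#' rational factor between the two rates.
#'
#' @param audio An `audio_signal`.
#' @param rate_hz Target sampling rate in Hz.
#' @return Resampled `audio_signal` at `rate_hz`.
#' @export
resample_audio <- function(audio, rate_hz) {
  audio <- as_audio(audio)
  if (audio$rate_hz == rate_hz) return(audio)
  p <- round(rate_hz)
  q <- round(audio$rate_hz)
  g <- gcd_int(p, q)
  y <- signal::resample(audio$samples, p / g, q / g)
  audio_signal(as.numeric(y), rate_hz)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting PCM 16/24-bit and IEEE float 32-bit.
#' Multichannel files are reduced to mono by taking the first channel unless
#' `channel = NULL`, in which case the sample matrix is returned in an
#' attribute.
#'
#' @param path Path to a `.wav` file.
#' @param channel Channel to extract for multichannel files (default 1).
#' @return An `audio_signal`.
#' @export
read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)

  x <- switch(as.character(fmt$format),
    "1" = {
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24) {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                  endian = "little"),
    stop("unsupported WAV format code: ", fmt$format)
  )

  if (fmt$channels > 1L) {
    m <- matrix(x, nrow = fmt$channels)
    if (is.null(channel)) {
      out <- audio_signal(m[1, ], fmt$rate)
      attr(out, "channels") <- t(m)
      return(out)
    }
    x <- m[channel, ]
  }
  audio_signal(x, fmt$rate)
}

#' Write a WAV file
#'
#' Writes mono or multichannel audio as IEEE float 32-bit (default, exact for
#' physical-unit tactile waveforms) or PCM 16-bit.
#'
#' @param x Numeric vector, matrix (samples x channels), or `audio_signal`.
#' @param path Output path.
#' @param rate_hz Sampling rate (taken from `x` when it is an `audio_signal`).
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate_hz = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "audio_signal")) {
    rate_hz <- x$rate_hz
    x <- x$samples
  }
  if (is.null(rate_hz)) stop("rate_hz required")
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x)
  interleaved <- as.numeric(t(x))

  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  block_align <- n_ch * bits / 8
  data_bytes <- length(interleaved) * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    v <- pmax(pmin(interleaved, 1), -1)
    writeBin(as.integer(round(v * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

# Analytic signal via the FFT; returns complex vector whose modulus is the
# Hilbert envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Averaged-periodogram (Welch) spectrum estimate with a Hann window.
# Returns one-sided magnitude (not power) on the FFT bin grid, suitable for
# comparison against an LTASS or a filter magnitude response.
welch_magnitude <- function(x, rate_hz, nfft = 4096, overlap = 0.5) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  acc <- numeric(nfft / 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[1:(nfft / 2 + 1)]
  }
  list(freq_hz = (0:(nfft / 2)) * rate_hz / nfft,
       magnitude = sqrt(acc / length(starts)))
}

# Raised-cosine (half-Hann) onset/offset ramp applied in place.
apply_raised_cosine <- function(x, n_on, n_off = n_on) {
  n <- length(x)
  if (n_on > 0) {
    k <- seq_len(min(n_on, n))
    x[k] <- x[k] * 0.5 * (1 - cos(pi * (k - 1) / n_on))
  }
  if (n_off > 0) {
    k <- seq_len(min(n_off, n))
    idx <- n - k + 1L
    x[idx] <- x[idx] * 0.5 * (1 - cos(pi * (k - 1) / n_off))
  }
  x
}
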