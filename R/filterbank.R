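# ERB-spaced FIR analysis filter bank.
#
# Band edges are equally spaced on the ERB-number scale (Glasberg & Moore):
#   ERBn(f) = 21.4 * log10(0.00437 f + 1)
# which approximates the spacing of cochlear filters, so the eight tactile
# carriers divide the speech range in a perceptually motivated way.

#' ERB-number scale conversions
#'
#' `erb_number()` maps frequency in Hz to ERB number; `erb_frequency()` is
#' its inverse.
#'
#' @param f_hz Frequency in Hz.
#' @param n ERB number.
#' @return Numeric vector.
#' @export
erb_number <- function(f_hz) 21.4 * log10(0.00437 * f_hz + 1)

#' @rdname erb_number
#' @export
erb_frequency <- function(n) (10^(n / 21.4) - 1) / 0.00437

#' Band edges equally spaced on the ERB scale
#'
#' @param lo_hz,hi_hz Frequency limits (Hz).
#' @param num_bands Number of bands; `num_bands + 1` edges are returned.
#' @return Numeric vector of edges (Hz), first exactly `lo_hz`, last exactly
#'   `hi_hz`.
#' @export
erb_band_edges <- function(lo_hz, hi_hz, num_bands) {
  e <- erb_frequency(seq(erb_number(lo_hz), erb_number(hi_hz),
                         length.out = num_bands + 1))
  e[1] <- lo_hz
  e[num_bands + 1] <- hi_hz
  e
}

#' Design the ERB-spaced analysis filter bank
#'
#' Linear-phase FIR band-pass filters (windowed-sinc, Hamming window) of the
#' configured order, one per band, with band edges equally spaced on the ERB
#' number scale between `band_lo_hz` and `band_hi_hz`. Windowed-sinc design
#' places the -6 dB points of each filter at its band edges, so adjacent
#' bands cross over at their shared edge.
#'
#' @param config A [vocoder_config()].
#' @return An `erb_filterbank`: list with `taps` (list of `fir_order + 1`
#'   coefficient vectors), `edges_hz`, `erb_edges`, `order`, and `rate_hz`.
#' @export
#' @examples
#' bank <- design_erb_filterbank(vocoder_config())
#' round(bank$edges_hz)
design_erb_filterbank <- function(config = vocoder_config()) {
  if (config$band_lo_hz < 20) stop("band_lo_hz must be at least 20 Hz")
  if (config$band_hi_hz >= config$audio_rate_hz / 2) {
    stop("band_hi_hz must be below the Nyquist frequency")
  }
  edges <- erb_band_edges(config$band_lo_hz, config$band_hi_hz,
                          config$num_bands)
  taps <- lapply(seq_len(config$num_bands), function(i) {
    fir_bandpass_hamming(config$fir_order, edges[i], edges[i + 1],
                         config$audio_rate_hz)
  })
  structure(list(taps = taps, edges_hz = edges,
                 erb_edges = erb_number(edges),
                 order = config$fir_order,
                 rate_hz = config$audio_rate_hz),
            class = "erb_filterbank")
}

#' @export
print.erb_filterbank <- function(x, ...) {
  cat(sprintf("<erb_filterbank> %d bands, order %d, fs %g Hz\n",
              length(x$taps), x$order, x$rate_hz))
  cat("  edges (Hz):", paste(round(x$edges_hz, 1), collapse = ", "), "\n")
  invisible(x)
}

# Windowed-sinc (Hamming) linear-phase band-pass design. The ideal
# band-pass impulse response truncated by the window crosses -6 dB at the
# two cutoff frequencies, so adjacent bands meet at their shared edge.
fir_bandpass_hamming <- function(order, f1_hz, f2_hz, fs) {
  stopifnot(order %% 2 == 0)
  k <- 0:order
  x <- k - order / 2
  w1 <- 2 * pi * f1_hz / fs
  w2 <- 2 * pi * f2_hz / fs
  h <- ifelse(x == 0, (w2 - w1) / pi, (sin(w2 * x) - sin(w1 * x)) / (pi * x))
  h * (0.54 - 0.46 * cos(2 * pi * k / order))
}

# FFT convolution with linear-phase group-delay compensation, so band
# signals stay time-aligned with the input.
apply_fir_aligned <- function(x, taps) {
  d <- (length(taps) - 1) %/% 2
  y <- signal::fftfilt(taps, c(x, numeric(d)))
  as.numeric(y[(d + 1):(d + length(x))])
}
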