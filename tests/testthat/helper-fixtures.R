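# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

test_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <- build_synthetic_corpus(seed = 42)
  }
  .fixture_cache$corpus
}

test_noise <- function() {
  if (is.null(.fixture_cache$noise)) {
    lt <- estimate_ltass(corpus_tokens_flat(test_corpus()))
    .fixture_cache$noise <-
      generate_speech_shaped_noise(fit_noise_filter(lt), duration_s = 20,
                                   seed = 42)
  }
  .fixture_cache$noise
}

tone_audio <- function(freq_hz, dur_s = 1, amp = 0.3, fs = 16000) {
  audio_signal(amp * sin(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs),
               fs)
}

# Independent ERB-edge oracle: numerically invert
# ERBn(f) = 21.4 log10(0.00437 f + 1) at equally spaced ERB numbers,
# deliberately avoiding the package's closed-form inverse.
oracle_erb_edges <- function(lo, hi, n_bands) {
  erbn <- function(f) 21.4 * log10(0.00437 * f + 1)
  targets <- seq(erbn(lo), erbn(hi), length.out = n_bands + 1)
  vapply(targets, function(tg) {
    stats::uniroot(function(f) erbn(f) - tg, c(1, 10000),
                   tol = 1e-9)$root
  }, numeric(1))
}

# Magnitude response of FIR taps at given frequencies.
fir_response_db <- function(taps, freq_hz, fs, nfft = 65536) {
  H <- Mod(stats::fft(c(taps, numeric(nfft - length(taps)))))
  bins <- round(freq_hz / fs * nfft) + 1
  20 * log10(H[bins])
}
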