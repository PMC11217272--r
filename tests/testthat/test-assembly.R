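test_that("endpoint detection matches the hand-checkable example", {
  x <- c(0, 0, 0.05, 0.5, 1.0, 0.5, 0.05, 0)
  ep <- detect_endpoints(x, 0.10)
  expect_identical(unname(ep), c(4L, 6L))  # spec's 0-based (3, 5)
  # full-scale constant signal spans everything
  ep2 <- detect_endpoints(rep(0.7, 100), 0.10)
  expect_identical(unname(ep2), c(1L, 100L))
  # relative threshold: gain-invariant
  expect_identical(detect_endpoints(x * 0.3, 0.10), ep)
  expect_error(detect_endpoints(numeric(10) + 0), "all-zero")
})

test_that("pairs containing exempt phonemes skip duration matching", {
  corpus <- test_corpus()
  a <- corpus_token(corpus, "male", "a\u028a", 1)  # diphthong
  b <- corpus_token(corpus, "male", "s", 1)
  md <- match_durations(a, b, "a\u028a", "s")
  expect_false(md$matched)
  expect_identical(md$a$samples, a$samples)
  expect_identical(md$b$samples, b$samples)
  # consonant exemption list
  expect_true(all(c("g", "d", "l", "r", "v", "w", "j") %in%
                    duration_match_exceptions()))
})

test_that("duration matching fades both tokens to the shorter 1% end point", {
  fs <- 16000
  t1 <- tone_audio(300, dur_s = 0.3, amp = 0.5)
  t2 <- tone_audio(350, dur_s = 0.5, amp = 0.5)
  md <- match_durations(t1, t2, "s", "f")
  expect_true(md$matched)
  e1 <- detect_endpoints(t1, 0.01)["end"]
  # both outputs silent beyond the shorter end point
  expect_true(all(md$b$samples[(e1 + 1):length(md$b$samples)] == 0))
  # fade spans the final 20 ms before the end point
  ramp <- round(0.020 * fs)
  pre_fade <- md$b$samples[1:(e1 - ramp)]
  expect_equal(pre_fade, t2$samples[1:(e1 - ramp)], tolerance = 1e-12)
  # never lengthens a token
  expect_lte(length(md$a$samples), length(t1$samples))
  # equal-length tokens end identically
  md2 <- match_durations(t1, tone_audio(350, dur_s = 0.3, amp = 0.5),
                         "s", "f")
  ea <- max(which(md2$a$samples != 0))
  eb <- max(which(md2$b$samples != 0))
  expect_equal(ea, eb, tolerance = 2)
})

test_that("SNR mixing sets the requested trimmed-RMS level difference", {
  set.seed(21)
  fs <- 16000
  ph <- tone_audio(800, dur_s = 0.4, amp = 0.4)
  noise <- audio_signal(stats::rnorm(fs), fs)
  pars <- assembly_params(snr_db = 5)
  mix <- mix_at_snr(ph, noise, pars)
  g <- attr(mix, "noise_gain")
  snr <- 20 * log10(trimmed_rms(ph) / signal_rms(noise$samples * g))
  expect_equal(snr, 5, tolerance = 0.01)
  # snr 0 with matched levels gives unit gain
  n0 <- audio_signal(noise$samples / signal_rms(noise$samples) *
                       trimmed_rms(ph), fs)
  expect_equal(attr(mix_at_snr(ph, n0, assembly_params(snr_db = 0)),
                    "noise_gain"), 1, tolerance = 1e-9)
  # leading/trailing silence on the phoneme leaves the gain unchanged
  padded <- audio_signal(c(numeric(2000), ph$samples, numeric(2000)), fs)
  expect_equal(attr(mix_at_snr(padded, noise, pars), "noise_gain"), g,
               tolerance = 1e-12)
})

test_that("noise intervals have the published timing and SNR", {
  fs <- 16000
  corpus <- test_corpus()
  noise <- test_noise()
  ph <- corpus_token(corpus, "female", "s", 2)
  pars <- assembly_params()
  set.seed(31)
  iv <- assemble_noise_interval(ph, noise, longest_ms = 600, pars)
  # noise token = longest phoneme + 400 ms
  expect_identical(length(iv$samples), as.integer(round(1.000 * fs)))
  comp <- attr(iv, "components")
  # phoneme placed exactly 200 ms after noise onset
  delay <- round(0.200 * fs)
  expect_equal(comp$phoneme[(delay + 1):(delay + length(ph$samples))],
               ph$samples, tolerance = 1e-12)
  expect_true(all(comp$phoneme[1:delay] == 0))
  # at least 200 ms of noise persists after the phoneme ends
  expect_gte(length(iv$samples) - (delay + length(ph$samples)),
             round(0.2 * fs))
  # re-measured SNR equals the request to within 0.01 dB
  expect_equal(measure_interval_snr(comp$phoneme, comp$noise),
               pars$snr_db, tolerance = 0.01)
  # interval is the sum of its components
  expect_equal(iv$samples, comp$phoneme + comp$noise, tolerance = 1e-12)
  # a phoneme longer than longest_ms is rejected
  expect_error(assemble_noise_interval(ph, noise, longest_ms = 10, pars),
               "shorter")
})

test_that("three intervals of a trial draw distinct noise excisions deterministically", {
  corpus <- test_corpus()
  noise <- test_noise()
  ph <- corpus_token(corpus, "male", "m", 1)
  set.seed(55)
  starts1 <- replicate(3, attr(assemble_noise_interval(ph, noise, 500),
                               "noise_start"))
  set.seed(55)
  starts2 <- replicate(3, attr(assemble_noise_interval(ph, noise, 500),
                               "noise_start"))
  expect_identical(starts1, starts2)
  expect_identical(length(unique(starts1)), 3L)
})
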