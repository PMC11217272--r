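test_that("zero envelopes synthesise to silence and cannot be calibrated", {
  cfg <- vocoder_config()
  env <- band_envelopes(matrix(0, 8, 1000), 16000)
  stim <- synthesize_tactile(env, cfg)
  expect_true(all(stim$waveform == 0))
  expect_error(scale_and_rove(stim, cfg), "zero")
})

test_that("a single constant-envelope band gives a pure carrier at its gain", {
  cfg <- vocoder_config()
  fs <- cfg$audio_rate_hz
  n <- fs  # 1 s
  env_m <- matrix(0, 8, n)
  env_m[6, ] <- 0.25  # band 6 carrier: 239 Hz at 0 dB gain
  stim <- synthesize_tactile(band_envelopes(env_m, fs), cfg)
  expect_equal(max(abs(stim$waveform)), 0.25, tolerance = 1e-6)
  P <- Mod(stats::fft(stim$waveform))^2
  f_peak <- (which.max(P[1:(n / 2)]) - 1) * fs / n
  expect_equal(f_peak, 239)
  # two active bands -> spectral power confined to two lines (allowing for
  # the finite-window leakage of the non-bin-centred 116.5 Hz carrier)
  env_m[2, ] <- 0.1
  stim2 <- synthesize_tactile(band_envelopes(env_m, fs), cfg)
  P2 <- Mod(stats::fft(stim2$waveform * signal::hanning(n)))^2
  P2 <- P2[1:(n / 2)]
  f2 <- (seq_along(P2) - 1) * fs / n
  near_lines <- abs(f2 - 116.5) <= 3 | abs(f2 - 239) <= 3
  expect_gt(sum(P2[near_lines]) / sum(P2), 0.999)
})

test_that("synthesis is linear in the envelopes", {
  cfg <- vocoder_config()
  set.seed(3)
  a <- matrix(abs(stats::rnorm(8 * 2000, sd = 0.1)), 8)
  b <- matrix(abs(stats::rnorm(8 * 2000, sd = 0.1)), 8)
  sa <- synthesize_tactile(band_envelopes(a, 16000), cfg)
  sb <- synthesize_tactile(band_envelopes(b, 16000), cfg)
  sab <- synthesize_tactile(band_envelopes(a + b, 16000), cfg)
  expect_equal(sab$waveform, sa$waveform + sb$waveform, tolerance = 1e-12)
  # waveform equals the sum of the retained per-band components
  expect_equal(sa$waveform, colSums(sa$per_band), tolerance = 1e-12)
})

test_that("calibration reaches the nominal acceleration level", {
  cfg <- vocoder_config()
  env <- band_envelopes(matrix(0.1, 8, 4000), 16000)
  stim <- scale_and_rove(synthesize_tactile(env, cfg), cfg)
  expect_equal(signal_rms(stim$waveform), 1e-6 * 10^(141.5 / 20),
               tolerance = 1e-6)
  expect_equal(tactile_level_db(stim), 141.5, tolerance = 1e-9)
  expect_identical(stim$applied_rove_db, 0)
  # per-band components are rescaled consistently
  expect_equal(stim$waveform, colSums(stim$per_band), tolerance = 1e-9)
})

test_that("the level rove is uniform within +/-3 dB around the nominal level", {
  cfg <- vocoder_config()
  env <- band_envelopes(matrix(0.1, 8, 500), 16000)
  base <- synthesize_tactile(env, cfg)
  set.seed(123)
  roves <- replicate(2000, {
    scale_and_rove(base, cfg, rove_enabled = TRUE)$applied_rove_db
  })
  expect_true(all(abs(roves) <= 3))
  expect_equal(mean(roves), 0, tolerance = 3 * 6 / sqrt(12 * 2000))
  lev <- tactile_level_db(scale_and_rove(base, cfg, rove_enabled = TRUE))
  expect_gte(lev, 138.5); expect_lte(lev, 144.5)
  # determinism of the rove draw
  set.seed(77)
  r1 <- scale_and_rove(base, cfg, TRUE)$applied_rove_db
  set.seed(77)
  r2 <- scale_and_rove(base, cfg, TRUE)$applied_rove_db
  expect_identical(r1, r2)
})

test_that("output power stays confined near the carriers for slow envelopes", {
  cfg <- vocoder_config()
  corpus <- test_corpus()
  tok <- corpus_token(corpus, "male", "\u0251\u02d0", 1)
  stim <- vocode(tok, cfg, expansion_on = FALSE)
  n <- length(stim$waveform)
  P <- Mod(stats::fft(stim$waveform))^2
  f <- (0:(n - 1)) * cfg$audio_rate_hz / n
  half <- f <= cfg$audio_rate_hz / 2
  inside <- rep(FALSE, n)
  for (fc in cfg$carrier_freqs_hz) inside <- inside | abs(f - fc) <= 30
  frac_out <- sum(P[half & !inside]) / sum(P[half])
  expect_lt(frac_out, 0.01)
})
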