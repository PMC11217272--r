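test_that("WAV files round-trip in float and PCM form", {
  set.seed(6)
  x <- audio_signal(stats::rnorm(5000, sd = 0.1), 16000)
  f <- tempfile(fileext = ".wav")
  write_wav(x, f)
  y <- read_wav(f)
  expect_equal(y$rate_hz, 16000)
  expect_equal(y$samples, x$samples, tolerance = 1e-6)
  write_wav(x, f, format = "pcm16")
  y16 <- read_wav(f)
  expect_equal(y16$samples, x$samples, tolerance = 1e-4)
  # multichannel
  m <- cbind(x$samples, -x$samples)
  write_wav(m, f, rate_hz = 16000)
  ch2 <- read_wav(f, channel = 2)
  expect_equal(ch2$samples, -x$samples, tolerance = 1e-6)
  unlink(f)
})

test_that("configurations round-trip through JSON", {
  cfg <- vocoder_config(rove_halfwidth_db = 2.5,
                        expansion = expansion_params(slope_db_per_octave = 4))
  f <- tempfile(fileext = ".json")
  write_config(cfg, f, assembly = assembly_params(snr_db = 7))
  back <- read_config(f)
  expect_equal(unclass(back$vocoder)[names(unclass(cfg))], unclass(cfg),
               ignore_attr = TRUE)
  expect_equal(back$assembly$snr_db, 7)
  expect_identical(config_hash(back$vocoder), config_hash(cfg))
  unlink(f)
})

test_that("vocode_file writes a calibrated stimulus with sidecar metadata", {
  corpus <- test_corpus()
  tok <- corpus_token(corpus, "male", "z", 1)
  in_wav <- tempfile(fileext = ".wav")
  out_wav <- tempfile(fileext = ".wav")
  pb_wav <- tempfile(fileext = ".wav")
  write_wav(tok, in_wav)
  meta <- vocode_file(in_wav, out_wav, expansion_on = TRUE,
                      per_band_wav = pb_wav, seed = 1)
  expect_equal(meta$rms_level_db_re_1uMs2, 141.5, tolerance = 1e-6)
  expect_identical(meta$applied_rove_db, 0)
  stim <- read_wav(out_wav)
  expect_equal(signal_rms(stim$samples) * meta$unit_scale_ms2_per_fs,
               1e-6 * 10^(141.5 / 20), tolerance = 1e-3)
  sidecar <- jsonlite::read_json(paste0(out_wav, ".json"))
  expect_identical(sidecar$config_hash, config_hash(vocoder_config()))
  # expansion changes the output for a non-constant envelope
  out2 <- tempfile(fileext = ".wav")
  vocode_file(in_wav, out2, expansion_on = FALSE)
  expect_false(isTRUE(all.equal(read_wav(out2)$samples, stim$samples)))
  # silence input fails at calibration
  sil <- tempfile(fileext = ".wav")
  write_wav(numeric(4000), sil, rate_hz = 16000)
  expect_error(vocode_file(sil, out_wav), "zero")
  unlink(c(in_wav, out_wav, pb_wav, out2, sil,
           paste0(c(out_wav, out2), ".json")))
})

test_that("vocoding is bit-identical under a fixed seed", {
  corpus <- test_corpus()
  tok <- corpus_token(corpus, "female", "e", 3)
  set.seed(33)
  s1 <- vocode(tok, expansion_on = TRUE, rove_enabled = TRUE)
  set.seed(33)
  s2 <- vocode(tok, expansion_on = TRUE, rove_enabled = TRUE)
  expect_identical(s1$waveform, s2$waveform)
  expect_identical(s1$applied_rove_db, s2$applied_rove_db)
})

test_that("every pair can be duration-matched and a sample renders end-to-end", {
  corpus <- test_corpus()
  noise <- test_noise()
  pairs <- phoneme_pairs()
  for (i in seq_len(nrow(pairs))) {
    a <- corpus_token(corpus, "male", pairs$phoneme_a[i], 1)
    b <- corpus_token(corpus, "male", pairs$phoneme_b[i], 1)
    md <- match_durations(a, b, pairs$phoneme_a[i], pairs$phoneme_b[i])
    expect_true(is.list(md))
  }
  # stratified sample of pairs rendered through the full trial chain
  tr <- generate_trial_list(seed = 17)
  pick <- c(which(tr$noise & tr$phoneme_type == "vowel")[1],
            which(tr$noise & tr$contrast_type == "voicing")[1],
            which(!tr$noise & tr$contrast_type == "diphthong")[1],
            which(!tr$noise & tr$contrast_type == "place-voiceless-plosive")[1])
  for (j in pick) {
    set.seed(j)
    rt <- render_trial(tr[j, ], corpus, noise)
    expect_length(rt$intervals, 3L)
    for (k in 1:3) {
      lev <- tactile_level_db(rt$intervals[[k]])
      expect_equal(lev, 141.5 + tr[j, paste0("rove_db_", k)],
                   tolerance = 1e-6)
    }
  }
})

test_that("spectrograms have the documented orientation and degenerate forms", {
  cfg <- vocoder_config()
  # constant single band -> one bright horizontal row
  env_m <- matrix(0, 8, 2000)
  env_m[5, ] <- 0.2
  sp <- render_tactile_spectrogram(band_envelopes(env_m, 16000))
  expect_identical(sp$style, "tactile")
  expect_true(all(sp$db[5, ] == 0))
  expect_true(all(sp$db[-5, ] == -80))
  # all-zero input -> uniform floor
  sp0 <- render_tactile_spectrogram(band_envelopes(matrix(0, 8, 100), 16000))
  expect_true(all(sp0$db == -80))
  # audio style: tone ridge at the tone frequency
  tone <- tone_audio(1000, dur_s = 0.2)
  spa <- render_tactile_spectrogram(tone, style = "audio")
  ridge <- spa$freq_hz[apply(spa$db, 2, which.max)]
  expect_lt(max(abs(ridge - 1000)), 100)
})
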