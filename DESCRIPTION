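Package: tactovoc
Title: Audio-to-Tactile Vocoder with Multi-Band Envelope Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts speech audio into calibrated vibro-tactile stimuli for
    haptic hearing research. Implements an eight-band tactile vocoder (an
    ERB-spaced FIR filter bank, Hilbert amplitude-envelope extraction, and
    amplitude modulation of fixed-phase vibro-tactile carrier tones), with
    optional multi-band dynamic-range expansion of the band envelopes to
    enhance formants and other high-intensity speech cues. Also provides
    speech-shaped masking-noise generation from a corpus long-term average
    speech spectrum, stimulus assembly for speech-in-noise testing (silence
    trimming, duration matching, SNR mixing, noise-interval timing), a
    three-alternative forced-choice phoneme-discrimination trial generator
    and scorer, and a synthetic two-talker formant-synthesis phoneme corpus
    so the full pipeline can be exercised without recorded speech.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
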