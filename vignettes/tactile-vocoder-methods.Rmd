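---
title: "Methods: the tactile vocoder, envelope expansion, and the synthetic test bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tactile vocoder, envelope expansion, and the synthetic test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactovoc)
```

## The processing model

`tactovoc` converts speech audio into a vibro-tactile acceleration waveform
intended for a single stimulation site (typically the dorsal wrist). The
chain implemented by `vocode()` is:

1. **Active-level normalisation.** The input's active speech level is
   measured in the manner of ITU-T P.56 method B (a 30-ms smoothed
   envelope compared against a threshold ladder with a 200-ms hangover and
   a 15.9-dB margin) and the waveform is rescaled — a pure gain — to a
   target active level (−26 dB re full scale by default). Levelling on the
   *active* level rather than the overall RMS prevents tokens with long
   pauses from being over-amplified. Normalisation is applied per token.
2. **Resampling to 16 kHz**, the rate available on compact real-time
   devices, using a polyphase anti-aliased resampler.
3. **ERB-spaced analysis filter bank.** Nine band edges are equally spaced
   on the ERB-number scale, $\mathrm{ERB_n}(f) = 21.4\,\log_{10}(0.00437 f
   + 1)$, between 50 and 7000 Hz, giving eight bands. We interpret "equally
   spaced on the ERB scale" as equally spaced *band edges* (not centres)
   because the 50 and 7000 Hz limits are stated as range endpoints. Each
   band is a 512th-order linear-phase FIR band-pass (windowed-sinc with a
   Hamming window), whose −6 dB points fall on the band edges so adjacent
   bands cross over at their shared edge. Band outputs are group-delay
   compensated so they stay time-aligned with the input.
4. **Envelope extraction.** Per band, the magnitude of the analytic signal
   (Hilbert transform via the FFT) is smoothed by a 6th-order Butterworth
   low-pass with a 23 Hz corner, applied forward–backward. "Zero-phase"
   filtering necessarily applies the magnitude response twice; the
   effective magnitude is the squared 6th-order response, and the tests
   account for this. Small negative excursions from filtering are clamped
   to zero.
5. **Multi-band envelope expansion** (optional; see below).
6. **Carrier synthesis.** Band $i$'s envelope modulates a fixed-phase
   sinusoid at 94.5, 116.5, 141.5, 170, 202.5, 239, 280.5 or 327.5 Hz with
   a fixed gain of 13.8, 12.1, 9.9, 6.4, 1.6, 0, 1.7 or 4 dB respectively;
   the gains compensate for vibro-tactile sensitivity differences across
   frequency. Carrier phase is zero at stimulus onset ("fixed phase" is
   otherwise unconstrained; a deterministic phase keeps runs bit-identical).
7. **Calibration and rove.** The summed waveform is scaled to an RMS
   acceleration of 141.5 dB re $10^{-6}\,$m/s² (≈ 11.885 m/s², about
   1.2 G). With roving enabled a per-stimulus offset drawn uniformly from
   ±3 dB is added so absolute intensity carries no stimulus information.

Because every stimulus is rescaled to the nominal RMS at the end of the
chain, the gain reduction that conventionally follows expansion is realised
implicitly by this calibration stage rather than as a separate block.

## The expander

Expansion is applied independently per band to the amplitude envelope.
With levels in dB, the static curve is

$$L_\text{out} = \begin{cases} L_\text{in} & L_\text{in} \le T \\
T + r\,(L_\text{in} - T) & L_\text{in} > T\end{cases},
\qquad r = 1 + \frac{s}{20\log_{10}2},$$

where the slope $s = 5$ dB/octave and the threshold $T$ sits 5 dB below
the RMS level of that band's whole envelope. One octave of level is
$20\log_{10}2 \approx 6.0206$ dB, so each octave of input above threshold
gains an extra 5 dB, giving $r \approx 1.830$. We read "a slope of 5 dB
per octave" as *additional output level per octave of input level above
threshold*: the alternative reading (output rising only 5 dB per input
octave, $r < 1$) would be compression, contradicting the expander's
purpose, and a per-octave-of-*frequency* reading has no meaning for a
scalar level mapping.

The gain (in dB) implied by the static curve is smoothed by a one-pole
ballistic: the 10-ms attack constant applies while the target gain is
rising and the 100-ms release constant while it is falling, so envelope
onsets are expanded quickly and decays released slowly. We smooth the
*gain*, not the envelope itself, which keeps the identity region exactly
transparent. The threshold is computed from the entire utterance envelope
(offline per-stimulus preparation); an all-zero band, whose RMS level is
undefined in dB, passes through unchanged. Two useful consequences checked
by the property tests: the expander is scale-invariant (rescaling the
input envelope rescales the output, because the threshold tracks the RMS),
and with expansion disabled the stage is the identity.

## Speech-shaped noise

The masker is built from the corpus itself: short-time Fourier magnitudes
(4096-sample windows) are averaged over all non-silent frames of all
tokens to form the long-term average speech spectrum (LTASS). The window
shape and hop are not critical; we use a Hann window with 50% overlap. A
frame is "silent" when its RMS falls below 10% of the token's peak frame
RMS, reusing the 10% convention of the endpoint definition for internal
consistency. A 2049-tap linear-phase FIR filter is then least-squares
fitted to the LTASS magnitude on the bin grid — for a uniform DFT grid the
optimum is simply the centred, truncated inverse DFT of the target
magnitude, so the fit is exact up to truncation and its residual is
non-increasing in tap count — and white Gaussian noise (the distribution
is unstated upstream; Gaussian is the standard choice) is filtered through
it, with group-delay compensation.

## Stimulus assembly

For speech-in-noise intervals, the SNR is defined on *audio* before
vocoding (the vocoder then processes the mixture): silence-trimmed phoneme
RMS minus noise-token RMS. The trimming endpoints are the first and last
samples whose absolute amplitude reaches 10% of the token maximum; the
noise token is not trimmed (it has no silences) and its RMS is measured on
the ramped token as assembled, so a re-measurement on the assembled
components returns the requested SNR exactly. The noise token outlasts
the longest phoneme of the trial by 400 ms, is excised from the long
masker at a random (or schedule-supplied) start point — a different token
per interval, so noise cues cannot identify the target — and carries 50-ms
raised-cosine on/off ramps; the phoneme starts 200 ms after noise onset,
leaving at least 200 ms of noise after it ends. The default SNR is 5 dB.

Duration matching fades both members of a pair with a 20-ms raised-cosine
ramp that reaches zero at the shorter token's 1%-amplitude end point; the
ramp is aligned to *end* at that point (the published constraint fixes
only the endpoint). Pairs containing a diphthong or /g, d, l, r, v, w, j/
are exempt. Raised-cosine ramps are half-Hann windows throughout.

## The discrimination experiment

The pair inventory holds 45 pairs (27 consonant in nine contrast
subgroups of three; 12 monophthong and 6 diphthong vowel pairs). A
schedule crosses 4 conditions (noise × expansion) with every pair and two
talkers, twice, giving 720 trials; order is randomised within each repeat,
matching the published procedure of testing all pairs and conditions per
repeat in sequence. Per trial the generator draws the odd phoneme, the
odd interval's position (uniform over three), one token per phoneme (the
two same-phoneme intervals share a token, as one token is selected per
phoneme per trial), per-interval roves, and per-interval noise offsets;
the interval-order and odd-position draws are independent. Scoring
aggregates percent correct by condition, talker, phoneme type and
contrast subgroup and is order-invariant; inferential statistics are left
to general-purpose tools, and the scorer exports plain long-format tables
for that purpose.

## The synthetic corpus

The synthetic corpus exists so the whole pipeline can be exercised and
tested without recorded speech. It emulates the structural properties of
a two-talker phoneme corpus: a "male" talker at a mean f0 of 145.4 Hz and
a "female" at 208.2 Hz, four tokens per phoneme with jitter in f0
(0.5% sd), duration (5%) and formant targets (2%), covering every phoneme
in the pair inventory. Voiced sounds are Klatt-style cascade formant
synthesis: an impulse train with −12 dB/oct glottal rolloff and +6 dB/oct
radiation characteristic drives three time-varying second-order
resonators; monophthong targets follow standard Southern British English
formant surveys, with a fixed 1.18 vocal-tract scale factor for the
female talker; diphthongs and semivowels interpolate between vowel
targets. Voiceless fricatives are band-shaped noise by place of
articulation; voiced fricatives add a voicing murmur and f0-rate
amplitude modulation; plosives are closure (+ low-frequency voicing bar
when voiced) + band-limited burst + aspiration or a short vocalic
release.

What it does *not* emulate: coarticulation, natural token variability
beyond parameter jitter, breathiness/aspiration detail, nasal zeros, or
anything about perceptual naturalness. Passing tests therefore show that
the *processing* behaves as specified on signals with speech-like
structure (periodicity, formant peaks and glides, frication bands,
closures), not that the stimuli are perceptually equivalent to recorded
speech. Published human discrimination scores are psychophysical results
and are out of scope for computational reproduction.

## Numerical choices and problem sizes

* Filter-bank responses are measured on a 65536-point FFT grid; band
  signals are delay-compensated by half the filter order.
* The envelope low-pass is run with `signal::filtfilt`; its edge
  transients motivate measuring steady-state values away from token
  boundaries in the tests.
* The P.56 ladder uses 0.5-dB threshold steps over 100 dB below the
  envelope peak, with linear interpolation at the margin crossing; the
  measurement falls back to the overall RMS level (with a warning) only
  for degenerate inputs whose activity never reaches the margin.
* f0 estimation uses the FFT autocorrelation with parabolic interpolation
  around the peak, searched between 70 and 350 Hz.
* Tests use token-length signals (0.2–1 s), a 20-s masker, and 30-s noise
  realisations for spectrum checks — sizes chosen so the statistical
  tolerances (e.g. third-octave spectrum agreement within 1 dB) are
  comfortably resolvable while the whole suite runs in seconds.
* Determinism: every stochastic step (jitter, noise draw, excision
  points, roves, schedule shuffles) consumes the R RNG stream, so a
  single `set.seed()` makes any pipeline run bit-identical.

## Known limitations

* The expander's per-stimulus threshold means the same audio embedded in
  different trials can receive slightly different expansion if its band
  RMS differs after assembly; this mirrors offline per-stimulus
  preparation rather than a streaming device implementation.
* The P.56 implementation follows the method's structure (envelope,
  hangover, margin) but is not a certified reference; for stationary
  tones it agrees with the RMS level to within 0.15 dB.
* WAV support covers PCM 16/24-bit and float32 mono/multichannel, which
  is sufficient for the pipeline's own outputs.
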