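# Synthetic two-talker phoneme corpus via source-filter (Klatt-style
# cascade) formant synthesis. Naturalness is not a goal: tokens only need
# the acoustic structure the vocoder pipeline responds to (f0 periodicity,
# formant peaks and glides, frication bands, closures and bursts).

CORPUS_RATE <- 16000
TALKER_F0 <- c(male = 145.4, female = 208.2)

# Canonical monophthong formant targets (F1, F2, F3 in Hz) for an adult
# male southern-British speaker; broadly after published SSBE vowel formant
# surveys (Deterding 1997, J. Int. Phon. Assoc.; Wells 1962). Female tracks
# use a fixed vocal-tract scale factor below.
VOWEL_FORMANTS <- list(
  "i\u02d0"       = c(280, 2250, 2890),
  "\u026a"        = c(360, 2100, 2700),
  "e"             = c(500, 1970, 2600),
  "\u00e6"        = c(700, 1550, 2500),
  "\u028c"        = c(640, 1200, 2400),
  "\u0251\u02d0"  = c(640, 1100, 2500),
  "\u0252"        = c(560, 920, 2500),
  "\u0254\u02d0"  = c(480, 760, 2500),
  "\u028a"        = c(380, 940, 2300),
  "u\u02d0"       = c(320, 920, 2200),
  "\u0259"        = c(500, 1400, 2500)   # schwa, used in glides
)
FEMALE_FORMANT_SCALE <- 1.18

# Diphthongs as start -> end monophthong targets.
DIPHTHONG_TARGETS <- list(
  "e\u026a"       = c("e", "\u026a"),
  "a\u028a"       = c("\u0251\u02d0", "\u028a"),
  "\u0254\u026a"  = c("\u0254\u02d0", "\u026a"),
  "\u026a\u0259"  = c("\u026a", "\u0259"),
  "\u0259\u028a"  = c("\u0259", "\u028a"),
  "\u028a\u0259"  = c("\u028a", "\u0259"),
  "e\u0259"       = c("e", "\u0259")
)

# Sonorant consonant formant targets (static), plus glide endpoints for the
# semivowels.
SONORANT_FORMANTS <- list(
  m = c(250, 1000, 2200),
  n = c(250, 1500, 2400),
  l = c(360, 1300, 2700),
  r = c(310, 1060, 1380)   # low F3 signals rhoticity
)
GLIDE_TARGETS <- list(
  j = c("i\u02d0", "\u0259"),
  w = c("u\u02d0", "\u0259")
)

# Frication bands (Hz) by place, and burst bands for plosives.
FRICATION_BANDS <- list(
  f              = c(1200, 7000),
  "\u03b8"       = c(1400, 7000),
  s              = c(4000, 7500),
  "\u0283"       = c(2000, 5000),
  v              = c(1200, 7000),
  "\u00f0"       = c(1400, 7000),
  z              = c(4000, 7500),
  "\u0292"       = c(2000, 5000)
)
BURST_BANDS <- list(
  p = c(400, 1500), b = c(400, 1500),
  t = c(2500, 4500), d = c(2500, 4500),
  k = c(1200, 2500), g = c(1200, 2500)
)

#' Build the synthesis recipe for one phoneme token
#'
#' Produces a source-filter recipe \u2014 f0, formant tracks (piecewise linear),
#' source type, duration \u2014 for a phoneme spoken by one of the two synthetic
#' talkers (mean f0 145.4 Hz "male", 208.2 Hz "female"), with optional
#' per-token jitter scales.
#'
#' @param label IPA phoneme label (must appear in [phoneme_inventory()]).
#' @param talker `"male"` or `"female"`.
#' @param jitter List of per-token perturbation scales: `f0` (relative sd of
#'   the token's mean f0), `formant` (relative sd of formant targets),
#'   `duration` (relative sd of duration).
#' @return A `phoneme_spec` list.
#' @export
phoneme_spec <- function(label, talker = c("male", "female"),
                         jitter = list(f0 = 0.005, formant = 0.02,
                                       duration = 0.05)) {
  talker <- match.arg(talker)
  inv <- phoneme_inventory()
  row <- inv[inv$label == label, ]
  if (nrow(row) != 1) stop("unknown phoneme label: ", label)
  dur_ms <- switch(row$class,
    monophthong = 300, diphthong = 400, fricative = 250,
    plosive = 230, affricate = 230, sonorant = 250)
  structure(list(label = label, class = row$class, voiced = row$voiced,
                 talker = talker, f0_hz = unname(TALKER_F0[talker]),
                 duration_ms = dur_ms, jitter = jitter),
            class = "phoneme_spec")
}

formant_targets <- function(vowel, talker) {
  f <- VOWEL_FORMANTS[[vowel]]
  if (is.null(f)) stop("no formant targets for: ", vowel)
  if (talker == "female") f * FEMALE_FORMANT_SCALE else f
}

# Klatt-style digital resonator cascade with per-sample (time-varying)
# centre frequencies. `f_track` is n x length(bw); coefficients follow
# Klatt (1980): y[n] = A x[n] + B y[n-1] + C y[n-2], A = 1 - B - C.
resonator_cascade <- function(x, f_track, bw = c(90, 110, 170), fs) {
  n <- length(x)
  y <- x
  for (j in seq_along(bw)) {
    C <- -exp(-2 * pi * bw[j] / fs)
    B <- 2 * exp(-pi * bw[j] / fs) * cos(2 * pi * f_track[, j] / fs)
    A <- 1 - B - C
    out <- numeric(n)
    y1 <- 0; y2 <- 0
    for (i in seq_len(n)) {
      v <- A[i] * y[i] + B[i] * y1 + C * y2
      y2 <- y1; y1 <- v
      out[i] <- v
    }
    y <- out
  }
  y
}

# Glottal-like source: impulse train at f0 with -12 dB/oct glottal rolloff
# plus a +6 dB/oct radiation characteristic (first difference), giving the
# familiar net -6 dB/oct speech source tilt.
voiced_source <- function(n, f0, fs) {
  period <- fs / f0
  pulses <- round(seq(1, n, by = period))
  pulses <- pulses[pulses <= n]
  x <- numeric(n)
  x[pulses] <- 1
  a <- exp(-2 * pi * 100 / fs)
  x <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  x <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  c(0, diff(x)) * fs / (2 * pi * 1000)  # unity gain near 1 kHz
}

bandpass_noise <- function(n, band_hz, fs) {
  bf <- signal::butter(2, pmin(band_hz, fs / 2 - 100) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filter(bf, stats::rnorm(n)))
}

lowpass_noise_free <- function(x, corner_hz, fs) {
  bf <- signal::butter(2, corner_hz / (fs / 2))
  as.numeric(signal::filter(bf, x))
}

linear_track <- function(n, from, to) {
  vapply(seq_along(from), function(j) seq(from[j], to[j], length.out = n),
         numeric(n))
}

#' Synthesise one phoneme token
#'
#' Renders a [phoneme_spec()] to audio at 16 kHz. Voiced sounds use an
#' impulse-train source through a cascade of formant resonators; voiceless
#' fricatives are band-shaped noise; plosives are closure + burst (+
#' aspiration, or a short vocalic release when voiced); diphthongs and
#' semivowel glides interpolate formant targets over the token. Tokens are
#' peak-normalised to 0.5 and padded with 20 ms of silence at each end.
#'
#' Token-to-token variability comes from the spec's jitter scales applied to
#' f0, duration and formant targets; draws use the current RNG stream.
#'
#' @param spec A `phoneme_spec`.
#' @param rate_hz Output rate (Hz).
#' @return An `audio_signal`, with the realised f0 in attribute `"f0_hz"`
#'   for voiced tokens.
#' @export
synthesize_phoneme <- function(spec, rate_hz = CORPUS_RATE) {
  stopifnot(inherits(spec, "phoneme_spec"))
  fs <- rate_hz
  jit <- function(x, sd_rel) x * (1 + stats::rnorm(length(x), 0, sd_rel))
  f0 <- jit(spec$f0_hz, spec$jitter$f0)
  dur <- jit(spec$duration_ms, spec$jitter$duration) / 1000
  n <- round(dur * fs)
  lab <- spec$label
  talker <- spec$talker

  vowel_like <- function(n, f_from, f_to, bw = c(90, 110, 170)) {
    src <- voiced_source(n, f0, fs)
    resonator_cascade(src, linear_track(n, f_from, f_to), bw, fs)
  }

  x <- switch(spec$class,
    monophthong = {
      f <- jit(formant_targets(lab, talker), spec$jitter$formant)
      apply_raised_cosine(vowel_like(n, f, f), round(0.03 * fs))
    },
    diphthong = {
      tg <- DIPHTHONG_TARGETS[[lab]]
      f1 <- jit(formant_targets(tg[1], talker), spec$jitter$formant)
      f2 <- jit(formant_targets(tg[2], talker), spec$jitter$formant)
      apply_raised_cosine(vowel_like(n, f1, f2), round(0.03 * fs))
    },
    sonorant = {
      if (lab %in% names(GLIDE_TARGETS)) {
        tg <- GLIDE_TARGETS[[lab]]
        f1 <- jit(formant_targets(tg[1], talker), spec$jitter$formant)
        f2 <- jit(formant_targets(tg[2], talker), spec$jitter$formant)
        apply_raised_cosine(vowel_like(n, f1, f2), round(0.03 * fs))
      } else {
        f <- jit(SONORANT_FORMANTS[[lab]] *
                   if (talker == "female") FEMALE_FORMANT_SCALE else 1,
                 spec$jitter$formant)
        y <- vowel_like(n, f, f, bw = c(120, 200, 250))
        if (lab %in% c("m", "n")) y <- lowpass_noise_free(y, 1200, fs)
        apply_raised_cosine(y, round(0.03 * fs))
      }
    },
    fricative = {
      band <- jit(FRICATION_BANDS[[lab]], spec$jitter$formant)
      y <- bandpass_noise(n, band, fs)
      y <- apply_raised_cosine(y, round(0.04 * fs))
      if (spec$voiced) {
        # voicing bar plus f0-rate amplitude modulation of the frication
        murmur <- lowpass_noise_free(voiced_source(n, f0, fs), 400, fs)
        murmur <- murmur / max(abs(murmur)) * 0.6 * max(abs(y))
        t <- (seq_len(n) - 1) / fs
        y <- y * (0.6 + 0.4 * 0.5 * (1 + sin(2 * pi * f0 * t))) +
          apply_raised_cosine(murmur, round(0.03 * fs))
      }
      y
    },
    affricate = {
      n_clos <- round(0.05 * fs)
      n_fric <- n - n_clos
      fric <- bandpass_noise(n_fric, FRICATION_BANDS[["\u0283"]], fs)
      fric <- fric * exp(-(seq_len(n_fric) - 1) / (0.12 * fs))
      c(numeric(n_clos), apply_raised_cosine(fric, round(0.002 * fs),
                                             round(0.03 * fs)))
    },
    plosive = {
      n_clos <- round(0.06 * fs)
      n_burst <- round(0.015 * fs)
      closure <- if (spec$voiced) {
        vb <- lowpass_noise_free(voiced_source(n_clos, f0, fs), 250, fs)
        vb / max(abs(vb)) * 0.08
      } else numeric(n_clos)
      burst <- bandpass_noise(n_burst, BURST_BANDS[[lab]], fs)
      burst <- burst * exp(-(seq_len(n_burst) - 1) / (0.004 * fs))
      tail_n <- n - n_clos - n_burst
      tail <- if (spec$voiced) {
        f <- jit(VOWEL_FORMANTS[["\u0259"]] *
                   if (talker == "female") FEMALE_FORMANT_SCALE else 1,
                 spec$jitter$formant)
        apply_raised_cosine(vowel_like(tail_n, f, f), round(0.005 * fs),
                            round(0.04 * fs))
      } else {
        asp <- bandpass_noise(tail_n, c(500, 6000), fs) *
          exp(-(seq_len(tail_n) - 1) / (0.025 * fs))
        asp * 0.4
      }
      burst <- burst / max(abs(burst))
      tail <- tail / max(abs(tail)) * if (spec$voiced) 0.9 else 0.35
      c(closure, burst, tail)
    },
    stop("unknown phoneme class: ", spec$class)
  )

  pad <- numeric(round(0.02 * fs))
  x <- c(pad, x / max(abs(x)) * 0.5, pad)
  out <- audio_signal(x, fs)
  if (spec$voiced) attr(out, "f0_hz") <- f0
  out
}

#' Build the synthetic two-talker corpus
#'
#' Synthesises `tokens_per_phoneme` distinct tokens of every phoneme in the
#' pair inventory for both talkers, with token-to-token jitter in f0,
#' duration and formant targets.
#'
#' @param seed Integer seed for reproducibility.
#' @param tokens_per_phoneme Tokens per (talker, phoneme).
#' @param labels Phoneme labels to include (default: full inventory).
#' @return A `synthetic_corpus`: nested list `tokens[[talker]][[label]][[k]]`
#'   of `audio_signal`s, plus `rate_hz`, `talkers`, `labels`.
#' @export
#' @examples
#' \donttest{
#' corpus <- build_synthetic_corpus(seed = 1, tokens_per_phoneme = 1,
#'                                  labels = c("s", "z"))
#' }
build_synthetic_corpus <- function(seed = NULL, tokens_per_phoneme = 4,
                                   labels = phoneme_inventory()$label) {
  if (!is.null(seed)) set.seed(seed)
  talkers <- names(TALKER_F0)
  tokens <- lapply(talkers, function(tk) {
    per_label <- lapply(labels, function(lab) {
      spec <- phoneme_spec(lab, tk)
      lapply(seq_len(tokens_per_phoneme), function(k) {
        synthesize_phoneme(spec)
      })
    })
    names(per_label) <- labels
    per_label
  })
  names(tokens) <- talkers
  structure(list(tokens = tokens, rate_hz = CORPUS_RATE,
                 talkers = talkers, labels = labels,
                 tokens_per_phoneme = tokens_per_phoneme),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d talkers x %d phonemes x %d tokens @ %g Hz\n",
              length(x$talkers), length(x$labels), x$tokens_per_phoneme,
              x$rate_hz))
  invisible(x)
}

#' Fetch one corpus token
#'
#' @param corpus A `synthetic_corpus`.
#' @param talker Talker label.
#' @param label Phoneme label.
#' @param token Token index.
#' @return An `audio_signal`.
#' @export
corpus_token <- function(corpus, talker, label, token = 1L) {
  tok <- corpus$tokens[[talker]][[label]][[token]]
  if (is.null(tok)) {
    stop("no token for talker=", talker, " label=", label, " k=", token)
  }
  tok
}

#' Flatten a corpus to a token list
#'
#' @param corpus A `synthetic_corpus`.
#' @param talkers Talkers to include.
#' @return Unnamed list of `audio_signal` tokens, e.g. for
#'   [estimate_ltass()].
#' @export
corpus_tokens_flat <- function(corpus, talkers = corpus$talkers) {
  unlist(lapply(talkers, function(tk) {
    unlist(corpus$tokens[[tk]], recursive = FALSE, use.names = FALSE)
  }), recursive = FALSE, use.names = FALSE)
}

#' Estimate fundamental frequency by autocorrelation
#'
#' Autocorrelation peak search over the plausible pitch-lag range with
#' parabolic interpolation around the peak for sub-sample precision.
#'
#' @param audio An `audio_signal`.
#' @param f_min_hz,f_max_hz Pitch search range (Hz).
#' @return Estimated f0 in Hz.
#' @export
estimate_f0 <- function(audio, f_min_hz = 70, f_max_hz = 350) {
  audio <- as_audio(audio)
  x <- audio$samples - mean(audio$samples)
  fs <- audio$rate_hz
  nfft <- 2^ceiling(log2(2 * length(x)))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:length(x)]
  lag_min <- floor(fs / f_max_hz)
  lag_max <- min(ceiling(fs / f_min_hz), length(r) - 1L)
  seg <- r[(lag_min + 1L):(lag_max + 1L)]
  k <- which.max(seg)
  lag <- lag_min + k - 1L
  # parabolic interpolation around the discrete peak
  if (lag > lag_min && lag < lag_max) {
    y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 0) lag <- lag + 0.5 * (y1 - y3) / denom
  }
  fs / lag
}
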