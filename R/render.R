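# Rendering a complete 3AFC trial: token selection, duration matching,
# noise-interval assembly, vocoding, and per-interval level roving.

#' Render the three observation intervals of one trial
#'
#' Applies the full stimulus chain to one row of a trial schedule: fetches
#' the scheduled corpus tokens, duration-matches the pair (unless exempt),
#' optionally embeds each interval's phoneme in a fresh speech-shaped noise
#' token at the experiment SNR, vocodes each interval (with expansion when
#' the condition says so), and roves each interval's level by the
#' scheduled amount.
#'
#' @param trial One-row data frame from [generate_trial_list()].
#' @param corpus A `synthetic_corpus` (or compatible token store).
#' @param noise_src Long speech-shaped noise `audio_signal` (needed for
#'   noise conditions).
#' @param config A [vocoder_config()].
#' @param params An [assembly_params()].
#' @param bank Optional pre-designed filter bank.
#' @return List with `intervals` (three [tactile_stimulus()]s),
#'   `correct_interval`, and `gap_ms` between intervals.
#' @export
render_trial <- function(trial, corpus, noise_src = NULL,
                         config = vocoder_config(),
                         params = assembly_params(), bank = NULL) {
  stopifnot(nrow(trial) == 1)
  if (is.null(bank)) bank <- design_erb_filterbank(config)
  tok_odd <- corpus_token(corpus, trial$talker, trial$odd_phoneme,
                          trial$token_odd)
  tok_std <- corpus_token(corpus, trial$talker, trial$std_phoneme,
                          trial$token_std)
  matched <- match_durations(tok_odd, tok_std, trial$odd_phoneme,
                             trial$std_phoneme, params)
  tok_odd <- matched$a
  tok_std <- matched$b

  longest_ms <- 1000 * max(length(tok_odd$samples),
                           length(tok_std$samples)) / tok_odd$rate_hz
  intervals <- vector("list", 3L)
  for (k in 1:3) {
    tok <- if (k == trial$odd_interval) tok_odd else tok_std
    sig <- if (isTRUE(trial$noise)) {
      if (is.null(noise_src)) stop("noise_src required for noise conditions")
      assemble_noise_interval(tok, noise_src, longest_ms, params,
                              start_frac = trial[[paste0("noise_frac_", k)]])
    } else tok
    stim <- vocode(sig, config, expansion_on = isTRUE(trial$expansion),
                   rove_enabled = FALSE, bank = bank)
    # apply the scheduled rove for this interval
    rove <- trial[[paste0("rove_db_", k)]]
    k_lin <- db_to_amp(rove)
    stim$waveform <- stim$waveform * k_lin
    if (!is.null(stim$per_band)) stim$per_band <- stim$per_band * k_lin
    stim$applied_rove_db <- rove
    intervals[[k]] <- stim
  }
  list(intervals = intervals, correct_interval = trial$correct_interval,
       gap_ms = params$interval_gap_ms)
}
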