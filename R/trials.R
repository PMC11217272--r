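# 3AFC trial schedule generation and scoring.
#
# Schedule structure: 4 conditions (noise on/off x expansion on/off) x 45
# pairs x 2 talkers, the whole block repeated twice with trial order
# re-randomised within each repeat -> 720 trials per participant.

CONDITIONS <- data.frame(
  condition = 1:4,
  noise = c(FALSE, FALSE, TRUE, TRUE),
  expansion = c(FALSE, TRUE, FALSE, TRUE)
)

#' Generate a 3AFC phoneme-discrimination trial schedule
#'
#' For each repeat, every combination of condition, phoneme pair, and talker
#' occurs exactly once, with trial order randomised within the repeat. Per
#' trial the generator draws: which phoneme of the pair is the odd one out,
#' the position (1-3) of the odd interval, one corpus token index (1-4) per
#' phoneme, a level rove per interval, and a noise-excision offset fraction
#' per interval (used only in noise conditions).
#'
#' @param pairs Pair inventory (default [phoneme_pairs()]).
#' @param talkers Talker labels.
#' @param repeats Number of full repeats of the condition x pair x talker
#'   block.
#' @param rove_halfwidth_db Level-rove half-width (dB) recorded per interval.
#' @param tokens_per_phoneme Number of corpus tokens per phoneme.
#' @param seed Optional integer seed.
#' @return A data frame of trial records, one row per trial, with columns
#'   `trial`, `repeat_block`, `condition`, `noise`, `expansion`, `talker`,
#'   pair descriptors, `odd_phoneme`, `std_phoneme`, `odd_interval`,
#'   `token_odd`, `token_std`, `rove_db_1..3`, `noise_frac_1..3`, and
#'   `correct_interval`.
#' @export
#' @examples
#' trials <- generate_trial_list(seed = 1)
#' nrow(trials)            # 720
#' table(trials$condition) # 180 each
generate_trial_list <- function(pairs = phoneme_pairs(),
                                talkers = c("male", "female"),
                                repeats = 2,
                                rove_halfwidth_db = 3,
                                tokens_per_phoneme = 4,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    grid <- expand.grid(condition = CONDITIONS$condition,
                        pair_id = pairs$pair_id,
                        talker = talkers,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    grid$repeat_block <- r
    blocks[[r]] <- grid
  }
  sched <- do.call(rbind, blocks)
  n <- nrow(sched)
  cond_row <- match(sched$condition, CONDITIONS$condition)
  sched$noise <- CONDITIONS$noise[cond_row]
  sched$expansion <- CONDITIONS$expansion[cond_row]
  pair_row <- match(sched$pair_id, pairs$pair_id)
  for (col in c("phoneme_a", "phoneme_b", "phoneme_type", "contrast_type")) {
    sched[[col]] <- pairs[[col]][pair_row]
  }

  odd_is_a <- sample(c(TRUE, FALSE), n, replace = TRUE)
  sched$odd_phoneme <- ifelse(odd_is_a, sched$phoneme_a, sched$phoneme_b)
  sched$std_phoneme <- ifelse(odd_is_a, sched$phoneme_b, sched$phoneme_a)
  sched$odd_interval <- sample.int(3L, n, replace = TRUE)
  sched$token_odd <- sample.int(tokens_per_phoneme, n, replace = TRUE)
  sched$token_std <- sample.int(tokens_per_phoneme, n, replace = TRUE)
  for (k in 1:3) {
    sched[[paste0("rove_db_", k)]] <-
      stats::runif(n, -rove_halfwidth_db, rove_halfwidth_db)
    sched[[paste0("noise_frac_", k)]] <- stats::runif(n)
  }
  sched$correct_interval <- sched$odd_interval
  sched$trial <- seq_len(n)
  rownames(sched) <- NULL
  sched[, c("trial", "repeat_block", "condition", "noise", "expansion",
            "talker", "pair_id", "phoneme_a", "phoneme_b", "phoneme_type",
            "contrast_type", "odd_phoneme", "std_phoneme", "odd_interval",
            "token_odd", "token_std",
            paste0("rove_db_", 1:3), paste0("noise_frac_", 1:3),
            "correct_interval")]
}

#' Score 3AFC responses
#'
#' A response is correct when it names the odd interval. Percent correct is
#' aggregated by condition x talker x phoneme type and by condition x
#' contrast type (the subgroup layout of the pair inventory), along with an
#' overall per-condition summary. Scoring is independent of trial order.
#'
#' @param trials Trial schedule from [generate_trial_list()].
#' @param responses Integer vector in `{1, 2, 3}` aligned with
#'   `trials$trial`, or a data frame with columns `trial` and `response`.
#' @return A list of data frames: `by_type` (condition, talker,
#'   phoneme_type, n, percent_correct), `by_contrast` (condition,
#'   contrast_type, n, percent_correct), and `overall` (condition, n,
#'   percent_correct).
#' @export
score_responses <- function(trials, responses) {
  if (is.data.frame(responses)) {
    idx <- match(trials$trial, responses$trial)
    responses <- responses$response[idx]
  }
  if (length(responses) != nrow(trials)) {
    stop("need one response per trial")
  }
  missing <- which(is.na(responses) | !(responses %in% 1:3))
  if (length(missing) > 0) {
    stop("missing or invalid responses for trials: ",
         paste(trials$trial[missing], collapse = ", "))
  }
  trials$correct <- responses == trials$odd_interval

  pct <- function(v) 100 * mean(v)
  agg <- function(formula) {
    n <- stats::aggregate(formula, data = trials, FUN = length)
    names(n)[ncol(n)] <- "n"
    p <- stats::aggregate(formula, data = trials, FUN = pct)
    names(p)[ncol(p)] <- "percent_correct"
    merge(n, p)
  }
  list(by_type = agg(correct ~ condition + talker + phoneme_type),
       by_contrast = agg(correct ~ condition + contrast_type),
       overall = agg(correct ~ condition))
}
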