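# Phoneme inventory and the 45-pair discrimination inventory.
# IPA labels are written as unicode escapes so the source stays ASCII.

# Labels used throughout (UTF-8 IPA, written as escapes):
IPA <- list(
  ih = "\u026a",            # small capital I
  ah = "\u0251\u02d0",      # long open back a
  ii = "i\u02d0",           # long close front i
  ae = "\u00e6",            # ash
  oo = "\u0254\u02d0",      # long open-mid back rounded
  uh = "\u028a",            # horseshoe u
  uu = "u\u02d0",
  vv = "\u028c",            # wedge
  e  = "e",
  o  = "\u0252",            # short open back rounded
  oi = "\u0254\u026a",
  ei = "e\u026a",
  au = "a\u028a",
  ia = "\u026a\u0259",
  ou = "\u0259\u028a",
  ua = "\u028a\u0259",
  ea = "e\u0259",
  th = "\u03b8",            # voiceless dental fricative
  dh = "\u00f0",            # voiced dental fricative
  sh = "\u0283",            # esh
  zh = "\u0292",            # ezh
  ch = "t\u0283"            # affricate
)

#' Phoneme inventory
#'
#' Every phoneme used in the discrimination pair inventory, with its type
#' (consonant or vowel), manner class (plosive, fricative, affricate,
#' sonorant, monophthong, diphthong) and voicing flag. Labels are IPA
#' (UTF-8).
#'
#' @return A data frame with columns `label`, `type`, `class`, `voiced`.
#' @export
phoneme_inventory <- function() {
  cons <- function(labels, class, voiced) {
    data.frame(label = labels, type = "consonant", class = class,
               voiced = voiced, stringsAsFactors = FALSE)
  }
  vow <- function(labels, class) {
    data.frame(label = labels, type = "vowel", class = class,
               voiced = TRUE, stringsAsFactors = FALSE)
  }
  rbind(
    cons(c("p", "t", "k"), "plosive", FALSE),
    cons(c("b", "d", "g"), "plosive", TRUE),
    cons(c("f", IPA$th, "s", IPA$sh), "fricative", FALSE),
    cons(c("v", IPA$dh, "z", IPA$zh), "fricative", TRUE),
    cons(IPA$ch, "affricate", FALSE),
    cons(c("l", "r", "j", "w", "m", "n"), "sonorant", TRUE),
    vow(c(IPA$ih, IPA$ah, IPA$ii, IPA$ae, IPA$oo, IPA$uh, IPA$uu,
          IPA$vv, IPA$e, IPA$o), "monophthong"),
    vow(c(IPA$oi, IPA$ei, IPA$au, IPA$ia, IPA$ou, IPA$ua, IPA$ea),
        "diphthong")
  )
}

#' Phoneme pair inventory for the discrimination task
#'
#' The 45 phoneme pairs (27 consonant, 18 vowel) used in the 3AFC
#' discrimination task, grouped by the type of contrast each pair probes:
#' place of articulation within voiceless/voiced plosives and fricatives and
#' within sonorants, voicing, manner, two-feature contrasts (manner+place,
#' place+voicing), and monophthong and diphthong vowel contrasts.
#'
#' @return A data frame with columns `pair_id`, `phoneme_a`, `phoneme_b`,
#'   `phoneme_type` (`"consonant"`/`"vowel"`), `contrast_type`.
#' @export
#' @examples
#' pairs <- phoneme_pairs()
#' table(pairs$contrast_type)
phoneme_pairs <- function() {
  p <- function(a, b, contrast) c(a, b, contrast)
  rows <- list(
    p("t", "p", "place-voiceless-plosive"),
    p("t", "k", "place-voiceless-plosive"),
    p("k", "p", "place-voiceless-plosive"),
    p("f", IPA$th, "place-voiceless-fricative"),
    p("f", "s", "place-voiceless-fricative"),
    p(IPA$sh, "s", "place-voiceless-fricative"),
    p("d", "b", "place-voiced-plosive"),
    p("g", "d", "place-voiced-plosive"),
    p("g", "b", "place-voiced-plosive"),
    p("v", IPA$dh, "place-voiced-fricative"),
    p("v", "z", "place-voiced-fricative"),
    p(IPA$dh, "z", "place-voiced-fricative"),
    p("l", "r", "place-sonorant"),
    p("j", "l", "place-sonorant"),
    p("m", "n", "place-sonorant"),
    p("z", "s", "voicing"),
    p(IPA$zh, IPA$sh, "voicing"),
    p(IPA$th, IPA$dh, "voicing"),
    p("t", "s", "manner"),
    p("b", "w", "manner"),
    p(IPA$ch, IPA$sh, "manner"),
    p(IPA$dh, "b", "manner+place"),
    p("k", "s", "manner+place"),
    p("g", "r", "manner+place"),
    p("v", "s", "place+voicing"),
    p(IPA$th, "z", "place+voicing"),
    p("m", "v", "place+voicing"),
    p(IPA$ih, IPA$ah, "monophthong"),
    p(IPA$ii, IPA$ae, "monophthong"),
    p(IPA$oo, IPA$ih, "monophthong"),
    p(IPA$uh, IPA$ah, "monophthong"),
    p(IPA$uu, IPA$vv, "monophthong"),
    p(IPA$ae, IPA$e, "monophthong"),
    p(IPA$uh, IPA$ih, "monophthong"),
    p(IPA$ae, IPA$o, "monophthong"),
    p(IPA$ii, IPA$uu, "monophthong"),
    p(IPA$vv, IPA$ae, "monophthong"),
    p(IPA$uu, IPA$uh, "monophthong"),
    p(IPA$ii, IPA$e, "monophthong"),
    p(IPA$oi, IPA$ei, "diphthong"),
    p(IPA$oi, IPA$au, "diphthong"),
    p(IPA$au, IPA$ei, "diphthong"),
    p(IPA$ia, IPA$ou, "diphthong"),
    p(IPA$ua, IPA$ei, "diphthong"),
    p(IPA$ea, IPA$ua, "diphthong")
  )
  m <- do.call(rbind, rows)
  data.frame(pair_id = seq_along(rows),
             phoneme_a = m[, 1], phoneme_b = m[, 2],
             phoneme_type = ifelse(m[, 3] %in% c("monophthong", "diphthong"),
                                   "vowel", "consonant"),
             contrast_type = m[, 3],
             stringsAsFactors = FALSE)
}
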