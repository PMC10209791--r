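# Pinyin (phonological code) handling.
#
# A phonological code is a romanized syllable with tone, either tone-marked
# ("zhǒng") or tone-digit ("zhong3"). For featurization the syllable is
# decomposed into (initial, final, tone digit); each slot becomes one symbol
# of a categorical alphabet, so the one-hot matrix of a syllable has at most
# three non-zero rows.

PINYIN_INITIALS <- c(
  "zh", "ch", "sh",
  "b", "p", "m", "f", "d", "t", "n", "l", "g", "k", "h",
  "j", "q", "x", "r", "z", "c", "s", "y", "w"
)

PINYIN_FINALS <- c(
  "iang", "iong", "uang",
  "ang", "eng", "ing", "ong", "iao", "ian", "uai", "uan",
  "ai", "ei", "ui", "ao", "ou", "iu", "ie", "ve", "er",
  "an", "en", "in", "un", "vn", "ia", "ua", "uo", "ue",
  "a", "o", "e", "i", "u", "v"
)

PINYIN_TONES <- as.character(0:4)

# diacritic vowel -> c(base letter, tone digit)
.tone_marks <- list(
  "ā" = c("a", "1"), "á" = c("a", "2"), "ǎ" = c("a", "3"), "à" = c("a", "4"),
  "ē" = c("e", "1"), "é" = c("e", "2"), "ě" = c("e", "3"), "è" = c("e", "4"),
  "ī" = c("i", "1"), "í" = c("i", "2"), "ǐ" = c("i", "3"), "ì" = c("i", "4"),
  "ō" = c("o", "1"), "ó" = c("o", "2"), "ǒ" = c("o", "3"), "ò" = c("o", "4"),
  "ū" = c("u", "1"), "ú" = c("u", "2"), "ǔ" = c("u", "3"), "ù" = c("u", "4"),
  "ǖ" = c("v", "1"), "ǘ" = c("v", "2"), "ǚ" = c("v", "3"), "ǜ" = c("v", "4"),
  "ü" = c("v", "0")
)

#' Alphabet of phonological-code symbols
#'
#' The ordered symbol set used to one-hot encode phonological codes:
#' syllable initials, then finals, then tone digits 0--4 (0 = neutral tone).
#'
#' @return Character vector of symbols.
#' @export
pinyin_alphabet <- function() {
  c(PINYIN_INITIALS, PINYIN_FINALS, PINYIN_TONES)
}

#' Decompose a pinyin syllable into initial, final and tone
#'
#' Accepts tone-marked syllables (`"zhǒng"`) and tone-digit syllables
#' (`"zhong3"`, `"ou"`); tone marks are normalized to digits, an unmarked
#' syllable gets the neutral tone 0, and `ü` is written `v`. Syllables with
#' no initial (e.g. `"ǒu"`) return an empty-string initial.
#'
#' @param syllable A single pinyin syllable.
#' @return A list with elements `initial`, `final`, `tone` (all character);
#'   all `NA` when the syllable cannot be decomposed.
#' @export
#' @examples
#' parse_pinyin("zhǒng")
#' parse_pinyin("ǒu")
parse_pinyin <- function(syllable) {
  bad <- list(initial = NA_character_, final = NA_character_, tone = NA_character_)
  if (length(syllable) != 1L || is.na(syllable) || nchar(syllable) == 0L) return(bad)
  s <- tolower(trimws(syllable))
  tone <- NA_character_
  # trailing tone digit
  if (grepl("[0-4]$", s)) {
    tone <- substr(s, nchar(s), nchar(s))
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  # tone marks
  out <- character(0)
  for (ch in chars_of(s)) {
    m <- .tone_marks[[ch]]
    if (!is.null(m)) {
      out <- c(out, m[1])
      if (m[2] != "0") tone <- m[2]
    } else {
      out <- c(out, ch)
    }
  }
  s <- paste(out, collapse = "")
  if (is.na(tone)) tone <- "0"
  if (!grepl("^[a-z]+$", s)) return(bad)
  ini <- ""
  for (cand in PINYIN_INITIALS) {
    if (startsWith(s, cand) && nchar(s) > nchar(cand)) {
      ini <- cand
      break
    }
  }
  fin <- substr(s, nchar(ini) + 1L, nchar(s))
  if (!(fin %in% PINYIN_FINALS)) {
    # a bare final with no initial ("ou"), or unparseable
    if (s %in% PINYIN_FINALS) {
      ini <- ""
      fin <- s
    } else {
      return(bad)
    }
  }
  list(initial = ini, final = fin, tone = tone)
}

# symbol sequence for one-hot encoding; character(0) when unparseable/empty
pinyin_symbols <- function(syllable) {
  p <- parse_pinyin(syllable)
  if (is.na(p$final)) return(character(0))
  c(if (nzchar(p$initial)) p$initial, p$final, p$tone)
}
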