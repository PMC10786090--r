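#' Parse a pinyin syllable string
#'
#' Splits a compact pinyin token such as \code{"ji1"} or \code{"zhang4"} into
#' its onset (initial), rime (final) and tone. The initial is the longest
#' leading consonant cluster drawn from the standard pinyin inventory (it may
#' be empty, as in \code{"an4"}); the trailing digit is the tone, with 0
#' denoting the neutral tone and no digit treated as neutral. Whether
#' initial + final spell a phonotactically legal Mandarin syllable is not
#' enforced: toy stimuli are allowed.
#'
#' @param x character vector of pinyin tokens.
#' @return A data frame with columns \code{initial}, \code{final} (non-empty)
#'   and \code{tone} (integer in 0..4), one row per token.
#' @examples
#' parse_syllable(c("ji1", "zhang4", "an4"))
#' @export
parse_syllable <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  tone <- ifelse(grepl("[0-9]$", x), as.integer(sub("^.*?([0-9])$", "\\1", x)), 0L)
  body <- sub("[0-9]$", "", x)
  if (any(is.na(tone)) || any(tone < 0L | tone > 4L))
    abort("ConfigError", "syllable tone must be a digit in 0..4")
  ini <- character(length(x))
  fin <- body
  two <- substr(body, 1L, 2L)
  one <- substr(body, 1L, 1L)
  is2 <- two %in% c("zh", "ch", "sh")
  ini[is2] <- two[is2]
  fin[is2] <- substr(body[is2], 3L, nchar(body[is2]))
  singles <- c("b", "p", "m", "f", "d", "t", "n", "l", "g", "k", "h",
               "j", "q", "x", "r", "z", "c", "s", "y", "w")
  is1 <- !is2 & one %in% singles & nchar(body) > 1L
  ini[is1] <- one[is1]
  fin[is1] <- substr(body[is1], 2L, nchar(body[is1]))
  if (any(!nzchar(fin)))
    abort("ConfigError",
          sprintf("syllable '%s' has an empty final", x[!nzchar(fin)][1]))
  data.frame(initial = ini, final = fin, tone = tone, stringsAsFactors = FALSE)
}

#' Component-match similarity between two syllables
#'
#' Weighted indicator similarity over the three syllable components:
#' \deqn{s(a, b) = w_i [a_{ini} = b_{ini}] + w_f [a_{fin} = b_{fin}]
#'   + w_t [a_{tone} = b_{tone}]}
#' with nonnegative weights summing to 1. Two syllables that agree on onset,
#' rime and tone score exactly 1; syllables sharing no component score 0.
#' Tone is an equality predicate, not a graded distance: items sharing a
#' syllable in the experimental design share it tone-included.
#'
#' The weights are user-calibratable; the defaults (0.4, 0.4, 0.2) weight the
#' segmental components equally and the tone half as much.
#'
#' @param a,b pinyin tokens (strings) or single-row data frames as returned
#'   by [parse_syllable()].
#' @param weights numeric length-3 vector \code{(w_initial, w_final, w_tone)};
#'   nonnegative, summing to 1 (within 1e-9).
#' @return similarity in \[0, 1\]; symmetric in its arguments.
#' @examples
#' syllable_similarity("ji1", "ji1")   # 1
#' syllable_similarity("ji1", "ji2")   # 0.8: same onset and rime
#' syllable_similarity("ji1", "wo3")   # 0
#' @export
syllable_similarity <- function(a, b, weights = c(0.4, 0.4, 0.2)) {
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    abort("WeightError",
          "'weights' must be 3 nonnegative numbers summing to 1")
  if (is.character(a)) a <- parse_syllable(a)
  if (is.character(b)) b <- parse_syllable(b)
  as.numeric(
    weights[1] * (a$initial == b$initial) +
    weights[2] * (a$final == b$final) +
    weights[3] * (a$tone == b$tone)
  )
}
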