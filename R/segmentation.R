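## Rule-based sentence segmentation and length accounting for clinical text.
## Chinese notes use fullwidth terminal punctuation; English notes use ASCII.
## Semicolons terminate sentences in both languages: clinical notes chain
## findings with semicolons and keyword evidence stays local to the clause.

zh_terminals <- "[\u3002\uff01\uff1f\uff1b\n]"  # fullwidth . ! ? ;
en_terminals <- "[.!?;\n]"

#' Split clinical text into sentences
#'
#' Rule-based splitting on terminal punctuation: for Chinese the fullwidth
#' marks \code{。 ！ ？ ；} and newline; for English
#' `. ! ? ;` and newline. Terminal marks stay attached to their sentence,
#' leading/trailing whitespace is trimmed, and empty fragments are dropped,
#' so re-splitting any returned sentence yields the sentence itself.
#'
#' @param text A single character string (may be empty).
#' @param language `"zh"` or `"en"`.
#' @return Character vector of sentences in original order (empty vector for
#'   empty text).
#' @examples
#' split_sentences("He smokes daily. BP stable.", "en")
#' @export
split_sentences <- function(text, language = c("zh", "en")) {
  language <- match.arg(language)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  term <- if (language == "zh") zh_terminals else en_terminals
  # keep the terminal mark with its sentence, then cut after it
  marked <- gsub(paste0("(", term, "+)"), "\\1\x01", text, perl = TRUE)
  parts <- strsplit(marked, "\x01", fixed = TRUE)[[1L]]
  parts <- gsub("^[[:space:]]+|[[:space:]]+$", "", parts)
  parts[nzchar(parts)]
}

#' Count length units of a text
#'
#' The unit convention differs by language, matching how the two benchmark
#' tasks report document length: English text is counted in
#' whitespace-delimited words; Chinese text is counted in non-whitespace
#' characters.
#'
#' @param text Character vector of texts.
#' @param language `"zh"` or `"en"` (recycled over `text`).
#' @return Integer vector of unit counts (0 for empty text).
#' @examples
#' count_units("He smokes daily.", "en") # 3 words
#' @export
count_units <- function(text, language = c("zh", "en")) {
  language <- match.arg(language)
  stopifnot(is.character(text))
  text[is.na(text)] <- ""
  if (language == "en") {
    vapply(strsplit(trimws(text), "[[:space:]]+"), function(w) {
      sum(nzchar(w))
    }, integer(1L))
  } else {
    nchar(gsub("[[:space:]]", "", text), type = "chars")
  }
}

#' Maximum and mean document length
#'
#' Length accounting for a corpus or a set of texts in the task's unit
#' (words for English, characters for Chinese). The reported mean is rounded
#' half-up to an integer, the convention of published length tables.
#'
#' @param x A `notephen_corpus`, or a character vector of texts.
#' @param language Unit convention when `x` is a character vector; for a
#'   corpus the per-document language tags are used.
#' @return A list with `max_units`, `mean_units` (exact) and `mean_reported`
#'   (rounded to integer).
#' @export
length_stats <- function(x, language = c("zh", "en")) {
  if (inherits(x, "notephen_corpus")) {
    if (!length(x)) stop("empty corpus", call. = FALSE)
    n <- vapply(seq_len(nrow(x$documents)), function(i) {
      count_units(x$documents$text[i], x$documents$language[i])
    }, integer(1L))
  } else {
    language <- match.arg(language)
    stopifnot(is.character(x))
    if (!length(x)) stop("empty text collection", call. = FALSE)
    n <- count_units(x, language)
  }
  m <- mean(n)
  list(max_units = max(n), mean_units = m,
       mean_reported = as.integer(round_half_up(m)))
}
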