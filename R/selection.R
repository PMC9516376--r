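#' Select the key sentences of a document
#'
#' The central length-reduction strategy: a long clinical document is cut
#' down to exactly those sentences that contain a task keyword, preserving
#' their original order. Kept sentences are joined with a single space for
#' English and with no separator for Chinese (terminal punctuation is already
#' part of each sentence). A document with no matching sentence yields an
#' empty selection — empty selections are preserved, not short-circuited to a
#' label, so training and inference see the same representation.
#'
#' @param text A single document's text.
#' @param language `"zh"` or `"en"`.
#' @param keywords A [keyword_list()].
#' @return A list of class `selected_document` with `selected_text`,
#'   `kept_indices` (strictly increasing sentence indices),
#'   `kept_sentences`, and `n_sentences_total`.
#' @examples
#' kw <- load_builtin_keywords("smoking")
#' select_key_sentences("He smokes daily. BP stable.", "en", kw)$selected_text
#' @export
select_key_sentences <- function(text, language, keywords) {
  sentences <- split_sentences(text, language)
  hit <- contains_keyword(sentences, keywords)
  kept <- which(hit)
  sep <- if (language == "zh") "" else " "
  structure(
    list(selected_text = paste(sentences[kept], collapse = sep),
         kept_indices = kept,
         kept_sentences = sentences[kept],
         n_sentences_total = length(sentences)),
    class = "selected_document"
  )
}

#' Apply key-sentence selection to every document of a corpus
#'
#' @param x A `notephen_corpus`.
#' @param keywords A [keyword_list()].
#' @return A `notephen_corpus` whose `text` column holds the selected text
#'   (possibly empty strings); all other fields are unchanged.
#' @export
select_corpus <- function(x, keywords) {
  stopifnot(inherits(x, "notephen_corpus"))
  docs <- x$documents
  docs$text <- vapply(seq_len(nrow(docs)), function(i) {
    select_key_sentences(docs$text[i], docs$language[i], keywords)$selected_text
  }, "")
  new_corpus(docs, x$scheme)
}

#' Oracle test: an upper bound for keyword-based selection
#'
#' Measures how much signal a keyword list can possibly lose: every document
#' containing at least one keyword is assigned its gold label; every
#' keyword-free document is assigned the scheme's fallback label. The
#' micro-averaged F1 of this oracle prediction against the gold labels bounds
#' what any downstream classifier restricted to the selected text can see —
#' the oracle errs exactly on keyword-free positive documents (a
#' keyword-bearing fallback document is still assigned its gold fallback
#' label).
#'
#' @param x A fully labeled `notephen_corpus`.
#' @param keywords A [keyword_list()].
#' @return A list with `micro_f1`, the oracle `predictions`, and `n_errors`.
#' @export
oracle_test <- function(x, keywords) {
  stopifnot(inherits(x, "notephen_corpus"))
  docs <- x$documents
  if (anyNA(docs$label)) stop("all documents must be labeled", call. = FALSE)
  if (!nrow(docs)) stop("empty corpus", call. = FALSE)
  has_kw <- contains_keyword(docs$text, keywords)
  pred <- ifelse(has_kw, docs$label, x$scheme$fallback_label)
  list(micro_f1 = micro_f1(docs$label, pred),
       predictions = pred,
       n_errors = sum(pred != docs$label))
}
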