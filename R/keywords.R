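#' Construct a keyword list
#'
#' A keyword list is an ordered, deduplicated set of surface strings used to
#' pick out key sentences, together with its provenance and a matching mode:
#' `"substring"` (contiguous, case-sensitive — the only sensible convention
#' for Chinese, which has no word boundaries) or `"word_boundary"`
#' (whole-token, case-insensitive — so English "smoke" does not fire inside
#' "smokescreen").
#'
#' @param terms Character vector of keyword strings; empty strings are
#'   rejected, duplicates dropped keeping first occurrence.
#' @param provenance One of `"builtin_guideline"`, `"builtin_smoking"`,
#'   `"tfidf_derived"`, `"custom"`.
#' @param match_mode `"substring"` or `"word_boundary"`.
#' @return An object of class `keyword_list`.
#' @export
keyword_list <- function(terms,
                         provenance = c("custom", "builtin_guideline",
                                        "builtin_smoking", "tfidf_derived"),
                         match_mode = c("substring", "word_boundary")) {
  provenance <- match.arg(provenance)
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(terms))
  terms <- terms[!is.na(terms)]
  if (any(!nzchar(terms))) stop("empty keyword term", call. = FALSE)
  terms <- terms[!duplicated(terms)]
  if (!length(terms)) stop("keyword list has no terms", call. = FALSE)
  esc <- regex_escape(terms)
  pattern <- if (match_mode == "word_boundary") {
    paste0("(?i)\\b(?:", paste(esc, collapse = "|"), ")\\b")
  } else {
    paste0("(?:", paste(esc, collapse = "|"), ")")
  }
  structure(list(terms = terms, provenance = provenance,
                 match_mode = match_mode, pattern = pattern),
            class = "keyword_list")
}

#' @export
print.keyword_list <- function(x, ...) {
  cat("<keyword_list> ", length(x$terms), " terms (", x$provenance, ", ",
      x$match_mode, " matching)\n", sep = "")
  utils::head(x$terms, 10L) |> paste(collapse = ", ") |> cat("...\n")
  invisible(x)
}

#' Load a built-in keyword list
#'
#' Two published lists ship with the package: the 7 English smoking-status
#' unigrams (cigarette, smoke, smoked, smoker, smokes, smoking, tobacco),
#' matched at word boundaries, and the Chinese guideline keyword list for the
#' severe drug hypersensitivity reaction task (disease names and
#' abbreviations such as SJS and DIHS, symptom terms such as
#' \code{红斑} (erythema), and rescue-drug terms such as
#' \code{肾上腺素} (adrenaline)), matched by substring.
#'
#' @param task `"smoking"` or `"dhr_guideline"`.
#' @return A [keyword_list()].
#' @examples
#' load_builtin_keywords("smoking")$terms
#' @export
load_builtin_keywords <- function(task = c("smoking", "dhr_guideline")) {
  task <- match.arg(task)
  fname <- switch(task,
                  smoking = "keywords_smoking.txt",
                  dhr_guideline = "keywords_dhr_guideline.txt")
  path <- system.file("extdata", fname, package = "notephen", mustWork = TRUE)
  terms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- terms[nzchar(terms)]
  if (task == "smoking") {
    keyword_list(terms, provenance = "builtin_smoking",
                 match_mode = "word_boundary")
  } else {
    keyword_list(terms, provenance = "builtin_guideline",
                 match_mode = "substring")
  }
}

#' Read/write a keyword list as plain text
#'
#' One term per line, UTF-8.
#'
#' @param path File path.
#' @param ... Passed on to [keyword_list()] (provenance, match_mode).
#' @return `read_keywords()` a [keyword_list()]; `write_keywords()` the path,
#'   invisibly.
#' @export
read_keywords <- function(path, ...) {
  terms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keyword_list(terms[nzchar(terms)], ...)
}

#' @rdname read_keywords
#' @param x A `keyword_list`.
#' @export
write_keywords <- function(x, path) {
  stopifnot(inherits(x, "keyword_list"))
  writeLines(x$terms, path, useBytes = TRUE)
  invisible(path)
}

#' Does a sentence contain any keyword?
#'
#' Substring mode: TRUE iff any term occurs as a contiguous substring.
#' Word-boundary mode: TRUE iff any term matches a whole token,
#' case-insensitively. Vectorized over sentences.
#'
#' @param sentences Character vector.
#' @param keywords A [keyword_list()].
#' @return Logical vector, one value per sentence.
#' @examples
#' contains_keyword("He smokes daily.", load_builtin_keywords("smoking"))
#' @export
contains_keyword <- function(sentences, keywords) {
  stopifnot(inherits(keywords, "keyword_list"), is.character(sentences))
  out <- grepl(keywords$pattern, sentences, perl = TRUE)
  out[is.na(sentences)] <- FALSE
  out
}

## ---------------------------------------------------------------------------
## Discriminative TF-IDF keyword derivation.
##
## Tokens: English -> lowercased whitespace tokens; Chinese -> character
## unigrams + bigrams over non-whitespace runs (no segmenter dependency).
## Weighting: tf (raw count) * smoothed idf log((1+n)/(1+df)) + 1, document
## vectors L2-normalized.

tokenize_for_tfidf <- function(text, language) {
  if (language == "en") {
    toks <- strsplit(tolower(trimws(text)), "[[:space:]]+")[[1L]]
    toks[nzchar(toks)]
  } else {
    chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1L]]
    if (!length(chars)) return(character())
    uni <- chars
    bi <- if (length(chars) >= 2L) {
      paste0(chars[-length(chars)], chars[-1L])
    } else {
      character()
    }
    c(uni, bi)
  }
}

# TRUE for terms free of digits, punctuation/special characters, and
# characters outside the corpus's primary script (zh: Han only; en: ASCII
# letters only).
term_is_clean <- function(terms, language) {
  if (language == "zh") {
    grepl("^\\p{Han}+$", terms, perl = TRUE)
  } else {
    grepl("^[a-zA-Z]+$", terms, perl = TRUE)
  }
}

#' Derive discriminative keywords by TF-IDF
#'
#' An unsupervised-then-filtered keyword derivation: (1) tokenize the
#' training documents (English: whitespace tokens; Chinese: character
#' unigrams and bigrams); (2) fit TF-IDF over the training corpus; (3) keep
#' the `top_n` terms by maximum TF-IDF weight; (4) drop candidates containing
#' digits, characters outside the corpus's primary script, or
#' punctuation/special characters; (5) score each survivor by its mean TF-IDF
#' weight in positive-labeled documents minus its mean weight in
#' fallback-labeled documents; (6) keep terms scoring above zero, ordered by
#' descending score. The result is a `keyword_list` matched in the corpus's
#' native mode.
#'
#' @param train A fully labeled `notephen_corpus` with at least one positive
#'   and one fallback-labeled document.
#' @param top_n Number of top TF-IDF candidate terms considered before
#'   filtering (default 2000).
#' @return A [keyword_list()] with provenance `"tfidf_derived"`; the
#'   per-term discrimination scores are attached as attribute `"score"`.
#' @export
extract_tfidf_keywords <- function(train, top_n = 2000L) {
  stopifnot(inherits(train, "notephen_corpus"))
  docs <- train$documents
  if (anyNA(docs$label)) stop("all training documents must be labeled",
                              call. = FALSE)
  fallback <- train$scheme$fallback_label
  is_pos <- docs$label != fallback
  if (!any(is_pos) || !any(!is_pos)) {
    stop("need at least one positive and one fallback-labeled document",
         call. = FALSE)
  }
  language <- docs$language[1L]

  # sparse doc-term triplets
  token_lists <- lapply(seq_len(nrow(docs)), function(i) {
    tokenize_for_tfidf(docs$text[i], docs$language[i])
  })
  counts <- lapply(token_lists, function(t) table(t))
  doc_i <- rep.int(seq_along(counts), lengths(counts))
  term <- unlist(lapply(counts, names), use.names = FALSE)
  tf <- unlist(lapply(counts, as.integer), use.names = FALSE)
  if (!length(term)) stop("corpus contains no tokens", call. = FALSE)

  n_docs <- nrow(docs)
  df <- table(term)[unique(term)]
  vocab <- names(df)
  df <- as.integer(df)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  names(idf) <- vocab

  w <- tf * idf[term]
  # L2-normalize per document
  norms <- sqrt(rowsum(w^2, doc_i)[, 1L])
  w <- w / norms[as.character(doc_i)]

  # step 3: top_n candidates by maximum weight anywhere
  max_w <- tapply(w, term, max)
  candidates <- names(sort(max_w, decreasing = TRUE))
  candidates <- utils::head(candidates, top_n)

  # step 4: drop digits / foreign alphabet / punctuation
  candidates <- candidates[term_is_clean(candidates, language)]
  if (!length(candidates)) {
    stop("no candidate terms survive filtering", call. = FALSE)
  }

  keep <- term %in% candidates
  sub_term <- factor(term[keep], levels = candidates)
  sub_doc <- doc_i[keep]
  sub_w <- w[keep]

  sum_by <- function(sel) {
    s <- rowsum(sub_w[sel], sub_term[sel])
    out <- stats::setNames(numeric(length(candidates)), candidates)
    out[rownames(s)] <- s[, 1L]
    out
  }
  mean_pos <- sum_by(is_pos[sub_doc]) / sum(is_pos)
  mean_neg <- sum_by(!is_pos[sub_doc]) / sum(!is_pos)
  score <- mean_pos - mean_neg

  kept <- score > 0
  if (!any(kept)) stop("no term scores above zero", call. = FALSE)
  ord <- order(score[kept], decreasing = TRUE)
  terms <- candidates[kept][ord]
  out <- keyword_list(terms, provenance = "tfidf_derived",
                      match_mode = if (language == "zh") "substring"
                                   else "word_boundary")
  attr(out, "score") <- stats::setNames(score[kept][ord], terms)
  out
}
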