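# Shared fixtures and independent oracles for the test suite.

tiny_scheme <- function() label_scheme(c("CASE", "NEG"), fallback_label = "NEG")

make_corpus <- function(texts, labels, language = "en",
                        scheme = tiny_scheme(), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("d%03d", seq_along(texts))
  corpus(data.frame(doc_id = ids, text = texts, language = language,
                    label = labels, stringsAsFactors = FALSE),
         scheme, mode = "lenient")
}

# Independent micro-F1 oracle: explicit per-class TP/FP/FN loop, then pooled
# F1 (kept deliberately naive and separate from the package implementation).
brute_micro_f1 <- function(gold, pred) {
  tp_sum <- 0; fp_sum <- 0; fn_sum <- 0
  for (cl in unique(c(gold, pred))) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(gold)) {
      if (pred[i] == cl && gold[i] == cl) tp <- tp + 1
      if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
      if (pred[i] != cl && gold[i] == cl) fn <- fn + 1
    }
    tp_sum <- tp_sum + tp; fp_sum <- fp_sum + fp; fn_sum <- fn_sum + fn
  }
  prec <- tp_sum / (tp_sum + fp_sum)
  rec <- tp_sum / (tp_sum + fn_sum)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Independent dense TF-IDF keyword-derivation oracle for English corpora:
# full document-term matrix, smoothed idf, L2 rows, then the positive-minus-
# fallback mean-weight score. Use top_n >= vocabulary size so candidate tie
# order cannot differ from the package's sparse implementation.
brute_tfidf_scores <- function(texts, labels, fallback, top_n = Inf) {
  toks <- lapply(texts, function(t) {
    w <- strsplit(tolower(t), "[[:space:]]+")[[1L]]
    w[nzchar(w)]
  })
  vocab <- sort(unique(unlist(toks)))
  n <- length(texts)
  tfm <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    tb <- table(toks[[i]])
    tfm[i, names(tb)] <- as.numeric(tb)
  }
  idf <- log((1 + n) / (1 + colSums(tfm > 0))) + 1
  w <- sweep(tfm, 2, idf, "*")
  w <- w / sqrt(rowSums(w^2))
  cand <- names(sort(apply(w, 2, max), decreasing = TRUE))
  cand <- head(cand, min(top_n, length(cand)))
  cand <- cand[grepl("^[a-zA-Z]+$", cand)]
  pos <- labels != fallback
  score <- colMeans(w[pos, cand, drop = FALSE]) -
    colMeans(w[!pos, cand, drop = FALSE])
  sort(score[score > 0], decreasing = TRUE)
}

# Small fast generator config for unit tests (shorter background documents
# than the study-scale defaults; explicit, not a changed default).
small_config <- function(seed = 1L, ...) {
  generator_config(doc_length_mean = 300, seed = seed, ...)
}
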