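## Pluggable document-embedding backends.
##
## Three strategies for turning a (possibly very long) document into one
## fixed-dimension vector:
##   truncate_encoder — keep the first max_tokens tokens and encode the one
##                      remaining block with a sentence encoder;
##   hierarchy_mean   — encode every sentence separately (each truncated to
##                      max_tokens) and average the sentence vectors;
##   hash_ngram       — hashed character n-gram counts (n = 1..3), L2
##                      normalized: a deterministic, download-free encoder
##                      that doubles as the default sentence encoder.
## External pretrained contextual encoders plug in through register_encoder()
## and are referenced by an identifier string; they are never re-implemented
## here and no fine-tuning is performed.

.encoder_registry <- new.env(parent = emptyenv())

#' Register an external text encoder backend
#'
#' An encoder is a function `function(texts, dim)` mapping a character vector
#' to a numeric matrix with `length(texts)` rows and `dim` columns (the
#' pooled sentence-level vectors of a pretrained model, say). Encoders are
#' looked up by the `encoder_id` of an [embedder_config()]; requesting an
#' unregistered id is an explicit error, never a silent fallback. The
#' deterministic `"hash_ngram"` encoder is pre-registered.
#'
#' @param id Identifier string.
#' @param fun The encoder function.
#' @return `id`, invisibly.
#' @export
register_encoder <- function(id, fun) {
  stopifnot(is_string(id), is.function(fun))
  assign(id, fun, envir = .encoder_registry)
  invisible(id)
}

get_encoder <- function(id) {
  if (!exists(id, envir = .encoder_registry, inherits = FALSE)) {
    stop("encoder backend '", id, "' is not registered; ",
         "use register_encoder() to plug in an external model",
         call. = FALSE)
  }
  get(id, envir = .encoder_registry, inherits = FALSE)
}

#' Configure a document embedder
#'
#' @param backend `"hash_ngram"`, `"truncate_encoder"` or `"hierarchy_mean"`.
#' @param encoder_id Identifier of the (sentence) encoder used by the
#'   `truncate_encoder` and `hierarchy_mean` strategies; ignored by
#'   `hash_ngram`. Defaults to the built-in `"hash_ngram"` encoder.
#' @param max_tokens Token budget per encoded block (default 512, the length
#'   limit of standard contextual encoders; English tokens are
#'   whitespace-delimited words, Chinese tokens are characters).
#' @param dim Output dimension of the document vectors (default 256).
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(backend = c("hash_ngram", "truncate_encoder",
                                        "hierarchy_mean"),
                            encoder_id = "hash_ngram",
                            max_tokens = 512L, dim = 256L) {
  backend <- match.arg(backend)
  stopifnot(is_string(encoder_id),
            is.numeric(max_tokens), max_tokens >= 1,
            is.numeric(dim), dim >= 1)
  structure(list(backend = backend, encoder_id = encoder_id,
                 max_tokens = as.integer(max_tokens), dim = as.integer(dim)),
            class = "embedder_config")
}

#' @export
print.embedder_config <- function(x, ...) {
  cat("<embedder_config> ", x$backend,
      if (x$backend != "hash_ngram") paste0(" via '", x$encoder_id, "'"),
      ", max_tokens = ", x$max_tokens, ", dim = ", x$dim, "\n", sep = "")
  invisible(x)
}

# Keep the first max_tokens tokens of a text (en: words, zh: characters).
truncate_tokens <- function(text, language, max_tokens) {
  if (!nzchar(text)) return(text)
  if (language == "en") {
    toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    paste(utils::head(toks, max_tokens), collapse = " ")
  } else {
    chars <- strsplit(text, "")[[1L]]
    paste(utils::head(chars, max_tokens), collapse = "")
  }
}

## --- hashed character n-gram encoder ---------------------------------------

HASH_SEED <- 104729  # fixed; part of the embedding definition

hash_ngram_vector <- function(text, dim) {
  if (is.na(text) || !nzchar(text)) return(numeric(dim))
  codes <- utf8ToInt(text)
  L <- length(codes)
  h <- codes
  if (L >= 2L) {
    h2 <- codes[-L] * 31 + codes[-1L]
    h <- c(h, h2)
    if (L >= 3L) {
      h3 <- h2[-(L - 1L)] * 31 + codes[-(1:2)]
      h <- c(h, h3)
    }
  }
  buckets <- ((h + HASH_SEED) %% dim) + 1L
  v <- tabulate(buckets, nbins = dim)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else as.numeric(v)
}

hash_ngram_encoder <- function(texts, dim) {
  out <- vapply(texts, hash_ngram_vector, numeric(dim), dim = dim,
                USE.NAMES = FALSE)
  if (is.null(nrow(out))) out <- matrix(out, ncol = dim) else out <- t(out)
  out
}

assign("hash_ngram", hash_ngram_encoder, envir = .encoder_registry)

## --- strategy implementations ----------------------------------------------

#' Embed a document
#'
#' Dispatches on the configured backend; see [embedder_config()]. All
#' backends are pure functions of `(text, config)` — repeated calls return
#' identical vectors — and always return a finite vector of length
#' `config$dim`.
#'
#' `embed_truncated()` keeps the first `max_tokens` tokens and encodes that
#' single block. `embed_hierarchy_mean()` splits the document into sentences,
#' encodes each (itself truncated to `max_tokens`) and returns the
#' element-wise mean of the sentence vectors (zero vector for empty text).
#' `embed_hash_ngram()` hashes character 1- to 3-grams of the full text into
#' `dim` buckets and L2-normalizes the counts.
#'
#' @param text A single document's text.
#' @param language `"zh"` or `"en"` (controls tokenization and sentence
#'   splitting).
#' @param config An [embedder_config()].
#' @return Numeric vector of length `config$dim`.
#' @examples
#' cfg <- embedder_config("hash_ngram", dim = 64)
#' sum(embed_document("erythema of the trunk", "en", cfg)^2) # unit norm
#' @export
embed_document <- function(text, language, config) {
  stopifnot(inherits(config, "embedder_config"))
  switch(config$backend,
         hash_ngram = embed_hash_ngram(text, language, config),
         truncate_encoder = embed_truncated(text, language, config),
         hierarchy_mean = embed_hierarchy_mean(text, language, config))
}

#' @rdname embed_document
#' @export
embed_truncated <- function(text, language, config) {
  stopifnot(inherits(config, "embedder_config"))
  enc <- get_encoder(config$encoder_id)
  block <- truncate_tokens(text, language, config$max_tokens)
  as.numeric(enc(block, config$dim)[1L, ])
}

#' @rdname embed_document
#' @export
embed_hierarchy_mean <- function(text, language, config) {
  stopifnot(inherits(config, "embedder_config"))
  enc <- get_encoder(config$encoder_id)
  sentences <- split_sentences(text, language)
  if (!length(sentences)) return(numeric(config$dim))
  blocks <- vapply(sentences, truncate_tokens, "", language = language,
                   max_tokens = config$max_tokens, USE.NAMES = FALSE)
  m <- enc(blocks, config$dim)
  colMeans(m)
}

#' @rdname embed_document
#' @export
embed_hash_ngram <- function(text, language, config) {
  stopifnot(inherits(config, "embedder_config"))
  hash_ngram_vector(text, config$dim)
}

#' Embed every document of a corpus
#'
#' @param x A `notephen_corpus` (labels, if any, are ignored).
#' @param config An [embedder_config()].
#' @return Numeric matrix, one row per document, `rownames` = `doc_id`.
#' @export
embed_corpus <- function(x, config) {
  stopifnot(inherits(x, "notephen_corpus"), inherits(config, "embedder_config"))
  docs <- x$documents
  m <- t(vapply(seq_len(nrow(docs)), function(i) {
    embed_document(docs$text[i], docs$language[i], config)
  }, numeric(config$dim)))
  if (!nrow(docs)) m <- matrix(numeric(), 0L, config$dim)
  rownames(m) <- docs$doc_id
  m
}
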