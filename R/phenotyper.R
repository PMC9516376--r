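#' Fit a keyword-guided document phenotyper
#'
#' The top-level model fit: takes a labeled corpus and returns a complete,
#' self-contained pipeline bundle — keyword list, embedder configuration and
#' the grid-searched classifier — that can be applied to new documents with
#' [predict()] or to an untagged archive with [mine_archive()].
#'
#' The pipeline is: (optional) key-sentence selection with `keywords`, then
#' document embedding per `embedder`, then a one-vs-rest classifier selected
#' by stratified cross-validated grid search ([grid_search_fit()]). With
#' `keywords = NULL` the classifier sees the original (possibly truncated by
#' the embedder) text — the baseline the selection strategy is compared
#' against. Documents whose selection is empty are embedded as empty text
#' (a zero vector for the hashed n-gram backend); the classifier learns the
#' empty-evidence-to-fallback mapping rather than it being hard-coded.
#'
#' @param x A fully labeled `notephen_corpus`.
#' @param keywords A [keyword_list()] for key-sentence selection, or `NULL`
#'   to classify the unselected text.
#' @param embedder An [embedder_config()].
#' @param family,grid,folds,seed Passed to [grid_search_fit()].
#' @return An object of class `phenotyper`: list with `model`
#'   (the `notephen_model`), `keywords`, `embedder`, `scheme`, and `n_train`.
#' @examples
#' \donttest{
#' corp <- generate_corpus(generator_config(seed = 1))
#' parts <- split_corpus(corp, test_fraction = 0.2, seed = 1)
#' fit <- phenotyper(parts$train, keywords = load_builtin_keywords("dhr_guideline"),
#'                   embedder = embedder_config(dim = 128), seed = 1)
#' mean(predict(fit, parts$test) == parts$test$documents$label)
#' }
#' @export
phenotyper <- function(x, keywords = NULL,
                       embedder = embedder_config(),
                       family = c("svc", "sgd_linear"),
                       grid = NULL, folds = 10L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(x, "notephen_corpus"))
  if (anyNA(x$documents$label)) {
    stop("all training documents must be labeled", call. = FALSE)
  }
  if (!is.null(keywords)) stopifnot(inherits(keywords, "keyword_list"))
  work <- if (is.null(keywords)) x else select_corpus(x, keywords)
  vectors <- embed_corpus(work, embedder)
  model <- grid_search_fit(vectors, x$documents$label, family = family,
                           grid = grid, folds = folds, seed = seed,
                           classes = x$scheme$labels)
  structure(
    list(model = model,
         keywords = keywords,
         embedder = embedder,
         scheme = x$scheme,
         n_train = length(x)),
    class = "phenotyper"
  )
}

#' @export
print.phenotyper <- function(x, ...) {
  cat("Keyword-guided document phenotyper\n")
  cat("  labels: ", paste(x$scheme$labels, collapse = ", "),
      " (fallback: ", x$scheme$fallback_label, ")\n", sep = "")
  if (is.null(x$keywords)) {
    cat("  selection: none (original text)\n")
  } else {
    cat("  selection: ", length(x$keywords$terms), " keywords (",
        x$keywords$provenance, ")\n", sep = "")
  }
  cat("  embedding: ", x$embedder$backend, ", dim ", x$embedder$dim,
      "\n", sep = "")
  cat(sprintf("  classifier: %s, CV micro-F1 %.4f on %d documents\n",
              x$model$family, x$model$cv_score, x$n_train))
  invisible(x)
}

#' @export
summary.phenotyper <- function(object, ...) {
  print(object)
  cat("\nGrid search results:\n")
  print(object$model$cv_results, row.names = FALSE)
  cat("\nChosen:", paste(names(object$model$chosen),
                         unlist(object$model$chosen),
                         sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.phenotyper <- function(object, ...) coef(object$model, ...)

#' Predict phenotype labels for new documents
#'
#' Runs the full fitted pipeline (selection, embedding, classification) on
#' new documents.
#'
#' @param object A fitted [phenotyper()].
#' @param newdata A `notephen_corpus` (labels, if present, are ignored).
#' @param ... Unused.
#' @return Character vector of predicted labels named by `doc_id`.
#' @export
predict.phenotyper <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "notephen_corpus"))
  if (!length(newdata)) return(stats::setNames(character(), character()))
  work <- if (is.null(object$keywords)) newdata else
    select_corpus(newdata, object$keywords)
  vectors <- embed_corpus(work, object$embedder)
  pred <- predict(object$model, vectors)
  stats::setNames(pred, newdata$documents$doc_id)
}

#' Save / load a fitted phenotyper bundle
#'
#' The bundle (keywords, embedder configuration, fitted classifier and label
#' scheme) is written as one RDS file, versioned with the package version.
#'
#' @param object A `phenotyper`.
#' @param path File path.
#' @return `save_phenotyper()` returns `path` invisibly; `load_phenotyper()`
#'   the restored `phenotyper`.
#' @export
save_phenotyper <- function(object, path) {
  stopifnot(inherits(object, "phenotyper"))
  bundle <- list(version = as.character(utils::packageVersion("notephen")),
                 object = object)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_phenotyper
#' @export
load_phenotyper <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle$object, "phenotyper")) {
    stop("not a phenotyper bundle: ", path, call. = FALSE)
  }
  bundle$object
}
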