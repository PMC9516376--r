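#' Define a label scheme
#'
#' A label scheme is the class vocabulary of a phenotyping task together with
#' its designated fallback label: the "no evidence" class a document receives
#' when nothing in its text speaks for any positive phenotype (e.g. `NEG` for
#' the drug-hypersensitivity task, `UNKNOWN` for smoking status).
#'
#' @param labels Character vector, the ordered class vocabulary.
#' @param fallback_label One element of `labels`, the no-evidence class.
#' @return An object of class `label_scheme` with elements `labels`,
#'   `fallback_label` and `positive_labels` (= `labels` minus the fallback).
#' @seealso [scheme_dhr()], [scheme_smoking()] for the shipped presets.
#' @examples
#' label_scheme(c("CASE", "NEG"), fallback_label = "NEG")
#' @export
label_scheme <- function(labels, fallback_label) {
  stopifnot(is.character(labels), length(labels) >= 2L,
            !anyNA(labels), !anyDuplicated(labels))
  if (!is_string(fallback_label) || !fallback_label %in% labels) {
    stop("`fallback_label` must be one of `labels`", call. = FALSE)
  }
  structure(
    list(labels = labels,
         fallback_label = fallback_label,
         positive_labels = setdiff(labels, fallback_label)),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", paste(x$labels, collapse = ", "),
      " (fallback: ", x$fallback_label, ")\n", sep = "")
  invisible(x)
}

#' Preset label scheme for the severe drug hypersensitivity reaction task
#'
#' Four severe DHR subtypes — Stevens-Johnson syndrome (SJS), drug-induced
#' hypersensitivity syndrome (DIHS), anaphylactic shock (AS) and
#' epidermolysis bullosa (EB) — plus the negative class `NEG` as fallback.
#'
#' @return A [label_scheme()].
#' @export
scheme_dhr <- function() {
  label_scheme(c("SJS", "DIHS", "AS", "EB", "NEG"), fallback_label = "NEG")
}

#' Preset label scheme for the smoking-status task
#'
#' Past smoker, current smoker and nonsmoker, with `UNKNOWN` as the fallback
#' class. The ambiguous "smoker" class of the original challenge is excluded,
#' following common practice on that benchmark.
#'
#' @return A [label_scheme()].
#' @export
scheme_smoking <- function() {
  label_scheme(c("PAST", "CURRENT", "NON", "UNKNOWN"),
               fallback_label = "UNKNOWN")
}

## ---------------------------------------------------------------------------

new_corpus <- function(documents, scheme) {
  structure(list(documents = documents, scheme = scheme),
            class = "notephen_corpus")
}

#' Build a labeled corpus from a document table
#'
#' A corpus is an ordered collection of documents — here one document is the
#' concatenated free text of one inpatient visit — with a label scheme.
#' Document ids must be unique; labels, where present, must belong to the
#' scheme (strict mode) or the offending documents are dropped with a warning
#' (lenient mode). Empty text is rejected unless `mode = "lenient"`.
#'
#' @param documents A data.frame with columns `doc_id` (character, unique),
#'   `text` (character), `language` (`"zh"` or `"en"`), and optionally
#'   `label`.
#' @param scheme A [label_scheme()].
#' @param mode `"strict"` (default) or `"lenient"`; see Details.
#' @return An object of class `notephen_corpus` with elements `documents`
#'   (the validated data.frame) and `scheme`.
#' @export
corpus <- function(documents, scheme, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(documents), inherits(scheme, "label_scheme"))
  needed <- c("doc_id", "text", "language")
  missing_cols <- setdiff(needed, names(documents))
  if (length(missing_cols)) {
    stop("documents table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(documents)) documents$label <- NA_character_
  documents <- documents[, c("doc_id", "text", "language", "label")]
  documents$doc_id <- as.character(documents$doc_id)
  documents$text <- as.character(documents$text)
  documents$text[is.na(documents$text)] <- ""
  documents$language <- as.character(documents$language)
  documents$label <- as.character(documents$label)
  rownames(documents) <- NULL

  dup <- documents$doc_id[duplicated(documents$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_lang <- setdiff(unique(documents$language), c("zh", "en"))
  if (length(bad_lang)) {
    stop("unknown language tag(s): ", paste(bad_lang, collapse = ", "),
         call. = FALSE)
  }
  empty <- !nzchar(documents$text)
  if (any(empty) && mode == "strict") {
    stop("empty text for doc_id: ",
         paste(documents$doc_id[empty], collapse = ", "),
         " (use mode = \"lenient\" to allow)", call. = FALSE)
  }
  known <- is.na(documents$label) | documents$label %in% scheme$labels
  if (!all(known)) {
    offending <- documents$doc_id[!known]
    if (mode == "strict") {
      stop("label outside scheme for doc_id: ",
           paste(offending, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", length(offending),
            " document(s) with labels outside the scheme", call. = FALSE)
    documents <- documents[known, , drop = FALSE]
    rownames(documents) <- NULL
  }
  new_corpus(documents, scheme)
}

#' @export
print.notephen_corpus <- function(x, ...) {
  cc <- class_counts(x)
  cat("<notephen_corpus> ", nrow(x$documents), " documents; labels: ",
      paste(sprintf("%s=%d", names(cc$per_label), cc$per_label),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.notephen_corpus <- function(x) nrow(x$documents)

#' @rdname corpus
#' @param i Index vector into the documents.
#' @param x A `notephen_corpus`.
#' @export
`[.notephen_corpus` <- function(x, i) {
  docs <- x$documents[i, , drop = FALSE]
  rownames(docs) <- NULL
  new_corpus(docs, x$scheme)
}

#' Read a tagged document corpus from disk
#'
#' Supports two plain-text formats: JSON Lines (one object per line with keys
#' `doc_id`, `text`, `language` and optional `label`) and UTF-8 CSV with a
#' header row and the same columns; the free-text column is quoted so Chinese
#' text containing commas round-trips.
#'
#' @param path Path to the file.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @param scheme A [label_scheme()].
#' @param mode Passed to [corpus()]: `"strict"` rejects unknown labels and
#'   empty text, `"lenient"` drops/permits them with a warning.
#' @return A `notephen_corpus`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"), scheme,
                        mode = c("strict", "lenient")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      docs <- data.frame(doc_id = character(), text = character(),
                         language = character(), label = character(),
                         stringsAsFactors = FALSE)
      return(corpus(docs, scheme, mode = mode))
    }
    recs <- lapply(lines, jsonlite::fromJSON)
    pick <- function(r, key, default = NA_character_) {
      v <- r[[key]]
      if (is.null(v) || !length(v) || is.na(v[1L])) default else as.character(v[1L])
    }
    docs <- data.frame(
      doc_id = vapply(recs, pick, "", key = "doc_id"),
      text = vapply(recs, pick, "", key = "text", default = ""),
      language = vapply(recs, pick, "", key = "language", default = "en"),
      label = vapply(recs, pick, "", key = "label"),
      stringsAsFactors = FALSE
    )
  } else {
    docs <- utils::read.csv(path, colClasses = "character",
                            fileEncoding = "UTF-8")
  }
  corpus(docs, scheme, mode = mode)
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()]: emits JSON Lines or UTF-8 CSV such that
#' reading the file back reproduces the corpus.
#'
#' @param x A `notephen_corpus`.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "notephen_corpus"))
  docs <- x$documents
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(docs)), function(i) {
      rec <- list(doc_id = docs$doc_id[i], text = docs$text[i],
                  language = docs$language[i])
      if (!is.na(docs$label[i])) rec$label <- docs$label[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(docs, path, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
  }
  invisible(path)
}

#' Stratified train/test split of a labeled corpus
#'
#' Splits by label so each class contributes its share of the test set, with
#' per-class test counts rounded by largest remainder (small classes keep
#' proportions close to the requested fraction). The partition is exact —
#' no document is lost or duplicated — and reproducible for a fixed seed.
#'
#' @param x A fully labeled `notephen_corpus`.
#' @param test_fraction Proportion of documents for the test set, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `notephen_corpus` elements `train` and `test`.
#' @examples
#' corp <- generate_corpus(generator_config(doc_length_mean = 200, seed = 1))
#' parts <- split_corpus(corp, test_fraction = 0.2, seed = 7)
#' class_counts(parts$test)
#' @export
split_corpus <- function(x, test_fraction, seed) {
  stopifnot(inherits(x, "notephen_corpus"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  labels <- x$documents$label
  if (anyNA(labels)) stop("all documents must be labeled", call. = FALSE)
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    stop("class(es) with fewer than 2 documents cannot be stratified: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  classes <- names(tab)
  n_test <- largest_remainder(as.numeric(tab), test_fraction)
  # never empty a class's training side
  n_test <- pmin(n_test, as.integer(tab) - 1L)
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      idx <- which(labels == classes[k])
      sample(idx, n_test[k])
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  list(train = x[setdiff(seq_along(labels), test_idx)],
       test = x[test_idx])
}

#' Per-class document counts
#'
#' @param x A `notephen_corpus`.
#' @return An object of class `class_counts`: list with `per_label` (named
#'   integer vector over the scheme's labels, counting non-missing labels)
#'   and `total` (their sum).
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "notephen_corpus"))
  lab <- factor(x$documents$label, levels = x$scheme$labels)
  per <- table(lab)
  per_label <- stats::setNames(as.integer(per), names(per))
  structure(list(per_label = per_label, total = sum(per_label)),
            class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  print(c(x$per_label, Total = x$total))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Published corpus bookkeeping (shipped as plain-text fixtures).

#' Published class distributions of the two benchmark tasks
#'
#' Per-class training/test document counts as published for the smoking-status
#' challenge and for the severe-DHR corpus. These are fixtures for
#' bookkeeping and consistency checks — the underlying corpora are
#' restricted/private and are not distributed.
#'
#' @param task `"smoking"` or `"dhr"`.
#' @return A data.frame with columns `label`, `train`, `test`.
#' @export
published_distribution <- function(task = c("smoking", "dhr")) {
  task <- match.arg(task)
  path <- system.file("extdata",
                      sprintf("published_%s_distribution.csv", task),
                      package = "notephen", mustWork = TRUE)
  out <- utils::read.csv(path, colClasses = c("character", "integer",
                                              "integer"))
  out
}

#' Published archive-mining outcome counts for the severe-DHR application
#'
#' Per-subtype counts from the 9-year archive run: cases previously reported
#' through the spontaneous reporting system (SRS) and expert-confirmed cases
#' by diagnosis site. Fixture data for summary arithmetic; see
#' [summarize_alerts()] for the corresponding computation on mined alerts.
#'
#' @return A data.frame with columns `label`, `srs_reported`,
#'   `confirmed_local`, `confirmed_other`.
#' @export
published_mining_counts <- function() {
  path <- system.file("extdata", "published_dhr_mining_counts.csv",
                      package = "notephen", mustWork = TRUE)
  utils::read.csv(path, colClasses = c("character", rep("integer", 3L)))
}
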