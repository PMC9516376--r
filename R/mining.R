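#' Mine an untagged document archive for phenotype cases
#'
#' Applies a fitted pipeline to a stream of documents, one at a time (single
#' pass, constant memory per document): each document is reduced to its key
#' sentences, embedded and classified, and an alert record is emitted if and
#' only if the predicted label is a positive class — fallback predictions are
#' never alerted. Each alert carries the evidence sentences the prediction
#' was based on, to support the downstream expert review that confirms or
#' rejects the case.
#'
#' @param x A `notephen_corpus` or a data.frame of documents (columns
#'   `doc_id`, `text`, `language`); gold labels, if present, are ignored.
#' @param model A fitted [phenotyper()].
#' @param mode `"strict"` raises on malformed documents (missing id or text);
#'   `"lenient"` logs a warning and skips them.
#' @return A list of class `mining_result`: `alerts` (data.frame with
#'   `doc_id`, `predicted_label`, `evidence`, `selected_unit_count`,
#'   `empty_selection`) and `summary` (list `n_scanned`, `n_alerted`,
#'   `per_label`).
#' @seealso [summarize_alerts()]
#' @export
mine_archive <- function(x, model, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "phenotyper"))
  docs <- if (inherits(x, "notephen_corpus")) x$documents else x
  stopifnot(is.data.frame(docs))
  positive <- model$scheme$positive_labels

  alerts <- vector("list", nrow(docs))
  n_scanned <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(docs))) {
    id <- docs$doc_id[i]
    text <- docs$text[i]
    lang <- docs$language[i]
    malformed <- is.na(id) || !nzchar(id) || is.na(text) ||
      !lang %in% c("zh", "en")
    if (malformed) {
      if (mode == "strict") {
        stop("malformed document at position ", i, call. = FALSE)
      }
      n_skipped <- n_skipped + 1L
      next
    }
    n_scanned <- n_scanned + 1L
    if (is.null(model$keywords)) {
      sel_text <- text
      evidence <- character()
    } else {
      sel <- select_key_sentences(text, lang, model$keywords)
      sel_text <- sel$selected_text
      evidence <- sel$kept_sentences
    }
    v <- embed_document(sel_text, lang, model$embedder)
    pred <- predict(model$model, matrix(v, nrow = 1L))
    if (pred %in% positive) {
      alerts[[i]] <- data.frame(
        doc_id = id,
        predicted_label = pred,
        evidence = paste(evidence, collapse = " | "),
        selected_unit_count = count_units(sel_text, lang),
        empty_selection = !nzchar(sel_text),
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_skipped) {
    warning("skipped ", n_skipped, " malformed document(s)", call. = FALSE)
  }
  alerts <- do.call(rbind, alerts[!vapply(alerts, is.null, TRUE)])
  if (is.null(alerts)) {
    alerts <- data.frame(doc_id = character(), predicted_label = character(),
                         evidence = character(),
                         selected_unit_count = integer(),
                         empty_selection = logical(),
                         stringsAsFactors = FALSE)
  }
  rownames(alerts) <- NULL
  per_label <- table(factor(alerts$predicted_label, levels = positive))
  structure(
    list(alerts = alerts,
         summary = list(n_scanned = n_scanned,
                        n_alerted = nrow(alerts),
                        per_label = stats::setNames(as.integer(per_label),
                                                    names(per_label)))),
    class = "mining_result"
  )
}

#' @export
print.mining_result <- function(x, ...) {
  cat("<mining_result> scanned ", x$summary$n_scanned, ", alerted ",
      x$summary$n_alerted, "\n", sep = "")
  print(summarize_alerts(x$alerts, positive_labels = names(x$summary$per_label)))
  invisible(x)
}

#' Summarize alert records per positive class
#'
#' Tabulates mined alerts by predicted label, with a total row equal to the
#' column sum — the shape of a published case-distribution table.
#'
#' @param alerts The `alerts` data.frame of a [mine_archive()] result, or any
#'   data.frame with a `predicted_label` column.
#' @param scheme A [label_scheme()]; alternatively give `positive_labels`
#'   directly.
#' @param positive_labels Character vector of positive labels (used when
#'   `scheme` is missing).
#' @return A data.frame with columns `label` and `n_alerts`, last row
#'   `"Total"`.
#' @export
summarize_alerts <- function(alerts, scheme = NULL, positive_labels = NULL) {
  if (!is.null(scheme)) positive_labels <- scheme$positive_labels
  if (is.null(positive_labels)) {
    stop("provide `scheme` or `positive_labels`", call. = FALSE)
  }
  lab <- character()
  if (is.data.frame(alerts) && nrow(alerts)) lab <- alerts$predicted_label
  bad <- setdiff(unique(lab), positive_labels)
  if (length(bad)) {
    stop("alert labels outside the positive classes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(lab, levels = positive_labels))
  data.frame(label = c(positive_labels, "Total"),
             n_alerts = c(as.integer(counts), sum(counts)),
             stringsAsFactors = FALSE)
}
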