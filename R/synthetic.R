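## Seeded synthetic corpus generator.
##
## Emulates the statistical structure the pipeline assumes about real
## inpatient-visit documents: very long, heavy-tailed background text
## (log-normal lengths, thousands of units on average with a max an order of
## magnitude higher), a small number of informative keyword-bearing marker
## sentences in positive documents, an imbalanced label distribution, and
## either Chinese-character or space-delimited English text. The background
## ("boilerplate") sentence bank is screened to contain no active keyword
## term, so with full injection and zero leakage the corpus is perfectly
## separable by construction and the oracle test must score exactly 1 —
## noise enters only through the explicit injection/leakage probabilities.

# Keyword-free clinical boilerplate, Chinese.
zh_boilerplate <- function() {
  c("今日查房，患儿一般情况可。",
    "体温正常，饮食睡眠可。",
    "大小便未见异常。",
    "心率平稳，呼吸均匀。",
    "血压在正常范围。",
    "查体腹软，无压痛。",
    "双肺呼吸音清。",
    "心律齐，未闻及杂音。",
    "神志清，精神反应可。",
    "血常规未见明显异常。",
    "肝肾功能指标平稳。",
    "电解质大致正常。",
    "继续补液支持治疗。",
    "密切观察病情变化。",
    "患儿病情平稳，继续现有方案。",
    "复查胸片未见新发病灶。",
    "家属对病情知情。",
    "夜间睡眠安稳。",
    "今日无发热。",
    "饮食耐受可，无呕吐。",
    "腹部查体未见异常。",
    "四肢活动自如。",
    "患儿精神可，配合查体。",
    "尿常规未见异常。",
    "继续监测生命体征。",
    "明日复查血常规。",
    "患儿无咳嗽咳痰。",
    "听诊心音有力。",
    "病程记录已更新。",
    "营养状况良好。")
}

# Keyword-free clinical boilerplate, English.
en_boilerplate <- function() {
  c("Vital signs are stable.",
    "Lungs are clear to auscultation bilaterally.",
    "Heart rate and rhythm are regular.",
    "Abdomen is soft and nontender.",
    "The patient is alert and oriented.",
    "Laboratory values are within normal limits.",
    "No acute distress noted on examination.",
    "Diet and sleep are adequate.",
    "Continue current medications as prescribed.",
    "Follow up in clinic in two weeks.",
    "Chest radiograph shows no acute process.",
    "Electrolytes are within the reference range.",
    "The wound is healing well.",
    "Ambulating without assistance.",
    "Pain is controlled with oral analgesics.",
    "No fever overnight.",
    "Renal function remains stable.",
    "Family was updated at the bedside.",
    "Plan discussed with the care team.",
    "Discharge planning is in progress.")
}

# Label-specific marker sentence templates, each containing at least one
# keyword of the corresponding built-in list and distinctive wording per
# label so classes are learnable.
builtin_marker_vocab <- function(task = c("dhr", "smoking")) {
  task <- match.arg(task)
  if (task == "dhr") {
    list(
      SJS = c("患儿躯干出现红斑，伴黏膜侵蚀。",
              "考虑Stevens-Johnson综合征，予以对症处理。",
              "可见斑丘疹，部分融合成片。"),
      DIHS = c("考虑药物超敏反应综合征。",
               "全身荨麻疹伴剥脱性皮炎。",
               "面部血管性水肿明显。"),
      AS = c("患儿突发过敏性休克。",
             "出现喘鸣及支气管痉挛。",
             "伴低血容量性低血压及发绀。"),
      EB = c("考虑大疱表皮松解症。",
             "可见松弛性水疱及表皮剥脱。",
             "双下肢表皮剥离伴叶状鳞屑。")
    )
  } else {
    list(
      PAST = c("The patient quit smoking ten years ago.",
               "He is a former smoker with a remote history.",
               "Smoked one pack daily until about 2005, then stopped."),
      CURRENT = c("The patient smokes one pack per day.",
                  "Currently smoking, counseled on cessation today.",
                  "He continues active tobacco use daily."),
      NON = c("The patient denies any tobacco use.",
              "She has never smoked in her life.",
              "Nonsmoker; no cigarette use reported.")
    )
  }
}

#' Configure the synthetic corpus generator
#'
#' Defaults emulate the severe-DHR study corpus: the five-class DHR scheme at
#' its published training-set class sizes (SJS 56, DIHS 44, AS 18, EB 32,
#' NEG 323 — roughly 2:1 negative:positive), Chinese text with log-normal
#' background lengths of mean about 4000 characters and a heavy upper tail
#' (maxima above 20,000), and guaranteed keyword evidence in every positive
#' document (`keyword_injection_prob = 1`) with no leakage into fallback
#' documents (`leakage_prob = 0`).
#'
#' @param scheme A [label_scheme()] (default [scheme_dhr()]).
#' @param n_per_label Named integer vector of documents per label; names must
#'   cover the scheme's labels.
#' @param doc_length_mean Mean background length in the language's unit
#'   (characters for zh, words for en); lengths are log-normal.
#' @param doc_length_sdlog Log-scale standard deviation of the length
#'   distribution (default 0.65).
#' @param keyword_injection_prob Probability that a positive document
#'   receives 1-3 marker sentences (default 1).
#' @param leakage_prob Probability that a fallback document receives one
#'   random marker sentence (default 0).
#' @param marker_vocab Named list mapping each positive label to its marker
#'   sentence templates; every template must contain at least one term of
#'   `keywords` (validated here). `NULL` selects the built-in vocabulary for
#'   the DHR or smoking preset scheme.
#' @param language `"zh"` or `"en"`; `NULL` infers it from the scheme preset
#'   (DHR: zh, smoking: en).
#' @param keywords The active [keyword_list()] the corpus must be separable
#'   under; `NULL` selects the built-in list matching the scheme.
#' @param seed Integer seed; generation is fully reproducible per seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(scheme = scheme_dhr(),
                             n_per_label = NULL,
                             doc_length_mean = 4000,
                             doc_length_sdlog = 0.65,
                             keyword_injection_prob = 1,
                             leakage_prob = 0,
                             marker_vocab = NULL,
                             language = NULL,
                             keywords = NULL,
                             seed = 1L) {
  stopifnot(inherits(scheme, "label_scheme"),
            doc_length_mean > 0, doc_length_sdlog >= 0,
            keyword_injection_prob >= 0, keyword_injection_prob <= 1,
            leakage_prob >= 0, leakage_prob <= 1)
  is_dhr <- identical(scheme$labels, scheme_dhr()$labels)
  is_smoking <- identical(scheme$labels, scheme_smoking()$labels)
  if (is.null(language)) {
    language <- if (is_smoking) "en" else "zh"
  }
  language <- match.arg(language, c("zh", "en"))
  if (is.null(keywords)) {
    keywords <- if (is_smoking) load_builtin_keywords("smoking")
                else load_builtin_keywords("dhr_guideline")
  }
  stopifnot(inherits(keywords, "keyword_list"))
  if (is.null(n_per_label)) {
    n_per_label <- if (is_dhr) {
      c(SJS = 56L, DIHS = 44L, AS = 18L, EB = 32L, NEG = 323L)
    } else if (is_smoking) {
      c(PAST = 36L, CURRENT = 35L, NON = 66L, UNKNOWN = 252L)
    } else {
      stop("`n_per_label` must be given for a custom scheme", call. = FALSE)
    }
  }
  if (!all(scheme$labels %in% names(n_per_label))) {
    stop("`n_per_label` must name every label of the scheme", call. = FALSE)
  }
  n_per_label <- n_per_label[scheme$labels]
  if (any(n_per_label < 0)) stop("negative document count", call. = FALSE)

  if (is.null(marker_vocab)) {
    marker_vocab <- if (is_dhr) builtin_marker_vocab("dhr")
                    else if (is_smoking) builtin_marker_vocab("smoking")
                    else stop("`marker_vocab` must be given for a custom scheme",
                              call. = FALSE)
  }
  missing_markers <- setdiff(scheme$positive_labels, names(marker_vocab))
  if (length(missing_markers)) {
    stop("marker_vocab lacks templates for: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  }
  for (lbl in scheme$positive_labels) {
    tmpl <- marker_vocab[[lbl]]
    if (!length(tmpl)) {
      stop("marker_vocab has no templates for ", lbl, call. = FALSE)
    }
    ok <- contains_keyword(tmpl, keywords)
    if (!all(ok)) {
      stop("marker template for ", lbl,
           " contains no keyword term: ", tmpl[!ok][1L], call. = FALSE)
    }
  }
  bank <- if (language == "zh") zh_boilerplate() else en_boilerplate()
  leaky <- contains_keyword(bank, keywords)
  if (any(leaky)) {
    stop("internal boilerplate bank leaks keyword(s): ",
         paste(bank[leaky], collapse = " / "), call. = FALSE)
  }
  structure(
    list(scheme = scheme, n_per_label = n_per_label,
         doc_length_mean = doc_length_mean,
         doc_length_sdlog = doc_length_sdlog,
         keyword_injection_prob = keyword_injection_prob,
         leakage_prob = leakage_prob,
         marker_vocab = marker_vocab,
         language = language,
         keywords = keywords,
         bank = bank,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# One synthetic document's text: background sentences up to the target
# length, with optional marker sentences spliced in at random positions.
compose_document <- function(config, target_units, markers) {
  bank <- config$bank
  bank_units <- count_units(bank, config$language)
  n_guess <- max(1L, ceiling(target_units / mean(bank_units)) + 5L)
  picks <- sample.int(length(bank), n_guess, replace = TRUE)
  cum <- cumsum(bank_units[picks])
  stop_at <- which(cum >= target_units)[1L]
  if (is.na(stop_at)) stop_at <- n_guess
  sentences <- bank[picks[seq_len(stop_at)]]
  if (length(markers)) {
    pos <- sort(sample.int(length(sentences) + 1L, length(markers),
                           replace = TRUE))
    out <- character(length(sentences) + length(markers))
    take <- pos + seq_along(pos) - 1L
    out[take] <- markers
    out[-take] <- sentences
    sentences <- out
  }
  sep <- if (config$language == "zh") "" else " "
  paste(sentences, collapse = sep)
}

#' Generate a labeled synthetic corpus
#'
#' For each label and each of its `n_per_label` documents: background
#' sentences are drawn from the keyword-free boilerplate bank until the
#' document reaches its sampled log-normal length; a positive-label document
#' receives, with probability `keyword_injection_prob`, one to three of its
#' label's marker sentences at random positions; a fallback-label document
#' receives, with probability `leakage_prob`, one random marker sentence.
#' Byte-identical output for a fixed config and seed.
#'
#' @param config A [generator_config()].
#' @return A labeled `notephen_corpus`.
#' @examples
#' cc <- class_counts(generate_corpus(generator_config(seed = 42)))
#' cc$total # 473 documents in the default DHR shape
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  scheme <- config$scheme
  with_seed(config$seed, {
    rows <- list()
    for (lbl in scheme$labels) {
      n <- config$n_per_label[[lbl]]
      if (!n) next
      is_pos <- lbl != scheme$fallback_label
      texts <- vapply(seq_len(n), function(k) {
        target <- stats::rlnorm(
          1L,
          meanlog = log(config$doc_length_mean) -
            config$doc_length_sdlog^2 / 2,
          sdlog = config$doc_length_sdlog
        )
        target <- max(30, target)
        markers <- character()
        if (is_pos) {
          if (stats::runif(1L) <= config$keyword_injection_prob) {
            tmpl <- config$marker_vocab[[lbl]]
            k_m <- sample.int(3L, 1L)
            markers <- tmpl[sample.int(length(tmpl), min(k_m, length(tmpl)))]
          }
        } else if (config$leakage_prob > 0 &&
                   stats::runif(1L) <= config$leakage_prob) {
          all_markers <- unlist(config$marker_vocab, use.names = FALSE)
          markers <- all_markers[sample.int(length(all_markers), 1L)]
        }
        compose_document(config, target, markers)
      }, "")
      rows[[lbl]] <- data.frame(
        doc_id = sprintf("%s-%04d", tolower(lbl), seq_len(n)),
        text = texts,
        language = config$language,
        label = lbl,
        stringsAsFactors = FALSE
      )
    }
    docs <- do.call(rbind, rows)
    rownames(docs) <- NULL
    corpus(docs, scheme)
  })
}

#' Generate an untagged synthetic archive with a withheld truth table
#'
#' Mining-stage fixture: emits an unlabeled document stream plus the hidden
#' true labels, so mining precision/recall can be scored on synthetic data.
#' The number of positive documents is `round(n_docs * positive_rate)`,
#' apportioned across the positive labels by largest remainder; document
#' order is shuffled (reproducibly) so labels are not inferable from
#' position.
#'
#' @param config A [generator_config()] (its `n_per_label` is ignored here).
#' @param n_docs Total number of documents.
#' @param positive_rate Proportion of positive documents, in `[0, 1)`.
#' @return A list with `documents` (an unlabeled `notephen_corpus`) and
#'   `truth` (data.frame `doc_id`, `true_label`).
#' @export
generate_archive <- function(config, n_docs, positive_rate) {
  stopifnot(inherits(config, "generator_config"),
            n_docs >= 0, positive_rate >= 0, positive_rate < 1)
  scheme <- config$scheme
  pos_labels <- scheme$positive_labels
  n_pos_total <- round(n_docs * positive_rate)
  n_pos <- largest_remainder(rep(1, length(pos_labels)),
                             n_pos_total / length(pos_labels))
  n_per <- stats::setNames(c(n_pos, n_docs - sum(n_pos)),
                           c(pos_labels, scheme$fallback_label))
  cfg <- config
  cfg$n_per_label <- n_per[scheme$labels]
  labeled <- generate_corpus(cfg)
  docs <- labeled$documents
  perm <- with_seed(config$seed + 7L, sample.int(nrow(docs)))
  docs <- docs[perm, , drop = FALSE]
  docs$doc_id <- sprintf("arch-%05d", seq_len(nrow(docs)))
  truth <- data.frame(doc_id = docs$doc_id, true_label = docs$label,
                      stringsAsFactors = FALSE)
  docs$label <- NA_character_
  rownames(docs) <- NULL
  list(documents = corpus(docs, scheme, mode = "lenient"), truth = truth)
}
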