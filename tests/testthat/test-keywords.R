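test_that("built-in keyword lists reproduce the published terms", {
  sk <- load_builtin_keywords("smoking")
  expect_equal(sk$terms, c("cigarette", "smoke", "smoked", "smoker",
                           "smokes", "smoking", "tobacco"))
  expect_equal(sk$match_mode, "word_boundary")

  gk <- load_builtin_keywords("dhr_guideline")
  expect_true("Stevens-Johnson综合征" %in% gk$terms)
  expect_true("肾上腺素" %in% gk$terms)
  expect_true(all(c("AS", "EB", "TEN", "SJS", "DIHS") %in% gk$terms))
  expect_equal(gk$match_mode, "substring")
  expect_false(any(duplicated(gk$terms)))
  expect_false(any(!nzchar(gk$terms)))

  # determinism: loading twice gives identical lists
  expect_identical(gk, load_builtin_keywords("dhr_guideline"))
  expect_error(load_builtin_keywords("unknown_task"))
})

test_that("keyword matching respects the match mode", {
  gk <- load_builtin_keywords("dhr_guideline")
  sk <- load_builtin_keywords("smoking")
  expect_true(contains_keyword("患儿出现红斑。", gk))
  expect_true(contains_keyword("He smokes daily.", sk))
  expect_false(contains_keyword("No relevant history.", sk))
  # word-boundary mode: no firing inside larger tokens; case-insensitive
  expect_false(contains_keyword("behind the smokescreen today", sk))
  expect_true(contains_keyword("TOBACCO use denied", sk))
  # vectorized and total
  res <- contains_keyword(c("smokes", "walks", NA), sk)
  expect_identical(res, c(TRUE, FALSE, FALSE))
})

test_that("keyword lists save and load as one term per line", {
  kw <- keyword_list(c("beta", "alpha", "beta"), match_mode = "word_boundary")
  expect_equal(kw$terms, c("beta", "alpha")) # dedup keeps first occurrence
  path <- withr::local_tempfile(fileext = ".txt")
  write_keywords(kw, path)
  back <- read_keywords(path, match_mode = "word_boundary")
  expect_equal(back$terms, kw$terms)
  expect_error(keyword_list(c("ok", "")), "empty")
})

test_that("TF-IDF keyword derivation matches an independent dense oracle", {
  texts <- c("severe rash on trunk today", "new rash with fever noted",
             "routine visit no issues today", "stable vitals with fever chart")
  labels <- c("CASE", "CASE", "NEG", "NEG")
  corp <- make_corpus(texts, labels)
  kw <- extract_tfidf_keywords(corp, top_n = 1000)
  expected <- brute_tfidf_scores(texts, labels, fallback = "NEG")
  expect_setequal(kw$terms, names(expected))
  got <- attr(kw, "score")[names(expected)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  # "rash" occurs in both positives and no negative: retained, top-scoring
  expect_equal(kw$terms[1], "rash")
  expect_gt(attr(kw, "score")[["rash"]], 0)
})

test_that("TF-IDF candidate filtering removes digits and foreign script", {
  texts <- c("covid19 rash seen here", "rash noted again today",
             "normal check up today", "all stable and well")
  corp <- make_corpus(texts, c("CASE", "CASE", "NEG", "NEG"))
  kw <- extract_tfidf_keywords(corp, top_n = 1000)
  expect_false("covid19" %in% kw$terms)
  # zh corpora keep Han-only terms
  zh <- make_corpus(c("患儿出现红斑X1。", "患儿出现红斑。", "体温正常。", "查体无异常。"),
                    c("CASE", "CASE", "NEG", "NEG"), language = "zh")
  kwz <- extract_tfidf_keywords(zh, top_n = 1000)
  expect_true(all(grepl("^\\p{Han}+$", kwz$terms, perl = TRUE)))
})

test_that("TF-IDF derivation obeys its contracts", {
  corp <- generate_corpus(small_config(seed = 5))
  top_n <- 50
  kw <- extract_tfidf_keywords(corp, top_n = top_n)
  expect_lte(length(kw$terms), top_n)
  expect_equal(kw$provenance, "tfidf_derived")
  # scores strictly positive and sorted descending
  sc <- attr(kw, "score")
  expect_true(all(sc > 0))
  expect_true(all(diff(sc) <= 0))

  # a marker token present in every positive and no negative is recovered
  # with the maximal score
  texts <- c("erythema seen on exam today", "widespread erythema noted now",
             "erythema of the trunk persists",
             "normal check up visit", "doing well at home", "stable and well")
  labels <- c("CASE", "CASE", "CASE", "NEG", "NEG", "NEG")
  kw2 <- extract_tfidf_keywords(make_corpus(texts, labels), top_n = 1000)
  expect_equal(kw2$terms[1], "erythema")

  # single-class corpora are rejected
  mono <- make_corpus(c("a b.", "c d."), c("NEG", "NEG"))
  expect_error(extract_tfidf_keywords(mono), "positive")
})
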