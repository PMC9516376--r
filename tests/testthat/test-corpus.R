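test_that("JSONL corpora parse, count and round-trip", {
  scheme <- scheme_dhr()
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"doc_id":"a","text":"患儿出现红斑。","language":"zh","label":"SJS"}',
    '{"doc_id":"b","text":"体温正常。","language":"zh","label":"NEG"}',
    '{"doc_id":"c","text":"查体无异常。","language":"zh","label":"NEG"}'
  ), path, useBytes = TRUE)
  corp <- read_corpus(path, scheme = scheme)
  expect_equal(length(corp), 3L)
  cc <- class_counts(corp)
  expect_equal(cc$per_label[["SJS"]], 1L)
  expect_equal(cc$per_label[["NEG"]], 2L)
  expect_equal(cc$total, 3L)

  out <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, out, format = "jsonl")
  expect_equal(read_corpus(out, scheme = scheme)$documents, corp$documents)

  # empty file -> empty corpus
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty)
  expect_equal(class_counts(read_corpus(empty, scheme = scheme))$total, 0L)
})

test_that("CSV round-trips Chinese free text containing commas", {
  scheme <- scheme_dhr()
  corp <- make_corpus(c("患儿发热，伴咳嗽。", "今日查房，情况可。"),
                      c("SJS", "NEG"), language = "zh", scheme = scheme)
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, path, format = "csv")
  back <- read_corpus(path, format = "csv", scheme = scheme)
  expect_equal(back$documents, corp$documents)
})

test_that("corpus invariants are enforced", {
  scheme <- tiny_scheme()
  docs <- data.frame(doc_id = c("x", "x"), text = c("a.", "b."),
                     language = "en", label = "NEG")
  expect_error(corpus(docs, scheme), "duplicate doc_id.*x")

  docs2 <- data.frame(doc_id = c("a", "b"), text = c("t.", "u."),
                      language = "en", label = c("CASE", "WHAT"))
  expect_error(corpus(docs2, scheme, mode = "strict"), "outside scheme")
  expect_warning(lenient <- corpus(docs2, scheme, mode = "lenient"),
                 "dropping 1")
  expect_equal(lenient$documents$doc_id, "a")

  docs3 <- data.frame(doc_id = "a", text = "", language = "en", label = "NEG")
  expect_error(corpus(docs3, scheme, mode = "strict"), "empty text")
  expect_silent(corpus(docs3, scheme, mode = "lenient"))
})

test_that("stratified split allocates per class and is an exact partition", {
  scheme <- label_scheme(c("A", "B"), "B")
  corp <- make_corpus(rep(c("alpha text.", "beta text."), each = 50),
                      rep(c("A", "B"), each = 50), scheme = scheme)
  parts <- split_corpus(corp, test_fraction = 0.2, seed = 7)
  cc <- class_counts(parts$test)
  expect_equal(unname(cc$per_label), c(10L, 10L))

  # determinism
  parts2 <- split_corpus(corp, test_fraction = 0.2, seed = 7)
  expect_identical(parts$test$documents, parts2$test$documents)

  # partition property over several seeds and fractions
  for (seed in c(1, 2, 99)) {
    p <- split_corpus(corp, test_fraction = 0.3, seed = seed)
    ids <- c(p$train$documents$doc_id, p$test$documents$doc_id)
    expect_equal(sort(ids), sort(corp$documents$doc_id))
    expect_length(intersect(p$train$documents$doc_id,
                            p$test$documents$doc_id), 0L)
  }

  # single-class corpus still splits
  one <- make_corpus(rep("only text.", 10), rep("B", 10), scheme = scheme)
  p1 <- split_corpus(one, test_fraction = 0.5, seed = 1)
  expect_equal(length(p1$train), 5L)
  expect_equal(length(p1$test), 5L)

  # a class with one member cannot be stratified
  bad <- make_corpus(c("a.", "b.", "c."), c("A", "B", "B"), scheme = scheme)
  expect_error(split_corpus(bad, 0.5, seed = 1), "fewer than 2.*A")
})

test_that("class counts are order-invariant and published totals add up", {
  corp <- make_corpus(c("a.", "b.", "c."), c("CASE", "NEG", "CASE"))
  cc1 <- class_counts(corp)
  cc2 <- class_counts(corp[c(3, 1, 2)])
  expect_identical(cc1$per_label, cc2$per_label)
  expect_equal(cc1$total, sum(cc1$per_label))

  dhr <- published_distribution("dhr")
  expect_equal(sum(dhr$train), 473L)
  expect_equal(sum(dhr$test), 110L)
  smoking <- published_distribution("smoking")
  expect_equal(sum(smoking$train), 389L)
  expect_equal(sum(smoking$test), 101L)
})
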