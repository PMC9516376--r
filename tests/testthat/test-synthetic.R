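test_that("generation is byte-identical for a fixed config and seed", {
  c1 <- generate_corpus(small_config(seed = 33))
  c2 <- generate_corpus(small_config(seed = 33))
  expect_identical(c1$documents, c2$documents)
  c3 <- generate_corpus(small_config(seed = 34))
  expect_false(identical(c1$documents$text, c3$documents$text))
})

test_that("generated class counts follow the config", {
  cfg <- generator_config(n_per_label = c(SJS = 10, DIHS = 0, AS = 0, EB = 0,
                                          NEG = 20),
                          doc_length_mean = 200, seed = 2)
  cc <- class_counts(generate_corpus(cfg))
  expect_equal(cc$per_label[["SJS"]], 10L)
  expect_equal(cc$per_label[["NEG"]], 20L)
  expect_equal(cc$total, 30L)
  # default shape reproduces the published training distribution
  cc_def <- class_counts(generate_corpus(small_config(seed = 1)))
  expect_equal(unname(cc_def$per_label),
               c(56L, 44L, 18L, 32L, 323L))
})

test_that("full injection and zero leakage give a perfect oracle, any seed", {
  kw <- load_builtin_keywords("dhr_guideline")
  for (seed in c(5, 17, 91)) {
    corp <- generate_corpus(small_config(seed = seed))
    expect_equal(oracle_test(corp, kw)$micro_f1, 1)
  }
  # leakage puts keywords into fallback documents but cannot break the
  # oracle rule (keyword-bearing documents keep their gold tag)
  leaky <- generate_corpus(small_config(seed = 3, leakage_prob = 1))
  expect_equal(oracle_test(leaky, kw)$micro_f1, 1)
  neg_texts <- leaky$documents$text[leaky$documents$label == "NEG"]
  expect_true(all(contains_keyword(neg_texts, kw)))
})

test_that("partial injection produces binomially many oracle errors", {
  kw <- load_builtin_keywords("dhr_guideline")
  p_miss <- 0.1
  cfg <- small_config(seed = 44, keyword_injection_prob = 1 - p_miss,
                      n_per_label = c(SJS = 100, DIHS = 100, AS = 100,
                                      EB = 100, NEG = 100))
  corp <- generate_corpus(cfg)
  ot <- oracle_test(corp, kw)
  n_pos <- 400
  bounds <- stats::qbinom(c(0.005, 0.995), n_pos, p_miss)
  expect_gte(ot$n_errors, bounds[1])
  expect_lte(ot$n_errors, bounds[2])
  # every error is a keyword-free positive
  docs <- corp$documents
  wrong <- ot$predictions != docs$label
  expect_true(all(docs$label[wrong] != "NEG"))
  expect_false(any(contains_keyword(docs$text[wrong], kw)))
})

test_that("background lengths match the configured distribution", {
  cfg <- generator_config(n_per_label = c(SJS = 0, DIHS = 0, AS = 0, EB = 0,
                                          NEG = 150),
                          doc_length_mean = 1000, seed = 10)
  corp <- generate_corpus(cfg)
  st <- length_stats(corp)
  expect_gt(st$mean_units, 0.9 * 1000)
  expect_lt(st$mean_units, 1.1 * 1000)
  expect_gt(st$max_units, st$mean_units)
})

test_that("marker templates without keywords are rejected at config time", {
  expect_error(
    generator_config(marker_vocab = list(SJS = "无关句子。",
                                         DIHS = "考虑药物超敏反应综合征。",
                                         AS = "患儿突发过敏性休克。",
                                         EB = "考虑大疱表皮松解症。"),
                     seed = 1),
    "contains no keyword")
})

test_that("archives carry a withheld truth table with exact allocation", {
  arch <- generate_archive(small_config(seed = 6), n_docs = 100,
                           positive_rate = 0.05)
  expect_equal(nrow(arch$truth), 100L)
  expect_equal(sum(arch$truth$true_label != "NEG"), 5L)
  expect_true(all(is.na(arch$documents$documents$label)))
  expect_identical(arch$documents$documents$doc_id, arch$truth$doc_id)

  # zero positive rate -> all fallback
  none <- generate_archive(small_config(seed = 6), n_docs = 30,
                           positive_rate = 0)
  expect_true(all(none$truth$true_label == "NEG"))

  # seeded rerun identical
  again <- generate_archive(small_config(seed = 6), n_docs = 100,
                            positive_rate = 0.05)
  expect_identical(arch$documents$documents, again$documents$documents)
  expect_identical(arch$truth, again$truth)
})
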