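test_that("micro-F1 agrees with a brute-force tally and equals accuracy", {
  expect_equal(micro_f1(c("A", "A", "B", "N"), c("A", "B", "B", "N")), 0.75)
  expect_equal(micro_f1(c("A", "B"), c("A", "B")), 1)

  labels <- c("SJS", "DIHS", "AS", "EB", "NEG")
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    gold <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    f1 <- micro_f1(gold, pred)
    expect_equal(f1, brute_micro_f1(gold, pred), tolerance = 1e-12)
    expect_equal(f1, mean(gold == pred), tolerance = 1e-12)
  }

  expect_error(micro_f1(c("A", "B"), "A"), "length")
  expect_error(micro_f1(character(), character()), "empty")
})

test_that("evaluation report satisfies the pooled-count identities", {
  set.seed(7)
  gold <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 60, replace = TRUE)
  rep_ <- evaluation_report(gold, pred)
  with(rep_$per_label, {
    expect_equal(sum(tp) + sum(fn), rep_$n_documents)
    expect_equal(sum(tp) + sum(fp), rep_$n_documents)
  })
  tp_sum <- sum(rep_$per_label$tp)
  fp_sum <- sum(rep_$per_label$fp)
  fn_sum <- sum(rep_$per_label$fn)
  expect_equal(rep_$micro_f1, 2 * tp_sum / (2 * tp_sum + fp_sum + fn_sum))
  expect_equal(sum(rep_$confusion), 60)
})

# fixed separable three-class vectors reused below
separable_xy <- function(n = 120, d = 20, seed = 3) {
  set.seed(seed)
  y <- sample(c("A", "B", "C"), n, replace = TRUE)
  mu <- list(A = c(rep(3, 5), rep(0, d - 5)),
             B = c(rep(0, 5), rep(3, 5), rep(0, d - 10)),
             C = c(rep(0, 10), rep(3, 5), rep(0, d - 15)))
  x <- t(vapply(y, function(l) mu[[l]] + stats::rnorm(d, sd = 0.3),
                numeric(d)))
  list(x = x, y = y)
}

test_that("grid search recovers separable classes with both families", {
  dat <- separable_xy()
  for (family in c("sgd_linear", "svc")) {
    m <- grid_search_fit(dat$x, dat$y, family = family, folds = 10, seed = 5)
    expect_gte(m$cv_score, 0.95)
    expect_gte(micro_f1(dat$y, predict(m, dat$x)), 0.95)
  }
})

test_that("grid search is deterministic and honors one-point grids", {
  dat <- separable_xy(n = 80)
  g1 <- grid_search_fit(dat$x, dat$y, family = "sgd_linear", seed = 11)
  g2 <- grid_search_fit(dat$x, dat$y, family = "sgd_linear", seed = 11)
  expect_identical(g1$chosen, g2$chosen)
  expect_identical(g1$cv_score, g2$cv_score)
  expect_identical(coef(g1), coef(g2))
  expect_identical(predict(g1, dat$x), predict(g2, dat$x))

  one <- data.frame(kernel = "linear", cost = 1)
  m1 <- grid_search_fit(dat$x, dat$y, family = "svc", grid = one, seed = 2)
  expect_identical(m1$chosen, list(kernel = "linear", cost = 1))
  expect_equal(m1$cv_score, m1$cv_results$cv_micro_f1[1])
  expect_identical(unlist(m1$chosen),
                   unlist(m1$cv_results[1, c("kernel", "cost")]))
})

test_that("grid search reduces folds for small classes and rejects bad input", {
  dat <- separable_xy(n = 40)
  y <- dat$y
  y[y == "C"] <- "A"
  y[1:4] <- "C" # class C has 4 members < 10 folds
  expect_warning(m <- grid_search_fit(dat$x, y, family = "svc",
                                      grid = data.frame(kernel = "linear",
                                                        cost = 1),
                                      folds = 10, seed = 1),
                 "reducing CV folds to 4")
  expect_equal(m$folds, 4L)

  expect_error(grid_search_fit(dat$x, rep("A", nrow(dat$x)), family = "svc"),
               "single class")
  expect_error(grid_search_fit(dat$x, dat$y, family = "svc",
                               grid = data.frame()), "empty")
})

test_that("prediction is deterministic, order-equivariant, dim-checked", {
  dat <- separable_xy(n = 90)
  m <- grid_search_fit(dat$x, dat$y, family = "svc",
                       grid = data.frame(kernel = "linear", cost = 1),
                       seed = 3)
  p <- predict(m, dat$x)
  perm <- sample(nrow(dat$x))
  expect_identical(predict(m, dat$x[perm, ]), p[perm])
  expect_error(predict(m, dat$x[, 1:5]), "dimension")
})

test_that("empty-evidence documents map to the fallback label", {
  # classifier trained with fallback docs embedded as zero vectors (empty
  # selection) learns to send the zero vector to the fallback class
  kw <- load_builtin_keywords("dhr_guideline")
  corp <- generate_corpus(small_config(seed = 14))
  fit <- phenotyper(corp, keywords = kw,
                    embedder = embedder_config(dim = 128),
                    grid = data.frame(kernel = "linear", cost = 1),
                    seed = 1)
  zero <- matrix(0, nrow = 1, ncol = 128)
  expect_equal(predict(fit$model, zero), "NEG")
})
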