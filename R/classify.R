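#' Micro-averaged F1 score
#'
#' True positives, false positives and false negatives are tallied per class
#' and pooled over all classes before the F1 formula is applied:
#' `2 * TP / (2 * TP + FP + FN)`. For single-label multiclass prediction —
#' the setting here — every error is one false positive for the predicted
#' class and one false negative for the gold class, so the pooled score
#' coincides with accuracy; it is reported as micro-F1 for comparability with
#' the phenotyping literature.
#'
#' @param gold Character vector of gold labels.
#' @param pred Character vector of predicted labels, same length.
#' @return A number in `[0, 1]`.
#' @examples
#' micro_f1(c("A", "A", "B", "N"), c("A", "B", "B", "N")) # 0.75
#' @export
micro_f1 <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must have the same length", call. = FALSE)
  }
  if (!length(gold)) stop("empty label sequences", call. = FALSE)
  if (anyNA(gold) || anyNA(pred)) stop("missing labels", call. = FALSE)
  classes <- union(gold, pred)
  tp <- fp <- fn <- 0L
  for (cl in classes) {
    tp <- tp + sum(gold == cl & pred == cl)
    fp <- fp + sum(gold != cl & pred == cl)
    fn <- fn + sum(gold == cl & pred != cl)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Full evaluation report for a multiclass prediction
#'
#' @param gold,pred Label vectors of equal length.
#' @param scheme Optional [label_scheme()] fixing the label order of the
#'   confusion matrix.
#' @return A list of class `evaluation_report`: `confusion` (gold rows x
#'   predicted columns), `per_label` data.frame of TP/FP/FN, `micro_f1`, and
#'   `n_documents`.
#' @export
evaluation_report <- function(gold, pred, scheme = NULL) {
  labels <- if (!is.null(scheme)) scheme$labels else sort(union(gold, pred))
  g <- factor(gold, levels = labels)
  p <- factor(pred, levels = labels)
  if (anyNA(g) || anyNA(p)) stop("labels outside the scheme", call. = FALSE)
  confusion <- table(gold = g, predicted = p)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  structure(
    list(confusion = confusion,
         per_label = data.frame(label = labels, tp = as.integer(tp),
                                fp = as.integer(fp), fn = as.integer(fn)),
         micro_f1 = micro_f1(gold, pred),
         n_documents = length(gold)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over", x$n_documents, "documents\n")
  print(x$confusion)
  cat(sprintf("micro-averaged F1: %.4f\n", x$micro_f1))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Binary learners used one-vs-rest.

# Averaged minibatch SGD for a regularized linear classifier.
# y in {-1, +1}; loss "hinge" or "log"; learning rate 1 / (alpha * t + 1).
sgd_binary_fit <- function(x, y, loss, alpha, epochs = 30L, batch = 32L) {
  n <- nrow(x)
  d <- ncol(x)
  w <- numeric(d)
  b <- 0
  w_avg <- numeric(d)
  b_avg <- 0
  n_avg <- 0L
  t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      t <- t + 1L
      eta <- 1 / (alpha * t + 1)
      sc <- drop(xb %*% w) + b
      if (loss == "hinge") {
        viol <- yb * sc < 1
        if (any(viol)) {
          gw <- -crossprod(xb[viol, , drop = FALSE], yb[viol]) / length(idx)
          gb <- -sum(yb[viol]) / length(idx)
        } else {
          gw <- numeric(d)
          gb <- 0
        }
      } else { # log loss
        g <- -yb / (1 + exp(yb * sc))
        gw <- crossprod(xb, g) / length(idx)
        gb <- sum(g) / length(idx)
      }
      w <- w - eta * (alpha * w + drop(gw))
      b <- b - eta * gb
      if (ep > epochs / 2) {
        w_avg <- w_avg + w
        b_avg <- b_avg + b
        n_avg <- n_avg + 1L
      }
    }
  }
  if (n_avg > 0L) {
    w <- w_avg / n_avg
    b <- b_avg / n_avg
  }
  list(w = w, b = b)
}

sgd_binary_score <- function(fit, x) drop(x %*% fit$w) + fit$b

#' @importFrom e1071 svm
svc_binary_fit <- function(x, y, kernel, cost) {
  yf <- factor(ifelse(y > 0, "pos", "rest"), levels = c("pos", "rest"))
  e1071::svm(x = x, y = yf,
             kernel = if (kernel == "rbf") "radial" else kernel,
             cost = cost, scale = FALSE, probability = FALSE)
}

svc_binary_score <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value toward the class named first in the
  # column label; flip if "rest" comes first
  s <- dv[, 1L]
  if (startsWith(colnames(dv)[1L], "rest")) s <- -s
  as.numeric(s)
}

# One-vs-rest fit over all classes. Returns per-class binary fits; a class
# absent from the training labels gets a NULL fit scoring -Inf.
ovr_fit <- function(x, y, classes, family, params) {
  fits <- lapply(classes, function(cl) {
    yb <- ifelse(y == cl, 1, -1)
    if (all(yb < 0)) return(NULL)
    if (all(yb > 0)) return(list(constant = Inf))
    if (family == "sgd_linear") {
      sgd_binary_fit(x, yb, loss = params$loss, alpha = params$alpha)
    } else {
      svc_binary_fit(x, yb, kernel = params$kernel, cost = params$cost)
    }
  })
  names(fits) <- classes
  fits
}

ovr_scores <- function(fits, x, family) {
  scores <- vapply(fits, function(f) {
    if (is.null(f)) return(rep(-Inf, nrow(x)))
    if (!is.null(f$constant)) return(rep(f$constant, nrow(x)))
    if (family == "sgd_linear") sgd_binary_score(f, x) else svc_binary_score(f, x)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L,
                                      dimnames = list(NULL, names(fits)))
  scores
}

default_grid <- function(family) {
  if (family == "sgd_linear") {
    expand.grid(loss = c("hinge", "log"), alpha = 10^seq(-5, -1),
                stringsAsFactors = FALSE)
  } else {
    expand.grid(kernel = c("linear", "rbf"), cost = c(0.1, 1, 10, 100),
                stringsAsFactors = FALSE)
  }
}

# Stratified fold ids (1..folds), seeded.
stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Grid-searched classifier over document vectors
#'
#' Trains a multiclass classifier on fixed-dimension document vectors with an
#' automatic grid search: every grid point is scored by stratified k-fold
#' cross-validated micro-F1 (mean over folds), the best point (ties broken by
#' grid order) is refit on all the training data. Two families are available,
#' both handled one-vs-rest: `"sgd_linear"`, a regularized linear model
#' trained by averaged minibatch stochastic gradient descent with hinge or
#' log loss, and `"svc"`, support-vector classification backed by libsvm
#' (package e1071).
#'
#' @param x Numeric matrix of document vectors (rows = documents).
#' @param y Character vector of labels, one per row of `x`.
#' @param family `"svc"` (default) or `"sgd_linear"`.
#' @param grid A data.frame of hyperparameter combinations (columns
#'   `loss`/`alpha` for sgd_linear, `kernel`/`cost` for svc); `NULL` uses the
#'   default grid.
#' @param folds Number of CV folds (default 10); automatically reduced with a
#'   warning when the smallest class has fewer members.
#' @param seed Integer seed controlling fold assignment and SGD shuffling;
#'   fixed seed implies identical results.
#' @param classes Optional label order (defaults to order of appearance).
#' @return An object of class `notephen_model` with elements `family`,
#'   `chosen` (the selected hyperparameters), `cv_score`, `cv_results`,
#'   `classes`, `dim` and the fitted one-vs-rest models.
#' @seealso [phenotyper()] for the corpus-level interface.
#' @export
grid_search_fit <- function(x, y, family = c("svc", "sgd_linear"),
                            grid = NULL, folds = 10L, seed = 1L,
                            classes = NULL) {
  family <- match.arg(family)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  if (anyNA(y)) stop("missing labels", call. = FALSE)
  if (is.null(classes)) classes <- unique(y)
  if (!all(y %in% classes)) stop("labels outside `classes`", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grid(family)
  if (!is.data.frame(grid) || !nrow(grid)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  grid <- as.data.frame(lapply(grid, function(col) {
    attributes(col) <- NULL
    col
  }), stringsAsFactors = FALSE)
  min_class <- min(table(y))
  folds <- as.integer(folds)
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning("smallest class has ", min_class,
            " members; reducing CV folds to ", folds, call. = FALSE)
  }
  fold_id <- stratified_folds(y, folds, seed)

  cv_scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fits <- with_seed(seed + 1000L * g + f, {
        ovr_fit(x[tr, , drop = FALSE], y[tr], classes, family, params)
      })
      sc <- ovr_scores(fits, x[!tr, , drop = FALSE], family)
      pred <- classes[max.col(sc, ties.method = "first")]
      micro_f1(y[!tr], pred)
    }, numeric(1L))
    mean(per_fold)
  }, numeric(1L))

  best <- which.max(cv_scores)
  chosen <- as.list(grid[best, , drop = FALSE])
  fits <- with_seed(seed + 999983L, ovr_fit(x, y, classes, family, chosen))
  structure(
    list(family = family,
         chosen = chosen,
         cv_score = cv_scores[best],
         cv_results = cbind(grid, cv_micro_f1 = cv_scores),
         folds = folds,
         seed = as.integer(seed),
         classes = classes,
         dim = ncol(x),
         fits = fits),
    class = "notephen_model"
  )
}

#' @export
print.notephen_model <- function(x, ...) {
  cat("<notephen_model> family:", x$family, "\n")
  cat("  chosen:", paste(names(x$chosen), unlist(x$chosen), sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  CV micro-F1 (%d-fold): %.4f\n", x$folds, x$cv_score))
  invisible(x)
}

#' @export
predict.notephen_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$dim) {
    stop("vector dimension ", ncol(newdata), " does not match model dim ",
         object$dim, call. = FALSE)
  }
  if (!nrow(newdata)) return(character())
  sc <- ovr_scores(object$fits, newdata, object$family)
  object$classes[max.col(sc, ties.method = "first")]
}

#' @export
coef.notephen_model <- function(object, ...) {
  if (object$family != "sgd_linear") {
    stop("coefficients are only available for the sgd_linear family",
         call. = FALSE)
  }
  w <- vapply(object$fits, function(f) f$w, numeric(object$dim))
  b <- vapply(object$fits, function(f) f$b, numeric(1L))
  rbind(w, intercept = b)
}
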