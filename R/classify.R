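#' Classifier configuration
#'
#' Settings for the maximum-margin classifier used by the cross-validation
#' protocols. Defaults: radial-basis kernel, cost 1, library-default gamma
#' (`1 / ncol(x)`), and standardization of features using statistics computed
#' on the training portion only.
#'
#' @param kernel One of `"radial"`, `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param cost Positive regularization constant.
#' @param gamma Kernel width, or `NULL` for the library default.
#' @param standardize Center/scale features with training-fold statistics.
#' @return A list of class `"svm_config"`.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL,
                       standardize = TRUE) {
  kernel <- match.arg(kernel, c("radial", "linear", "polynomial", "sigmoid"))
  stopifnot(is.numeric(cost), cost > 0)
  structure(
    list(kernel = kernel, cost = cost, gamma = gamma,
         standardize = isTRUE(standardize)),
    class = "svm_config"
  )
}

check_features <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) {
    stop("feature rows and labels differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  list(x = x, y = labels)
}

#' Train a maximum-margin classifier and predict test labels
#'
#' Features are standardized with the training fold's mean and standard
#' deviation (never the test fold's), an SVM with the configured kernel is
#' fit, and test labels are predicted. A decision value of exactly zero is
#' broken toward class 0. If every training feature dimension has zero
#' variance the classifier is degenerate; a warning is issued and the
#' training majority class (ties toward 0) is predicted.
#'
#' @param train_x Numeric matrix of training features (rows = samples).
#' @param train_y Integer labels in `{0, 1}`; both classes must be present.
#' @param test_x Numeric matrix of test features, same columns as `train_x`.
#' @param config An [svm_config()].
#' @return Integer vector of predicted labels with attribute
#'   `"decision_values"` (signed; positive favours class 1).
#' @export
train_predict <- function(train_x, train_y, test_x, config = svm_config()) {
  tr <- check_features(train_x, train_y)
  test_x <- as.matrix(test_x)
  storage.mode(test_x) <- "double"
  if (length(unique(tr$y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }

  sdv <- apply(tr$x, 2, sd)
  if (all(sdv < 1e-12)) {
    warning("zero variance in all training feature dimensions; ",
            "falling back to majority-class prediction")
    maj <- if (sum(tr$y == 1L) > sum(tr$y == 0L)) 1L else 0L
    pred <- rep(maj, nrow(test_x))
    attr(pred, "decision_values") <- rep(0, nrow(test_x))
    return(pred)
  }

  xs <- tr$x
  ts <- test_x
  if (config$standardize) {
    mu <- colMeans(tr$x)
    sc <- ifelse(sdv < 1e-12, 1, sdv)
    xs <- sweep(sweep(tr$x, 2, mu), 2, sc, "/")
    ts <- sweep(sweep(test_x, 2, mu), 2, sc, "/")
  }

  args <- list(x = xs, y = factor(tr$y, levels = c(0L, 1L)),
               kernel = config$kernel, cost = config$cost, scale = FALSE)
  if (!is.null(config$gamma)) args$gamma <- config$gamma
  fit <- do.call(e1071::svm, args)

  pr <- predict(fit, ts, decision.values = TRUE)
  raw <- attr(pr, "decision.values")
  pair <- strsplit(colnames(raw)[1], "/", fixed = TRUE)[[1]]
  dv <- if (pair[1] == "1") as.numeric(raw) else -as.numeric(raw)
  pred <- as.integer(dv > 0)  # dv == 0 resolves to class 0
  attr(pred, "decision_values") <- dv
  pred
}

new_cv_result <- function(protocol, predictions, truth, accuracy, n_fits,
                          fold_accuracies = NULL, seed = NULL) {
  structure(
    list(protocol = protocol, predictions = predictions, truth = truth,
         accuracy = accuracy, n_fits = n_fits,
         fold_accuracies = fold_accuracies, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("protocol=%s accuracy=%.4f (n_fits=%d)\n",
              x$protocol, x$accuracy, x$n_fits))
  if (!is.null(x$fold_accuracies)) {
    cat("per-repeat accuracies:",
        paste(sprintf("%.4f", x$fold_accuracies), collapse = " "), "\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For each of the `n` samples, trains on the remaining `n - 1` and predicts
#' the held-out one; exactly `n` fits are performed. The accuracy is the
#' fraction of correctly predicted samples over all samples. Deterministic
#' given the input and configuration.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer labels in `{0, 1}`, at least 2 samples per class.
#' @param config An [svm_config()].
#' @return A `"cv_result"` with per-sample `predictions`, `accuracy` and
#'   `n_fits = n`.
#' @export
loocv <- function(features, labels, config = svm_config()) {
  d <- check_features(features, labels)
  if (min(table(factor(d$y, levels = 0:1))) < 2L) {
    stop("leave-one-out requires at least 2 samples per class", call. = FALSE)
  }
  n <- nrow(d$x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    pred[i] <- train_predict(d$x[-i, , drop = FALSE], d$y[-i],
                             d$x[i, , drop = FALSE], config)[1]
  }
  new_cv_result("loo", pred, d$y, mean(pred == d$y), n_fits = n)
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat, samples are randomly partitioned into `k` stratified subsets
#' (each class spread as evenly as possible across folds); each subset serves
#' once as the test set, giving predicted labels for every sample and one
#' per-repeat accuracy. The final accuracy is the mean over repeats; with the
#' defaults `k = 10, repeats = 10` this performs 100 fits and averages 10
#' per-repeat accuracies. Fully reproducible from `seed`.
#'
#' @inheritParams loocv
#' @param k Number of folds, `>= 2` and at most the smaller class count.
#' @param repeats Number of independent random partitions.
#' @param seed Integer seed driving all partitioning.
#' @return A `"cv_result"` with `fold_accuracies` (one per repeat),
#'   `accuracy` (their mean) and `n_fits = k * repeats`.
#' @export
repeated_kfold <- function(features, labels, k = 10L, repeats = 10L,
                           seed = 1L, config = svm_config()) {
  d <- check_features(features, labels)
  k <- check_count(k, "k", min = 2L)
  repeats <- check_count(repeats, "repeats", min = 1L)
  counts <- table(factor(d$y, levels = 0:1))
  if (min(counts) < 1L) stop("both classes must be present", call. = FALSE)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the smaller class count (", min(counts), ")",
         call. = FALSE)
  }
  n <- nrow(d$x)
  acc <- numeric(repeats)
  pred_last <- integer(n)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- integer(n)
      for (cl in c(0L, 1L)) {
        idx <- which(d$y == cl)
        fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
      pred <- integer(n)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        pred[test] <- train_predict(d$x[-test, , drop = FALSE], d$y[-test],
                                    d$x[test, , drop = FALSE], config)
      }
      acc[r] <- mean(pred == d$y)
      pred_last <- pred
    }
  })
  new_cv_result("kfold", pred_last, d$y, mean(acc), n_fits = k * repeats,
                fold_accuracies = acc, seed = seed)
}
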