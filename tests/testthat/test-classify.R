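# Well-separated two-class feature clouds in the (avg clustering, entropy)
# plane, mimicking the geometry of the real feature space.
separable_features <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  x0 <- cbind(runif(n_per_class, 0.15, 0.25), runif(n_per_class, 0.4, 0.6))
  x1 <- cbind(runif(n_per_class, 0.75, 0.85), runif(n_per_class, 2.8, 3.2))
  list(x = rbind(x0, x1), y = rep(c(0L, 1L), each = n_per_class))
}

test_that("a test point deep inside one class is assigned to that class", {
  d <- separable_features()
  expect_equal(train_predict(d$x, d$y, rbind(c(0.2, 0.5)))[1], 0L)
  expect_equal(train_predict(d$x, d$y, rbind(c(0.8, 3.0)))[1], 1L)
  expect_error(train_predict(d$x[d$y == 0, ], d$y[d$y == 0], rbind(c(0, 0))),
               "both classes")
})

test_that("standardization uses training statistics only (no leakage)", {
  d <- separable_features(seed = 3)
  test_pts <- rbind(c(0.2, 0.5), c(0.8, 3.0))
  base <- train_predict(d$x, d$y, test_pts)
  # appending wild extra test rows must not move the original predictions
  more <- train_predict(d$x, d$y, rbind(test_pts, c(1e4, -1e4)))
  expect_identical(base[1:2], more[1:2])
  expect_identical(attr(base, "decision_values")[1:2],
                   attr(more, "decision_values")[1:2])
  # presenting scaled test features refits on the same training data, so the
  # boundary is unchanged: re-evaluating the original points reproduces the
  # original decision values exactly
  train_predict(d$x, d$y, test_pts * 10)
  again <- train_predict(d$x, d$y, test_pts)
  expect_identical(attr(base, "decision_values"),
                   attr(again, "decision_values"))
})

test_that("an exactly symmetric setup lands on the boundary and breaks toward class 0", {
  tr <- rbind(c(-1, 0), c(-2, 0), c(-1, 1), c(-2, -1),
              c(1, 0), c(2, 0), c(1, -1), c(2, 1))
  ty <- rep(c(0L, 1L), each = 4)
  p <- train_predict(tr, ty, matrix(0, 1, 2), svm_config(kernel = "linear"))
  expect_lt(abs(attr(p, "decision_values")[1]), 1e-9)
  expect_equal(p[1], 0L)
})

test_that("degenerate zero-variance training falls back to the majority class", {
  x <- matrix(1, nrow = 10, ncol = 2)
  y <- c(rep(0L, 6), rep(1L, 4))
  expect_warning(p <- train_predict(x, y, matrix(1, 3, 2)), "majority")
  expect_equal(p[1:3], rep(0L, 3))
})

test_that("leave-one-out performs n fits and scores separable data perfectly", {
  d <- separable_features()
  fits <- 0L
  trace("svm", where = asNamespace("e1071"), print = FALSE,
        tracer = function() fits <<- fits + 1L)
  on.exit(untrace("svm", where = asNamespace("e1071")), add = TRUE)
  res <- loocv(d$x, d$y)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_fits, nrow(d$x))
  expect_equal(fits, nrow(d$x))
  expect_length(res$predictions, nrow(d$x))
  expect_error(loocv(d$x[1:20, ], rep(0L, 20)), "class")
})

test_that("identical features with imbalanced labels score the majority rate", {
  x <- matrix(0.5, nrow = 20, ncol = 2)
  y <- c(rep(0L, 12), rep(1L, 8))
  res <- suppressWarnings(loocv(x, y))
  expect_equal(res$accuracy, 0.6)  # every round predicts the training majority
})

test_that("repeated stratified k-fold is seed-reproducible and counts k*repeats fits", {
  d <- separable_features(seed = 8)
  fits <- 0L
  trace("svm", where = asNamespace("e1071"), print = FALSE,
        tracer = function() fits <<- fits + 1L)
  on.exit(untrace("svm", where = asNamespace("e1071")), add = TRUE)
  r1 <- repeated_kfold(d$x, d$y, k = 5, repeats = 4, seed = 99)
  expect_equal(fits, 20L)
  expect_equal(r1$n_fits, 20L)
  expect_length(r1$fold_accuracies, 4L)
  expect_equal(r1$accuracy, mean(r1$fold_accuracies))
  expect_equal(r1$accuracy, 1.0)
  r2 <- repeated_kfold(d$x, d$y, k = 5, repeats = 4, seed = 99)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_error(repeated_kfold(d$x, d$y, k = 25, repeats = 2), "exceeds")
})
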