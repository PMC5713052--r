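test_that("column normalisation produces unit-norm columns and reusable norms", {
  expect_equal(as.vector(normalize_columns(matrix(c(3, 4), 2, 1))),
               c(0.6, 0.8))
  u <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(unname(normalize_columns(u)[, ]), u)
  set.seed(61)
  X <- matrix(rnorm(40), 10, 4)
  Xn <- normalize_columns(X)
  expect_equal(unname(sqrt(colSums(Xn^2))), rep(1, 4), tolerance = 1e-12)
  # norms fitted on one matrix apply to another
  Y <- normalize_columns(X[1:3, ], norms = attr(Xn, "norms"))
  attr(Y, "norms") <- NULL
  expect_equal(unname(Y), unname(Xn[1:3, ]))
  expect_error(normalize_columns(cbind(X, 0)), "zero-norm")
})

test_that("the GRBF kernel matches its closed form", {
  expect_equal(grbf_kernel(matrix(1, 1, 3), matrix(1, 1, 3), sigma = 2)[1, 1], 1)
  expect_equal(grbf_kernel(matrix(0), matrix(sqrt(2) * 5), sigma = 5)[1, 1],
               exp(-1), tolerance = 1e-12)
  expect_equal(grbf_kernel(matrix(0), matrix(1e4), sigma = 1)[1, 1], 0)
  expect_error(grbf_kernel(matrix(1), matrix(1), sigma = 0), "sigma > 0")
  expect_error(grbf_kernel(matrix(1, 1, 2), matrix(1, 1, 3), sigma = 1),
               "dimension")
})

test_that("the two-point problem reproduces the hand-solved hard-margin SVM", {
  X <- matrix(c(0, 1), 2, 1)
  fit <- svm_train(X, c(-1, 1), C = 1e4, kernel = "linear")
  f <- predict(fit, matrix(c(0, 0.5, 1), 3, 1))
  expect_lt(f[1], 0)
  expect_equal(f[2], 0, tolerance = 1e-4)   # boundary at x = 0.5
  expect_gt(f[3], 0)
  expect_equal(f[1], -1, tolerance = 1e-4)  # margins are +/- 1
  expect_equal(f[3], 1, tolerance = 1e-4)
})

test_that("trained models satisfy dual feasibility and the margin condition", {
  set.seed(62)
  for (rep in 1:5) {
    n <- 14
    X <- rbind(matrix(rnorm(n, -1), n / 2, 2), matrix(rnorm(n, 1), n / 2, 2))
    y <- rep(c(-1, 1), each = n / 2)
    C <- sample(c(1, 10, 100), 1)
    fit <- svm_train(X, y, C = C, kernel = "grbf", sigma = 1)
    expect_equal(sum(fit$dual_coef), 0, tolerance = 1e-8)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-12))
    # free support vectors sit on the margin
    free <- fit$alpha > 1e-6 * C & fit$alpha < C * (1 - 1e-6)
    if (any(free)) {
      f <- predict(fit, fit$support_vectors[free, , drop = FALSE])
      expect_equal(abs(f), rep(1, sum(free)), tolerance = 1e-4)
    }
    # decision values equal direct summation over stored coefficients
    Xt <- matrix(rnorm(10), 5, 2)
    K <- grbf_kernel(Xt, fit$support_vectors, 1)
    expect_equal(predict(fit, Xt),
                 as.vector(K %*% fit$dual_coef) + fit$b, tolerance = 1e-12)
  }
  expect_error(svm_train(matrix(1:4, 2), c(1, 1), C = 1), "both classes")
  expect_error(svm_train(matrix(1:4, 2), c(-1, 1), C = -1), "positive")
})

test_that("the GRBF kernel solves XOR and C never hurts separable training accuracy", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(-1, 1, 1, -1)
  fit <- svm_train(X, y, C = 100, kernel = "grbf", sigma = 0.5)
  expect_identical(predict(fit, X, type = "class"), y)

  set.seed(63)
  Xs <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  ys <- rep(c(-1, 1), each = 10)
  accs <- vapply(c(0.01, 0.1, 1, 10, 100), function(C)
    mean(predict(svm_train(Xs, ys, C = C, sigma = 2), Xs, type = "class") == ys),
    numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("SMO decision values match a generic QP solver on tiny problems", {
  skip_if_not_installed("kernlab")
  set.seed(64)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    y <- c(rep(-1, 2), rep(1, n - 2))
    X[y == 1, ] <- X[y == 1, ] + 1.5
    Xt <- matrix(rnorm(8), 4, 2)
    fit <- svm_train(X, y, C = 10, kernel = "grbf", sigma = 1.2)
    expect_equal(predict(fit, Xt),
                 qp_svm_decision(X, y, C = 10, sigma = 1.2, Xt),
                 tolerance = 1e-4)
  }
})

test_that("SMO agrees with an established SVM implementation on the fixture data", {
  skip_if_not_installed("e1071")
  tab <- table3_features()
  X <- normalize_columns(as.matrix(tab[, c("mean", "skewness")]))
  attr(X, "norms") <- NULL
  y <- ifelse(tab$label == "injured", 1, -1)
  for (p in list(c(500, 2.658), c(1, 1))) {
    fit <- svm_train(X, y, C = p[1], kernel = "grbf", sigma = p[2])
    ref <- e1071::svm(X, factor(y), scale = FALSE, kernel = "radial",
                      gamma = 1 / (2 * p[2]^2), cost = p[1])
    dv <- as.vector(attr(predict(ref, X, decision.values = TRUE),
                         "decision.values"))
    if (ref$levels[1] == "-1") dv <- -dv  # e1071 orients toward its first level
    mine <- predict(fit, X)
    expect_equal(mine, dv, tolerance = 1e-3)
    # svm_decide is the labelled view of the same decision values
    sd <- svm_decide(fit, X)
    expect_equal(sd$decision, mine)
    expect_identical(sd$label, ifelse(mine >= 0, 1, -1))
  }
})

test_that("trapezoid AUC equals the tie-aware pair-counting statistic", {
  r <- roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, -1, 1, -1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))

  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, -1))$auc, 1)

  set.seed(65)
  for (rep in 1:200) {
    n <- sample(6:20, 1)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # frequent ties
    a <- roc_auc(s, y)$auc
    expect_equal(a, pair_count_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(s, -y)$auc, 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("confusion counts follow the healthy-negative / injured-positive convention", {
  expect_equal(confusion_matrix(c(1, 1, -1, -1), c(1, -1, 1, -1)),
               c(TN = 1L, FP = 1L, FN = 1L, TP = 1L))
  expect_equal(confusion_matrix(c(-1, 1), c(-1, 1)),
               c(TN = 1L, FP = 0L, FN = 0L, TP = 1L))
  all_inj <- confusion_matrix(rep(1, 5), rep(-1, 5))
  expect_equal(unname(all_inj), c(0L, 5L, 0L, 0L))
  expect_equal(confusion_matrix(c("injured", "healthy"),
                                c("injured", "injured")),
               c(TN = 0L, FP = 0L, FN = 1L, TP = 1L))
  expect_error(confusion_matrix(integer(0), integer(0)), "nonempty")
})

test_that("cross-validation is deterministic, perfect on separated blobs, and chance-level under permutation", {
  set.seed(66)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2), matrix(rnorm(60, 10, 1), 30, 2))
  y <- rep(c(-1, 1), each = 30)
  cv <- cross_validate(X, y, k = 10, C = 10, sigma = 3, seed = 4)
  expect_equal(cv$auc, 1)
  expect_equal(cv$mse, 0)
  expect_equal(unname(cv$confusion), c(30L, 0L, 0L, 30L))
  cv2 <- cross_validate(X, y, k = 10, C = 10, sigma = 3, seed = 4)
  expect_identical(cv$decision, cv2$decision)
  expect_identical(cv$folds, cv2$folds)

  # permuted labels: pooled CV AUC concentrates at 1/2
  set.seed(67)
  Xp <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200, 4), 100, 2))
  null_auc <- vapply(1:50, function(s) {
    yp <- sample(rep(c(-1, 1), each = 100))
    cross_validate(Xp, yp, k = 10, C = 1, sigma = 2, seed = s,
                   normalize = "none")$auc
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.08)

  expect_error(cross_validate(X, y, k = 100, C = 1), "exceed")
})

test_that("stratified folds keep both classes represented at the fixture's class balance", {
  y <- c(rep(-1, 11), rep(1, 14))
  folds <- corneaHSI:::.stratified_folds(y, 10, seed = 2)
  expect_identical(sort(unique(folds)), 1:10)
  for (f in 1:10) {
    expect_true(any(folds != f & y == -1))
    expect_true(any(folds != f & y == 1))
    expect_lte(sum(folds == f), 4L)
  }
})
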