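#' Column normalisation to unit Euclidean length
#'
#' Divides each feature column by its Euclidean norm so that all features
#' carry comparable weight in the kernel. The norms are attached so that
#' test data can be scaled by the norms fitted on training data.
#'
#' @param X numeric matrix, samples in rows.
#' @param norms optional previously fitted norms to apply instead of
#'   computing new ones.
#' @return The normalised matrix with attribute `"norms"`.
#' @examples
#' attr(normalize_columns(matrix(c(3, 4), 2, 1)), "norms")  # 5
#' @export
normalize_columns <- function(X, norms = NULL) {
  X <- as.matrix(X)
  if (is.null(norms)) norms <- sqrt(colSums(X^2))
  if (any(norms <= 0)) stop("zero-norm feature column")
  out <- sweep(X, 2, norms, "/")
  attr(out, "norms") <- norms
  out
}

#' Gaussian radial basis function kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}, where
#' \eqn{\sigma} is the kernel width. (The common precision form
#' \eqn{\exp(-\gamma \|d\|^2)} corresponds to \eqn{\gamma = 1/(2\sigma^2)}.)
#'
#' @param X,Y numeric matrices with samples in rows and equal numbers of
#'   columns; `Y` defaults to `X`.
#' @param sigma kernel width, > 0.
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @examples
#' grbf_kernel(matrix(0), matrix(sqrt(2)), sigma = 1)  # exp(-1)
#' @export
grbf_kernel <- function(X, Y = X, sigma) {
  stopifnot(sigma > 0)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# coerce labels to +/-1 with "injured" (or the second factor level, or +1)
# as the positive class; returns y and the label names
.as_pm1 <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    lev <- if (all(y %in% c("healthy", "injured"))) c("healthy", "injured")
           else sort(unique(y))
    if (length(lev) > 2L) stop("binary labels required")
    out <- ifelse(y == lev[length(lev)], 1, -1)
    attr(out, "levels") <- lev
    out
  } else {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    structure(as.numeric(y), levels = c("-1", "1"))
  }
}

#' Train a soft-margin SVM by sequential minimal optimisation
#'
#' Solves the dual of the two-class soft-margin SVM,
#' \deqn{\min_\alpha \tfrac12 \alpha^T Q \alpha - e^T \alpha, \quad
#'       0 \le \alpha_i \le C,\ \ y^T\alpha = 0,}
#' with \eqn{Q_{ij} = y_i y_j K(x_i, x_j)}, by SMO with maximal-violating-
#' pair working-set selection, iterating until the KKT violation falls
#' below `tol`. The decision function is
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b}.
#'
#' @param X numeric matrix of training samples (rows).
#' @param y labels: -1/+1 numeric, or a factor/character with two levels
#'   (for healthy/injured data, injured is the positive class).
#' @param C box constraint, > 0.
#' @param kernel `"grbf"` or `"linear"`.
#' @param sigma GRBF kernel width (ignored for the linear kernel).
#' @param tol KKT stopping tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `csvm`: support vectors, dual coefficients
#'   `alpha * y`, bias `b`, kernel settings, iteration count.
#' @examples
#' X <- matrix(c(0, 1), 2, 1)
#' fit <- svm_train(X, c(-1, 1), C = 1e3, kernel = "linear")
#' predict(fit, matrix(c(0, 0.5, 1), 3, 1))
#' @export
svm_train <- function(X, y, C = 1, kernel = c("grbf", "linear"), sigma = 1,
                      tol = 1e-6, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- .as_pm1(y)
  lev <- attr(y, "levels")
  n <- length(y)
  if (n < 2L || nrow(X) != n) stop("need matching X rows and labels, n >= 2")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (C <= 0) stop("C must be positive")
  K <- if (kernel == "grbf") grbf_kernel(X, X, sigma) else tcrossprod(X)

  a <- numeric(n); G <- rep(-1, n); Q <- K * outer(y, y); it <- 0L
  repeat {
    yg <- -y * G
    up <- (y ==  1 & a < C - 1e-12) | (y == -1 & a > 1e-12)
    lo <- (y == -1 & a < C - 1e-12) | (y ==  1 & a > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol || it >= max_iter) break
    it <- it + 1L
    ai0 <- a[i]; aj0 <- a[j]
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    if (y[i] != y[j]) {
      delta <- (-G[i] - G[j]) / quad; diff <- ai0 - aj0
      a[i] <- ai0 + delta; a[j] <- aj0 + delta
      if (diff > 0) { if (a[j] < 0) { a[j] <- 0; a[i] <- diff } }
      else          { if (a[i] < 0) { a[i] <- 0; a[j] <- -diff } }
      if (diff > 0) { if (a[i] > C) { a[i] <- C; a[j] <- C - diff } }
      else          { if (a[j] > C) { a[j] <- C; a[i] <- C + diff } }
    } else {
      delta <- (G[i] - G[j]) / quad; s <- ai0 + aj0
      a[i] <- ai0 - delta; a[j] <- aj0 + delta
      if (s > C) { if (a[i] > C) { a[i] <- C; a[j] <- s - C } }
      else       { if (a[j] < 0) { a[j] <- 0; a[i] <- s } }
      if (s > C) { if (a[j] > C) { a[j] <- C; a[i] <- s - C } }
      else       { if (a[i] < 0) { a[i] <- 0; a[j] <- s } }
    }
    G <- G + Q[, i] * (a[i] - ai0) + Q[, j] * (a[j] - aj0)
  }
  free <- a > 1e-8 & a < C - 1e-8
  yg <- -y * G
  b <- if (any(free)) mean(yg[free]) else {
    up <- (y ==  1 & a < C - 1e-12) | (y == -1 & a > 1e-12)
    lo <- (y == -1 & a < C - 1e-12) | (y ==  1 & a > 1e-12)
    (max(yg[up]) + min(yg[lo])) / 2
  }
  sv <- a > 1e-10
  structure(list(support_vectors = X[sv, , drop = FALSE],
                 dual_coef = (a * y)[sv], alpha = a[sv], b = b,
                 kernel = kernel, sigma = sigma, C = C,
                 iterations = it, levels = lev, n_train = n),
            class = "csvm")
}

#' @export
print.csvm <- function(x, ...) {
  cat(sprintf("<csvm> %s kernel%s, C = %g: %d support vectors of %d samples, b = %.4g (%d SMO iterations)\n",
              x$kernel,
              if (x$kernel == "grbf") sprintf(" (sigma = %g)", x$sigma) else "",
              x$C, nrow(x$support_vectors), x$n_train, x$b, x$iterations))
  invisible(x)
}

#' @export
coef.csvm <- function(object, ...) {
  list(dual_coef = object$dual_coef, b = object$b)
}

#' Evaluate the SVM decision function
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` over the stored support
#' vectors. The predicted class is `sign(f)`; a decision value of exactly
#' zero predicts the positive class.
#'
#' @param object a fitted [svm_train()] model.
#' @param newdata numeric matrix of samples (rows).
#' @param type `"decision"` for raw values, `"class"` for -1/+1 labels.
#' @param ... unused.
#' @return Numeric decision values or -1/+1 class labels.
#' @export
predict.csvm <- function(object, newdata,
                         type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$support_vectors))
    stop("dimension mismatch with the training data")
  Kt <- if (object$kernel == "grbf")
    grbf_kernel(newdata, object$support_vectors, object$sigma)
  else tcrossprod(newdata, object$support_vectors)
  f <- as.vector(Kt %*% object$dual_coef) + object$b
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' @rdname predict.csvm
#' @param model a fitted [svm_train()] model.
#' @return `svm_decide` returns a list with `decision` and `label`.
#' @export
svm_decide <- function(model, newdata) {
  f <- predict(model, newdata, type = "decision")
  list(decision = f, label = ifelse(f >= 0, 1, -1))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values, recording
#' (FPR, TPR) at each, and integrates by the trapezoid rule. The result
#' equals the Mann-Whitney pair-counting statistic with ties counted 1/2;
#' 1 is a perfect ranking, 0.5 is chance.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels -1/+1 or two-level factor/character labels (both classes
#'   present).
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @examples
#' roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, -1, 1, -1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_pm1(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  np <- sum(y == 1); nn <- sum(y == -1)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group tied scores so the sweep moves through whole tie groups at once
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(threshold = c(Inf, ss[last]),
                    fpr = c(0, fp[last] / nn),
                    tpr = c(0, tp[last] / np))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Confusion matrix counts
#'
#' Healthy (-1) is the negative class and injured (+1) the positive class.
#'
#' @param pred,truth equal-length label vectors (-1/+1 or two-level
#'   factor/character).
#' @return Named integer vector `c(TN, FP, FN, TP)`.
#' @export
confusion_matrix <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth))
    stop("pred and truth must be nonempty and of equal length")
  p <- .as_pm1(pred); t <- .as_pm1(truth)
  c(TN = sum(p == -1 & t == -1), FP = sum(p == 1 & t == -1),
    FN = sum(p == -1 & t == 1),  TP = sum(p == 1 & t == 1))
}

# stratified fold assignment: per class, shuffle then deal round-robin;
# k = n is leave-one-out and involves no randomness
.stratified_folds <- function(y, k, seed) {
  if (k == length(y)) return(seq_along(y))
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated SVM evaluation
#'
#' Stratified k-fold cross-validation of [svm_train()]: per fold, the model
#' is fitted on the training part and decision values are computed for the
#' held-out part; the pooled out-of-fold decision values give the ROC and
#' its AUC (reported as `auc`), the pooled 0/1-coded label mean squared
#' error (`mse`, equal to the misclassification rate), the plain fraction
#' correct (`accuracy`), and the confusion counts. Column normalisation is
#' fitted per training fold by default; `normalize = "joint"` instead
#' normalises the full matrix once before splitting (the convention used
#' for the packaged feature-table replication), `"none"` disables it.
#'
#' @param X numeric feature matrix (samples in rows).
#' @param y labels (-1/+1 or healthy/injured).
#' @param k number of folds (default 10); `k = n` gives leave-one-out.
#' @param C,kernel,sigma,tol passed to [svm_train()].
#' @param seed fold-assignment seed.
#' @param normalize `"fold"`, `"joint"` or `"none"`.
#' @return An object of class `cv_report`: `auc`, `roc`, `mse`,
#'   `accuracy`, `confusion`, `iterations` (summed over folds),
#'   `decision` (pooled out-of-fold values), `folds`, `seed`.
#' @export
cross_validate <- function(X, y, k = 10L, C = 1, kernel = c("grbf", "linear"),
                           sigma = 1, seed = 1L,
                           normalize = c("fold", "joint", "none"),
                           tol = 1e-6) {
  kernel <- match.arg(kernel); normalize <- match.arg(normalize)
  X <- as.matrix(X)
  y <- .as_pm1(y); lev <- attr(y, "levels")
  n <- length(y)
  if (k > n) stop("k must not exceed the number of samples")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (normalize == "joint") X <- normalize_columns(X)
  folds <- .stratified_folds(y, k, seed)
  dec <- numeric(n); iters <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(y[!te])) < 2L)
      stop("a training fold lost one class; reduce k")
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (normalize == "fold") {
      Xtr <- normalize_columns(Xtr)
      Xte <- normalize_columns(Xte, norms = attr(Xtr, "norms"))
    }
    fit <- svm_train(Xtr, y[!te], C = C, kernel = kernel, sigma = sigma,
                     tol = tol)
    dec[te] <- predict(fit, Xte)
    iters <- iters + fit$iterations
  }
  ra <- roc_auc(dec, y)
  pred <- ifelse(dec >= 0, 1, -1)
  structure(list(auc = ra$auc, roc = ra$roc,
                 mse = mean(((pred + 1) / 2 - (y + 1) / 2)^2),
                 accuracy = mean(pred == y),
                 confusion = confusion_matrix(pred, y),
                 iterations = iters, decision = dec, folds = folds,
                 seed = as.integer(seed), levels = lev,
                 settings = list(k = k, C = C, kernel = kernel,
                                 sigma = sigma, normalize = normalize)),
            class = "cv_report")
}

#' Plot the pooled ROC curve of a cross-validation report
#'
#' @param x a `cv_report` from [cross_validate()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Pooled ROC (AUC = %.4f)", x$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<cv_report> %d-fold CV, %s kernel (C = %g, sigma = %g, %s normalisation)\n",
              s$k, s$kernel, s$C, s$sigma, s$normalize))
  cat(sprintf("  pooled AUC %.4f | MSE %.4f | accuracy %.4f | %d solver iterations\n",
              x$auc, x$mse, x$accuracy, x$iterations))
  cat(sprintf("  confusion: TN %d, FP %d, FN %d, TP %d\n",
              x$confusion["TN"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TP"]))
  invisible(x)
}
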