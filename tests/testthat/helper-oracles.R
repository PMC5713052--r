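# Independent reference implementations used as oracles. These are written
# as plain double loops / direct definitions, deliberately sharing no code
# with the package internals.

# sliding-window normalised cross-correlation, brute force over all offsets
brute_ncc <- function(image, template) {
  m <- nrow(template); n <- ncol(template)
  t0 <- template - mean(template)
  tn <- sqrt(sum(t0^2))
  out <- matrix(NA_real_, nrow(image) - m + 1L, ncol(image) - n + 1L)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    w <- image[i:(i + m - 1L), j:(j + n - 1L)]
    w0 <- w - mean(w)
    d <- tn * sqrt(sum(w0^2))
    out[i, j] <- if (d < 1e-10 * tn) 0 else sum(w0 * t0) / d
  }
  out
}

# grayscale erosion by min-over-support with reflected borders
brute_erode <- function(img, du, dv, b, reflect = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  refl_idx <- function(x, n) if (x < 1) 2 - x else if (x > n) 2 * n - x else x
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (k in seq_along(du)) {
      r <- i + du[k]; c <- j + dv[k]
      if (reflect) {
        r <- refl_idx(r, nr); c <- refl_idx(c, nc)
      } else if (r < 1 || r > nr || c < 1 || c > nc) next
      vals <- c(vals, img[r, c] - b[k])
    }
    out[i, j] <- min(vals)
  }
  out
}

# AUC as the Mann-Whitney pair-counting statistic, ties counted one half
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# SVM dual solved by a generic interior-point QP solver (kernlab::ipop),
# returning decision values on given test points
qp_svm_decision <- function(X, y, C, sigma, X_test) {
  K <- exp(-as.matrix(stats::dist(rbind(X, X_test)))^2 / (2 * sigma^2))
  n <- nrow(X)
  Ktr <- K[seq_len(n), seq_len(n), drop = FALSE]
  Q <- Ktr * outer(y, y) + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 12, maxiter = 200)
  a <- kernlab::primal(sol)
  g <- as.vector(Ktr %*% (a * y))
  free <- a > 1e-6 * C & a < C * (1 - 1e-6)
  bias <- if (any(free)) mean(y[free] - g[free]) else {
    up <- (y == 1 & a < C - 1e-8) | (y == -1 & a > 1e-8)
    lo <- (y == -1 & a < C - 1e-8) | (y == 1 & a > 1e-8)
    v <- y - g
    (max(v[up]) + min(v[lo])) / 2
  }
  Kte <- K[n + seq_len(nrow(X_test)), seq_len(n), drop = FALSE]
  as.vector(Kte %*% (a * y)) + bias
}

# compact spectral model for fast unit tests (16 bands)
small_model <- function(noise_sd = 0.5)
  spectrum_model(wavelengths = seq(400, 1000, length.out = 16),
                 noise_sd = noise_sd)

# calibrated reflectance cube for a scene
calibrate_scene <- function(sc)
  flat_field_correct(sc$cube, ref_frames(sc$dark, sc$white))
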