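test_that("gamma adjustment matches the power law on the normalised scale", {
  img <- matrix(seq(0, 1, length.out = 101), 101, 1)  # values k/100
  expect_equal(gamma_adjust(img, gamma = 1, clip_percentiles = c(0, 100)),
               img, tolerance = 1e-12)
  g05 <- gamma_adjust(img, gamma = 0.5, clip_percentiles = c(0, 100))
  expect_equal(g05[26, 1], 0.5, tolerance = 1e-12)        # 0.25 ^ 0.5
  g2 <- gamma_adjust(img, gamma = 2, clip_percentiles = c(0, 100))
  expect_equal(g2[51, 1], 0.25, tolerance = 1e-12)        # 0.5 ^ 2
  expect_true(mean(g2) < mean(img))                       # gamma > 1 darkens
  expect_error(gamma_adjust(matrix(3, 4, 4), 0.5), "degenerate")
})

test_that("band-group selection by mutual information finds the structured group", {
  set.seed(41)
  nb <- 20
  pattern <- outer(sin(seq(0, 3 * pi, length.out = 32)),
                   cos(seq(0, 2 * pi, length.out = 32)))
  data <- array(rnorm(32 * 32 * nb), c(32, 32, nb))
  for (b in 9:12) data[, , b] <- 3 * pattern + 0.2 * rnorm(32 * 32)
  cube <- hypercube(data, seq(400, 1000, length.out = nb))
  groups <- list(c(1, 4), c(5, 8), c(9, 12), c(13, 16), c(17, 20))
  sel <- select_band_group(cube, groups)
  expect_identical(sel$group, 3L)
  expect_identical(sel$bands, 9:12)
  expect_identical(which.max(sel$scores), 3L)

  # all-identical bands: every score ties, lowest group wins
  same <- hypercube(array(rep(pattern, nb), c(32, 32, nb)),
                    seq(400, 1000, length.out = nb))
  sel2 <- select_band_group(same, groups)
  expect_identical(sel2$group, 1L)
  expect_true(all(abs(sel2$scores - sel2$scores[1]) < 1e-12))
  expect_error(select_band_group(cube, list(c(5, 4))), "empty")
})

test_that("erosion matches the brute-force minimum over the SE support", {
  set.seed(42)
  img <- matrix(runif(144, 0, 100), 12, 12)
  se <- ball_se(2, 3)
  expect_equal(erode(img, se), brute_erode(img, se$du, se$dv, se$b), tolerance = 0)
  expect_equal(erode(img, se, border = "ignore"),
               brute_erode(img, se$du, se$dv, se$b, reflect = FALSE),
               tolerance = 0)
  flat <- matrix(TRUE, 3, 3)
  g <- expand.grid(du = -1:1, dv = -1:1)
  expect_equal(erode(img, flat),
               brute_erode(img, g$du, g$dv, numeric(9)), tolerance = 0)
})

test_that("constant images erode to known constants", {
  img <- matrix(42, 10, 10)
  expect_equal(erode(img, matrix(TRUE, 3, 3)), img)           # flat SE
  expect_equal(erode(img, ball_se(3, 5)), img - 5)            # minus apex
  expect_error(erode(matrix(1, 5, 5), ball_se(6, 1)), "larger than the image")
})

test_that("the fast ball-erosion path is exact against the generic path", {
  set.seed(43)
  for (rep in 1:4) {
    nr <- sample(25:45, 1); nc <- sample(25:45, 1)
    r <- sample(8:15, 1); h <- runif(1, 0, 60)
    img <- matrix(runif(nr * nc, 0, 150), nr, nc)
    se <- ball_se(r, h)
    for (reflect in c(TRUE, FALSE))
      expect_equal(corneaHSI:::.erode_ball_cpp(img, r, h, reflect),
                   corneaHSI:::.erode_cpp(img, se$du, se$dv, se$b, reflect),
                   tolerance = 0)
  }
})

test_that("erosion is anti-extensive and order preserving", {
  set.seed(44)
  img1 <- matrix(runif(400, 0, 100), 20, 20)
  img2 <- img1 + matrix(runif(400, 0, 10), 20, 20)  # img2 >= img1
  se <- ball_se(4, 7)
  e1 <- erode(img1, se); e2 <- erode(img2, se)
  expect_true(all(e1 <= img1))
  expect_true(all(e1 <= e2))
})

test_that("the LoG kernel has zero sum, the printed centre value, and convolution identities", {
  for (sigma in c(0.1, 0.5, 2)) {
    k <- log_kernel(9, sigma)
    expect_equal(sum(k), 0, tolerance = 1e-12)
    # sampled kernel recomputed directly from the printed expression
    h <- 4; x <- matrix(-h:h, 9, 9); y <- t(x); r2 <- x^2 + y^2
    raw <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
    expect_equal(raw[5, 5], -2 / sigma^2, tolerance = 1e-12)
    expect_equal(k, raw - mean(raw), tolerance = 1e-12)
  }
  expect_error(log_kernel(8, 1), "odd")

  expect_equal(log_filter(matrix(3.7, 20, 20), 9, 0.5),
               matrix(0, 20, 20), tolerance = 1e-9)
  impulse <- matrix(0, 21, 21); impulse[11, 11] <- 1
  resp <- log_filter(impulse, 5, 0.8)
  expect_equal(resp[9:13, 9:13], log_kernel(5, 0.8), tolerance = 1e-12)
})

test_that("PCA reproduces hand-computed and oracle eigenstructure", {
  # 3-pixel 2-band toy: covariance [[2/3,1/3],[1/3,2/3]], eigenvalues 1, 1/3
  b1 <- matrix(c(1, 0, -1), 1, 3); b2 <- matrix(c(0, 1, -1), 1, 3)
  p <- pca_fit(list(b1, b2))
  expect_equal(p$mean_vector, c(0, 0))
  expect_equal(p$eigenvalues, c(1, 1 / 3), tolerance = 1e-12)

  # rank-1 data: second eigenvalue zero and dropped
  r1 <- pca_fit(list(matrix(rnorm(16), 4), matrix(0, 4, 4)))
  r1b <- pca_fit(list(b1, 2 * b1))
  expect_identical(r1b$n_retained, 1L)
  expect_equal(r1b$eigenvalues[2], 0, tolerance = 1e-12)

  set.seed(45)
  for (rep in 1:5) {
    nb <- sample(3:5, 1)
    imgs <- lapply(seq_len(nb), function(i) matrix(rnorm(16 * 16), 16, 16))
    p <- pca_fit(imgs)
    X <- sapply(imgs, as.vector)
    # oracle: singular values of the centred matrix
    sv <- svd(sweep(X, 2, colMeans(X)))$d
    expect_equal(p$eigenvalues, sv^2 / nrow(X), tolerance = 1e-8)
    # trace identity and orthonormality
    expect_equal(sum(p$eigenvalues), sum(diag(crossprod(sweep(X, 2, colMeans(X))) / nrow(X))),
                 tolerance = 1e-6)
    expect_equal(crossprod(p$eigenvectors), diag(nb), tolerance = 1e-8)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(nb)) {
      v <- p$eigenvectors[, j]
      expect_gt(v[which.max(abs(v))], 0)
    }
  }
  expect_error(pca_fit(list(matrix(1, 2, 2))), "at least 2")
  expect_error(pca_fit(list(matrix(1, 2, 2), matrix(2, 2, 2))), "constant")
})

test_that("PC difference images obey swap symmetry and degenerate-range policy", {
  set.seed(46)
  imgs <- lapply(1:4, function(i) matrix(rnorm(100), 10, 10))
  p <- pca_fit(imgs)
  d12 <- pc_subtract(p, c(1, 2))
  d21 <- pc_subtract(p, c(2, 1))
  expect_true(all(abs((255L - d12) - d21) <= 1L))  # rounding at ties only
  expect_true(all(d12 >= 0L & d12 <= 255L))
  # identical score images: zero range maps to the all-zero image
  pz <- p
  pz$score_images[[2]] <- pz$score_images[[1]]
  expect_equal(pc_subtract(pz, c(2, 1)), matrix(0L, 10, 10))
  expect_error(pc_subtract(p, c(1, 1)), "differ")
  expect_error(pc_subtract(p, c(1, 99)), "retained")
})

test_that("a rank-2 cube's PC difference is proportional to the pattern difference", {
  # orthogonal spatial patterns with distinct variances drive the two PCs
  n <- 16
  p1 <- outer(sin(2 * pi * seq_len(n) / n), rep(1, n)); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- outer(rep(1, n), sin(2 * pi * seq_len(n) / n)); p2 <- p2 / sqrt(sum(p2^2))
  imgs <- list(3 * p1 + 1 * p2, 3 * p1 - 1 * p2, -3 * p1 + 1 * p2, -3 * p1 - 1 * p2)
  p <- pca_fit(imgs)
  expect_identical(p$n_retained, 2L)
  d <- p$score_images[[2]] - p$score_images[[1]]
  # scores are linear in p1, p2, so the difference lies in their span
  B <- cbind(as.vector(p1), as.vector(p2))
  resid <- as.vector(d) - B %*% solve(crossprod(B), crossprod(B, as.vector(d)))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("CNR follows its definition and is scale invariant", {
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1:2, 1:2] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[6:10, ] <- TRUE
  img[roi] <- 100
  img[bg] <- 50 + rep(c(-10, 10), length.out = sum(bg))  # mean 50, pop sd 10
  expect_equal(cnr(img, roi, bg), 5)
  expect_equal(cnr(3.7 * img, roi, bg), 5)
  img2 <- img; img2[roi] <- 50
  expect_equal(cnr(img2, roi, bg), 0)
  expect_error(cnr(img, roi, roi), "overlap")
  expect_error(cnr(matrix(1, 10, 10), roi, bg), "zero standard deviation")
})

test_that("the enhancement chain is deterministic and separates scene classes", {
  m <- small_model(noise_sd = 1)
  cfg <- enhance_config(band_range = c(4, 10), se_radius = 10, se_height = 10)
  sc_h <- make_scene(m, label = "healthy", seed = 11)
  sc_i <- make_scene(m, label = "injured", seed = 11)
  rh <- calibrate_scene(sc_h); ri <- calibrate_scene(sc_i)
  eh <- enhance_image(rh, cfg)
  expect_identical(eh$image, enhance_image(rh, cfg)$image)
  ei <- enhance_image(ri, cfg)
  msk_roi <- matrix(FALSE, 100, 100); msk_roi[41:60, 41:60] <- TRUE
  msk_bg <- matrix(FALSE, 100, 100); msk_bg[c(1:20, 81:100), ] <- TRUE
  expect_false(isTRUE(all.equal(cnr(eh$image, msk_roi, msk_bg),
                                cnr(ei$image, msk_roi, msk_bg))))
  expect_named(ei$intermediates, c("selected", "gamma", "eroded", "log"))
  expect_true(all(ei$image >= 0L & ei$image <= 255L))
})
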