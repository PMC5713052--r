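#' Non-flat ball structuring element
#'
#' A ball (hemisphere) structuring element for grayscale morphology: support
#' is the discrete disk of radius `r` in the image plane, and the height
#' profile is \eqn{b(u,v) = h \sqrt{1 - (u^2+v^2)/r^2}} gray levels, so the
#' apex height at the origin is `h`. During erosion the height is subtracted
#' inside the moving minimum, which removes bright compact artefacts (such
#' as specular glare) of roughly the ball's size while preserving larger
#' structures.
#'
#' @param radius SE radius in pixels.
#' @param height apex height in gray levels.
#' @return An object of class `ball_se`: list with `radius`, `height`, and
#'   offset vectors `du`, `dv`, `b`.
#' @examples
#' se <- ball_se(2, 3)
#' se$b[se$du == 0 & se$dv == 0]  # apex = height
#' @export
ball_se <- function(radius, height) {
  stopifnot(radius >= 1, height >= 0)
  g <- expand.grid(du = -radius:radius, dv = -radius:radius)
  keep <- g$du^2 + g$dv^2 <= radius^2
  g <- g[keep, ]
  b <- height * sqrt(pmax(1 - (g$du^2 + g$dv^2) / radius^2, 0))
  structure(list(radius = radius, height = height,
                 du = as.integer(g$du), dv = as.integer(g$dv), b = b),
            class = "ball_se")
}

#' @export
print.ball_se <- function(x, ...) {
  cat(sprintf("<ball_se> radius %d px, height %g gray levels, %d offsets\n",
              x$radius, x$height, length(x$b)))
  invisible(x)
}

#' Grayscale erosion
#'
#' Erodes an image with a flat or non-flat structuring element:
#' `out(x) = min over SE support of img(x + u) - b(u)`, with `b = 0` for
#' flat SEs. Borders are reflect-padded by default; `border = "ignore"`
#' instead restricts the minimum to offsets that fall inside the image.
#'
#' @param img numeric matrix.
#' @param se a [ball_se], or a logical/0-1 matrix with odd dimensions
#'   interpreted as a flat SE centred on its middle element.
#' @param border `"reflect"` or `"ignore"`.
#' @return Numeric matrix of the same size.
#' @examples
#' img <- matrix(10, 8, 8)
#' range(erode(img, ball_se(2, 5)))  # constant 10 - 5 = 5
#' @export
erode <- function(img, se, border = c("reflect", "ignore")) {
  border <- match.arg(border)
  stopifnot(is.matrix(img))
  if (inherits(se, "ball_se")) {
    # large balls go through the Monge-decomposed line solver; small ones
    # through the generic minimum (the two are exact and interchangeable)
    if (se$radius >= 8L)
      return(.erode_ball_cpp(img, se$radius, se$height, border == "reflect"))
    du <- se$du; dv <- se$dv; b <- se$b
  } else if (is.matrix(se)) {
    if (nrow(se) %% 2L == 0L || ncol(se) %% 2L == 0L)
      stop("flat SE matrix must have odd dimensions")
    cr <- (nrow(se) + 1L) %/% 2L; cc <- (ncol(se) + 1L) %/% 2L
    idx <- which(se != 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("flat SE has empty support")
    du <- as.integer(idx[, 1] - cr); dv <- as.integer(idx[, 2] - cc)
    b <- numeric(length(du))
  } else stop("'se' must be a ball_se or a matrix")
  .erode_cpp(img, du, dv, b, border == "reflect")
}

#' Gamma (power-law) contrast adjustment
#'
#' Intensities are linearly rescaled to \[0, 1\] between the two clip
#' percentiles (values outside are clipped), raised to the power `gamma`,
#' then mapped back onto the image's original numeric range. `gamma < 1`
#' brightens a dark image, `gamma > 1` darkens it.
#'
#' @param img numeric matrix.
#' @param gamma exponent, > 0.
#' @param clip_percentiles lower/upper percentile (0-100) clip points.
#' @return Numeric matrix.
#' @examples
#' img <- matrix(seq(0, 1, length.out = 25), 5, 5)
#' gamma_adjust(img, 0.5)[13]  # sqrt(0.5)
#' @export
gamma_adjust <- function(img, gamma = 0.7, clip_percentiles = c(1, 99)) {
  stopifnot(gamma > 0, length(clip_percentiles) == 2L)
  qs <- stats::quantile(img, clip_percentiles / 100, names = FALSE,
                        na.rm = FALSE)
  if (qs[2] - qs[1] <= .Machine$double.eps * max(abs(qs), 1))
    stop("degenerate image: clip percentiles coincide")
  x <- pmin(pmax((img - qs[1]) / (qs[2] - qs[1]), 0), 1)
  rng <- range(img)
  rng[1] + x^gamma * (rng[2] - rng[1])
}

# mutual information between two images from a joint equal-width histogram
.mutual_info <- function(a, b, bins = 64L) {
  cut_idx <- function(x) {
    r <- range(x)
    if (r[2] - r[1] <= 0) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- cut_idx(as.vector(a)); ib <- cut_idx(as.vector(b))
  joint <- matrix(tabulate((ib - 1L) * bins + ia, nbins = bins * bins),
                  bins, bins) / length(ia)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Select the most informative band group
#'
#' Scores contiguous groups of bands by the average mutual information
#' between each band image and the group's mean image (estimated from a
#' 64 x 64-bin joint histogram, natural log), and returns the group with
#' the highest score. A structured group scores high because its bands
#' share spatial content; pure-noise groups score low. Ties break to the
#' lowest group index. The default grouping splits a 256-band cube into
#' five 50-band windows; on corneal cubes the second window (bands 51-100,
#' roughly 518-633 nm) is the one that carries the injury contrast.
#'
#' @param cube a [hypercube].
#' @param groups list of `c(first, last)` 1-based inclusive band ranges.
#' @param bins histogram bins per axis for the MI estimate.
#' @return List with `group` (index into `groups`), `bands` (the selected
#'   band indices) and `scores` (per-group mean MI).
#' @export
select_band_group <- function(cube,
                              groups = list(c(1, 50), c(51, 100), c(101, 150),
                                            c(151, 200), c(201, 250)),
                              bins = 64L) {
  stopifnot(inherits(cube, "hypercube"))
  nb <- dim(cube$data)[3L]
  scores <- vapply(groups, function(g) {
    if (g[2] < g[1]) stop("empty band group")
    if (g[1] < 1 || g[2] > nb) stop("band group outside the cube's bands")
    bands <- g[1]:g[2]
    gmean <- apply(cube$data[, , bands, drop = FALSE], c(1, 2), mean)
    mean(vapply(bands, function(b)
      .mutual_info(cube$data[, , b], gmean, bins), numeric(1)))
  }, numeric(1))
  g <- which.max(scores)
  list(group = g, bands = groups[[g]][1]:groups[[g]][2], scores = scores)
}

#' Laplacian-of-Gaussian kernel and filter
#'
#' The kernel is sampled on the centred integer grid from
#' \deqn{\nabla^2 G(x,y) = \frac{x^2 + y^2 - 2\sigma^2}{\sigma^4}
#'       \exp\!\left(-\frac{x^2+y^2}{2\sigma^2}\right)}
#' and then shifted to exact zero sum, which guarantees zero response on
#' flat regions (the continuous expression only integrates to zero over the
#' infinite plane). Filtering is 2-D convolution with reflected borders.
#' Small `sigma` gives sharp, noise-sensitive edges; large `sigma` blurs
#' them.
#'
#' @param size odd kernel side length.
#' @param sigma Gaussian scale, > 0.
#' @return `log_kernel` returns a `size` x `size` matrix with zero sum;
#'   `log_filter` the filtered image.
#' @examples
#' sum(log_kernel(9, 0.5))  # 0
#' @export
log_kernel <- function(size, sigma) {
  if (size %% 2L == 0L) stop("kernel size must be odd")
  stopifnot(sigma > 0)
  h <- (size - 1L) / 2
  x <- matrix(-h:h, size, size); y <- t(x)
  r2 <- x^2 + y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

#' @param img numeric matrix to filter.
#' @rdname log_kernel
#' @export
log_filter <- function(img, size = 9L, sigma = 0.1) {
  k <- log_kernel(size, sigma)
  h <- (size - 1L) / 2
  nr <- nrow(img); nc <- ncol(img)
  if (h >= nr || h >= nc) stop("kernel larger than image")
  pad_idx <- function(n) c(rev(seq_len(h) + 1L), seq_len(n),
                           n - seq_len(h))
  p <- img[pad_idx(nr), pad_idx(nc)]
  out <- matrix(0, nr, nc)
  for (u in seq_len(size))            # convolution: kernel index reversed
    for (v in seq_len(size))
      out <- out + k[size - u + 1L, size - v + 1L] *
        p[(u - 1L) + seq_len(nr), (v - 1L) + seq_len(nc)]
  out
}

#' Principal component analysis of a band stack
#'
#' Treats pixels as observations and bands as variables: each band image is
#' flattened, the per-band mean vector is removed, and the population
#' covariance (1/M, M = number of pixels) is eigendecomposed. Score images
#' are the centred data projected onto each eigenvector, reshaped to the
#' image grid. Components with eigenvalue at most `1e-12` of the leading
#' eigenvalue carry no variance and are dropped; at most `n_components`
#' (default 10) are retained. Eigenvector signs follow the convention that
#' the largest-magnitude loading is positive.
#'
#' @param band_images list of at least two equal-size numeric matrices.
#' @param n_components maximum number of retained components.
#' @return An object of class `pca_result`: `mean_vector`, `eigenvalues`
#'   (all, descending), `eigenvectors` (matrix, one column per component),
#'   `score_images` (list, retained components only), `n_retained`.
#' @export
pca_fit <- function(band_images, n_components = 10L) {
  if (!is.list(band_images) || length(band_images) < 2L)
    stop("need at least 2 band images")
  dims <- dim(band_images[[1]])
  X <- vapply(band_images, function(im) {
    if (!identical(dim(im), dims)) stop("band images differ in shape")
    as.vector(im)
  }, numeric(prod(dims)))
  M <- nrow(X)
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  covx <- crossprod(Xc) / M
  eg <- eigen(covx, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (ev[1] <= 0) stop("constant data: no nonzero eigenvalue")
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  keep <- which(ev > 1e-12 * ev[1])
  keep <- keep[seq_len(min(length(keep), n_components))]
  scores <- lapply(keep, function(j) matrix(Xc %*% vecs[, j], dims[1], dims[2]))
  structure(list(mean_vector = m, eigenvalues = ev, eigenvectors = vecs,
                 score_images = scores, n_retained = length(keep),
                 image_dim = dims),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pv <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<pca_result> %d variables, %d retained components (%.1f%% variance)\n",
              length(x$eigenvalues), x$n_retained,
              100 * sum(pv[seq_len(x$n_retained)])))
  invisible(x)
}

#' Principal-component difference image
#'
#' Subtracts one PC score image from another and min-max rescales the
#' difference to 8-bit gray levels 0-255 (rounded). Differencing the two
#' leading score images cancels the shared background and leaves the
#' spatial structure on which they disagree - for corneal cubes, the injury
#' boundary. A constant difference (zero range) maps to the all-zero image.
#'
#' @param pcs a [pca_fit()] result.
#' @param pair `c(a, b)`: computes `score[a] - score[b]`. Default `c(2, 1)`,
#'   the second component minus the first.
#' @return Integer matrix with values in 0-255.
#' @export
pc_subtract <- function(pcs, pair = c(2, 1)) {
  stopifnot(inherits(pcs, "pca_result"), length(pair) == 2L)
  if (pair[1] == pair[2]) stop("pc_pair indices must differ")
  if (any(pair < 1) || any(pair > pcs$n_retained))
    stop("pc_pair index outside the retained components")
  d <- pcs$score_images[[pair[1]]] - pcs$score_images[[pair[2]]]
  rng <- range(d)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(abs(rng), 1))
    return(matrix(0L, nrow(d), ncol(d)))
  matrix(as.integer(round((d - rng[1]) / (rng[2] - rng[1]) * 255)),
         nrow(d), ncol(d))
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean(img[roi]) - mean(img[bg])| / sd(img[bg])`, with the
#' population (1/n) standard deviation of the background. Scale-invariant;
#' higher values mean the region of interest stands out more clearly from
#' the background noise.
#'
#' @param img numeric matrix.
#' @param roi_mask,bg_mask logical matrices; nonempty and disjoint.
#' @return A single number.
#' @export
cnr <- function(img, roi_mask, bg_mask) {
  stopifnot(is.matrix(img), any(roi_mask), any(bg_mask))
  if (any(roi_mask & bg_mask)) stop("roi and background masks overlap")
  bg <- img[bg_mask]
  s <- sqrt(mean((bg - mean(bg))^2))
  if (s <= 0) stop("background has zero standard deviation")
  abs(mean(img[roi_mask]) - mean(bg)) / s
}

#' Enhancement-chain configuration
#'
#' Collects every tunable parameter of [enhance_image()]. The defaults are
#' the working set of the enhancement chain: gamma 0.7 with 1-99 percentile
#' clipping, the five 50-band groups for band selection (with the second
#' group, bands 50-100, pinned when `band_range` is given), a ball SE of
#' radius 50 and height 50, a 9 x 9 Laplacian-of-Gaussian at sigma 0.1, ten
#' retained principal components, and the PC2 - PC1 difference image.
#'
#' @param gamma,clip_percentiles see [gamma_adjust()].
#' @param band_groups candidate groups for [select_band_group()].
#' @param band_range `c(first, last)` to pin the processed bands and skip
#'   selection (default `c(50, 100)`); `NULL` runs the MI-based selection.
#' @param se_radius,se_height ball SE parameters, see [ball_se()].
#' @param log_size,log_sigma see [log_filter()].
#' @param n_components,pc_pair see [pca_fit()] and [pc_subtract()].
#' @param apply_gamma,apply_erosion,apply_log stage switches; disabling all
#'   three reduces the chain to plain PCA + PC subtraction.
#' @return An object of class `enhance_config`.
#' @export
enhance_config <- function(gamma = 0.7, clip_percentiles = c(1, 99),
                           band_groups = list(c(1, 50), c(51, 100),
                                              c(101, 150), c(151, 200),
                                              c(201, 250)),
                           band_range = c(50, 100),
                           se_radius = 50L, se_height = 50,
                           log_size = 9L, log_sigma = 0.1,
                           n_components = 10L, pc_pair = c(2, 1),
                           apply_gamma = TRUE, apply_erosion = TRUE,
                           apply_log = TRUE) {
  stopifnot(gamma > 0, log_size %% 2L == 1L, log_sigma > 0,
            pc_pair[1] != pc_pair[2])
  structure(list(gamma = gamma, clip_percentiles = clip_percentiles,
                 band_groups = band_groups, band_range = band_range,
                 se_radius = se_radius, se_height = se_height,
                 log_size = log_size, log_sigma = log_sigma,
                 n_components = n_components, pc_pair = pc_pair,
                 apply_gamma = apply_gamma, apply_erosion = apply_erosion,
                 apply_log = apply_log),
            class = "enhance_config")
}

#' Run the image-enhancement chain on a calibrated cube
#'
#' Applies, in order: band selection (a fixed range or MI-based group
#' selection), per-band gamma adjustment, grayscale erosion with a non-flat
#' ball SE (removes saturated glare), Laplacian-of-Gaussian filtering
#' (sharpens boundaries), per-cube PCA over the processed bands, and the
#' PC difference image quantised to 8 bits. Deterministic: identical cube
#' and config give identical output.
#'
#' @param cube a calibrated (reflectance) [hypercube], typically the
#'   100 x 100 region-of-interest crop.
#' @param cfg an [enhance_config()].
#' @return An object of class `enhanced_image`: list with `image` (the
#'   final 0-255 integer matrix), `pca`, `bands` (processed band indices),
#'   `config`, and `intermediates` (named list of per-stage band stacks).
#' @export
enhance_image <- function(cube, cfg = enhance_config()) {
  stopifnot(inherits(cube, "hypercube"), inherits(cfg, "enhance_config"))
  if (anyNA(cube$data)) stop("cube contains NA (defective) pixels")
  nb <- dim(cube$data)[3L]
  if (is.null(cfg$band_range)) {
    sel <- select_band_group(cube, cfg$band_groups)
    bands <- sel$bands
  } else {
    if (cfg$band_range[1] < 1 || cfg$band_range[2] > nb)
      stop("band_range outside the cube's bands")
    bands <- cfg$band_range[1]:cfg$band_range[2]
  }
  imgs <- lapply(bands, function(b) cube$data[, , b])
  inter <- list(selected = imgs)
  if (cfg$apply_gamma) {
    imgs <- lapply(imgs, gamma_adjust, gamma = cfg$gamma,
                   clip_percentiles = cfg$clip_percentiles)
    inter$gamma <- imgs
  }
  if (cfg$apply_erosion) {
    se <- ball_se(cfg$se_radius, cfg$se_height)
    imgs <- lapply(imgs, erode, se = se)
    inter$eroded <- imgs
  }
  if (cfg$apply_log) {
    imgs <- lapply(imgs, log_filter, size = cfg$log_size,
                   sigma = cfg$log_sigma)
    inter$log <- imgs
  }
  pca <- pca_fit(imgs, n_components = cfg$n_components)
  final <- pc_subtract(pca, cfg$pc_pair)
  structure(list(image = final, pca = pca, bands = bands, config = cfg,
                 intermediates = inter),
            class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %d x %d 8-bit image from %d bands (%d-%d), %d PCs\n",
              nrow(x$image), ncol(x$image), length(x$bands),
              min(x$bands), max(x$bands), x$pca$n_retained))
  invisible(x)
}

#' Display an enhanced image as an 8-bit grayscale raster
#'
#' @param x an `enhanced_image` from [enhance_image()].
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.enhanced_image <- function(x, ...) {
  img <- x$image
  # transpose/flip so the matrix displays in image orientation
  graphics::image(t(img[nrow(img):1, ]), zlim = c(0, 255),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(img) / ncol(img), ...)
  invisible(x)
}

#' Dilate a binary mask by a disk
#'
#' Small utility used to carve a safety margin around the injury mask when
#' defining CNR background regions.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, radius = 3L) {
  stopifnot(is.matrix(mask))
  # dilation by duality: -erode(-f); flat disk SE, borders ignored
  g <- expand.grid(du = -radius:radius, dv = -radius:radius)
  g <- g[g$du^2 + g$dv^2 <= radius^2, ]
  -.erode_cpp(-(mask * 1), as.integer(g$du), as.integer(g$dv),
              numeric(nrow(g)), FALSE) > 0.5
}
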