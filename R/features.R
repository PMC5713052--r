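#' First-order gray-level histogram
#'
#' `P(I) = (number of pixels with gray level I) / (total pixels)` for
#' integer gray levels `0 .. n_levels - 1`.
#'
#' @param img matrix of integer gray levels in `[0, n_levels - 1]`.
#' @param n_levels number of gray levels (default 256, 8-bit).
#' @return Numeric probability vector of length `n_levels`, named by gray
#'   level.
#' @examples
#' gray_histogram(matrix(c(0, 0, 255, 255), 2))[c("0", "255")]
#' @export
gray_histogram <- function(img, n_levels = 256L) {
  v <- as.vector(img)
  if (any(v != round(v)) || any(v < 0) || any(v > n_levels - 1L))
    stop("image values must be integers in [0, ", n_levels - 1L, "]")
  P <- tabulate(v + 1L, nbins = n_levels) / length(v)
  names(P) <- 0:(n_levels - 1L)
  P
}

#' First-order histogram statistics
#'
#' From a gray-level probability vector `P(I)` computes the mean
#' \eqn{m_1 = \sum I P(I)} and the central moments
#' \eqn{\mu_k = \sum (I - m_1)^k P(I)} for k = 2, 3, 4, and derives the
#' dimensionless texture features used for classification:
#' `std = sqrt(mu2)`, `skewness = mu3 / mu2^1.5` (asymmetry about the
#' mean), and non-excess `kurtosis = mu4 / mu2^2` (sharpness; 3 for a
#' Gaussian, at least 1 for any non-degenerate discrete distribution). A
#' degenerate histogram (`mu2 = 0`) gets skewness and kurtosis 0 by
#' convention.
#'
#' @param P probability vector over gray levels `0 .. length(P) - 1`.
#' @return An object of class `histogram_stats`: list with `P`, `m1`,
#'   `mu2`, `mu3`, `mu4`, `std`, `skewness`, `kurtosis`.
#' @examples
#' P <- gray_histogram(matrix(c(0, 0, 0, 4), 2))
#' first_order_stats(P)$m1  # 1
#' @export
first_order_stats <- function(P) {
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8)
    stop("'P' must be a probability vector")
  I <- seq_along(P) - 1
  m1 <- sum(I * P)
  mu <- vapply(2:4, function(k) sum((I - m1)^k * P), numeric(1))
  mu2 <- mu[1]; mu3 <- mu[2]; mu4 <- mu[3]
  if (mu2 > 0) {
    skw <- mu3 / mu2^1.5
    krt <- mu4 / mu2^2
  } else skw <- krt <- 0
  structure(list(P = P, m1 = m1, mu2 = mu2, mu3 = mu3, mu4 = mu4,
                 std = sqrt(mu2), skewness = skw, kurtosis = krt),
            class = "histogram_stats")
}

#' @export
print.histogram_stats <- function(x, ...) {
  cat(sprintf("<histogram_stats> mean %.2f, std %.2f, skewness %.3f, kurtosis %.3f\n",
              x$m1, x$std, x$skewness, x$kurtosis))
  invisible(x)
}

#' Extract the four-feature table from enhanced images
#'
#' Computes mean, standard deviation, skewness and kurtosis of the 8-bit
#' gray-level histogram of each enhanced image, one row per image, in the
#' same layout as [table3_features()].
#'
#' @param images list of 8-bit integer matrices (or `enhanced_image`
#'   objects).
#' @param labels character/factor vector of `"healthy"`/`"injured"`, one
#'   per image.
#' @param eye_ids optional identifiers (default sequential).
#' @return A data.frame with columns `eye_id`, `label`, `mean`, `std`,
#'   `skewness`, `kurtosis`.
#' @export
extract_features <- function(images, labels, eye_ids = seq_along(images)) {
  if (!length(images)) stop("no images supplied")
  stopifnot(length(labels) == length(images))
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (inherits(img, "enhanced_image")) img <- img$image
    st <- first_order_stats(gray_histogram(img))
    data.frame(eye_id = eye_ids[i], label = as.character(labels[i]),
               mean = st$m1, std = st$std, skewness = st$skewness,
               kurtosis = st$kurtosis)
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("healthy", "injured"))
  out
}
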