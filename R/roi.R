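#' Normalised cross-correlation template matching via FFT
#'
#' Locates a template inside a band image by normalised cross-correlation,
#' computed in the frequency domain: the raw correlation and the local
#' window sums are all obtained with zero-padded FFTs, then combined into
#' the zero-mean, unit-norm correlation coefficient per valid window. Values
#' are in \[-1, 1\]; 1 is an exact (affine) match. Windows with (near) zero
#' variance get correlation 0. Ties at the peak break to the smallest row,
#' then smallest column.
#'
#' @param image numeric matrix, strictly larger than the template in both
#'   dimensions.
#' @param template numeric matrix with nonzero variance.
#' @return An object of class `template_match`: list with `correlation_map`
#'   (one value per valid top-left placement), `peak_offset` (1-based
#'   (row, col) of the best placement) and `peak_value`.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' tpl <- img[11:25, 21:35]
#' match_template(img, tpl)$peak_offset  # c(11, 21)
#' @export
match_template <- function(image, template) {
  stopifnot(is.matrix(image), is.matrix(template))
  M <- nrow(image); N <- ncol(image)
  m <- nrow(template); n <- ncol(template)
  if (m >= M || n >= N) stop("template must be strictly smaller than image")
  t0 <- template - mean(template)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm < .Machine$double.eps) stop("template has zero variance")

  P <- M + m - 1L; Q <- N + n - 1L
  pad <- function(x) {
    out <- matrix(0, P, Q); out[seq_len(nrow(x)), seq_len(ncol(x))] <- x; out
  }
  # cross-correlation: conjugate product in the frequency domain
  xcorr <- function(a, b) {
    r <- Re(stats::fft(stats::fft(pad(a)) * Conj(stats::fft(pad(b))),
                       inverse = TRUE)) / (P * Q)
    r[seq_len(M - m + 1L), seq_len(N - n + 1L)]
  }
  ones <- matrix(1, m, n)
  num   <- xcorr(image, t0)              # sum over window of image * t0
  s1    <- xcorr(image, ones)            # window sums
  s2    <- xcorr(image^2, ones)          # window sums of squares
  winvar <- s2 - s1^2 / (m * n)
  winvar[winvar < 0] <- 0
  denom <- tnorm * sqrt(winvar)
  cc <- num / denom
  cc[denom < 1e-10 * tnorm] <- 0
  cc <- pmin(pmax(cc, -1), 1)
  # row-major tie-break: first maximum scanning rows within columns... we
  # want smallest row, then smallest column
  pk <- which(cc == max(cc), arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE][1, ]
  structure(list(correlation_map = cc,
                 peak_offset = c(row = unname(pk[1]), col = unname(pk[2])),
                 peak_value = max(cc)),
            class = "template_match")
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("<template_match> peak %.4f at (row %d, col %d), map %d x %d\n",
              x$peak_value, x$peak_offset[1], x$peak_offset[2],
              nrow(x$correlation_map), ncol(x$correlation_map)))
  invisible(x)
}

# bilinear resampling of one matrix to a target size; the output grid maps
# linearly onto the input grid with matched corners, so a same-size resample
# is the identity and a linear ramp stays a linear ramp
.bilinear_resize <- function(img, out_size) {
  nr <- nrow(img); nc <- ncol(img)
  or_ <- out_size[1]; oc <- out_size[2]
  ri <- if (or_ == 1L) rep(1, 1) else 1 + (seq_len(or_) - 1) * (nr - 1) / (or_ - 1)
  ci <- if (oc == 1L) rep(1, 1) else 1 + (seq_len(oc) - 1) * (nc - 1) / (oc - 1)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, or_)
  if (nc == 1L) c0 <- rep(1L, oc)
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  a <- img[r0, c0, drop = FALSE]; b <- img[r0, c1, drop = FALSE]
  d <- img[r1, c0, drop = FALSE]; e <- img[r1, c1, drop = FALSE]
  wr <- matrix(fr, or_, oc); wc <- matrix(fc, or_, oc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + d * wr * (1 - wc) + e * wr * wc
}

#' Crop a cube to a bounding box and resample to a fixed size
#'
#' Every band is cropped identically and resampled with bilinear
#' interpolation to `out_size` (default 100 x 100, the working size of the
#' enhancement chain). The wavelength grid is unchanged. When the crop
#' already has the output size the resample is exact.
#'
#' @param cube a [hypercube].
#' @param bbox `c(row, col, height, width)`, 1-based top-left corner; must
#'   lie inside the cube.
#' @param out_size target `c(rows, cols)`.
#' @return A [hypercube] of spatial size `out_size`.
#' @export
crop_resize <- function(cube, bbox, out_size = c(100, 100)) {
  stopifnot(inherits(cube, "hypercube"), length(bbox) == 4L)
  d <- dim(cube$data)
  r0 <- bbox[1]; c0 <- bbox[2]; h <- bbox[3]; w <- bbox[4]
  if (r0 < 1 || c0 < 1 || h < 1 || w < 1 ||
      r0 + h - 1 > d[1] || c0 + w - 1 > d[2])
    stop("bbox lies outside the cube extents")
  out <- array(NA_real_, c(out_size, d[3]))
  for (b in seq_len(d[3])) {
    crop <- cube$data[r0:(r0 + h - 1), c0:(c0 + w - 1), b]
    out[, , b] <- if (h == out_size[1] && w == out_size[2]) crop
                  else .bilinear_resize(crop, out_size)
  }
  hypercube(out, cube$wavelengths, kind = cube$kind)
}
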