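#' Dark-current and white-reference frames
#'
#' The pair of reference measurements used for flat-field calibration: the
#' dark frame records the sensor offset with the light path blocked, the
#' white frame records the response to a near-perfect diffuse reflector
#' (e.g. spectralon). Either may be a single 2-D frame broadcast over all
#' bands, or a full M x N x L stack with one frame per band.
#'
#' @param dark,white numeric matrices (M x N) or arrays (M x N x L) of the
#'   same shape.
#' @return An object of class `ref_frames`.
#' @export
ref_frames <- function(dark, white) {
  if (is.matrix(dark)) dark <- array(dark, c(dim(dark), 1L))
  if (is.matrix(white)) white <- array(white, c(dim(white), 1L))
  if (!identical(dim(dark), dim(white)))
    stop("'dark' and 'white' must have identical dimensions")
  structure(list(dark = dark, white = white), class = "ref_frames")
}

#' @export
print.ref_frames <- function(x, ...) {
  d <- dim(x$dark)
  cat(sprintf("<ref_frames> %d x %d pixels, %d band frame(s)\n", d[1], d[2], d[3]))
  invisible(x)
}

# broadcast a reference array over the bands of a cube
.ref_band <- function(ref, b) if (dim(ref)[3L] == 1L) ref[, , 1L] else ref[, , b]

#' Locate defective sensor pixels
#'
#' A pixel is defective when its white-reference response does not exceed its
#' dark-current level by more than `tolerance`: there the denominator of the
#' reflectance formula is unusable and calibration output is masked out.
#'
#' @param refs a [ref_frames] pair.
#' @param tolerance minimum usable dynamic range in counts. The default is
#'   `1e-6` of the white frame's dynamic range.
#' @return Logical array of the reference shape; `TRUE` marks defective
#'   pixels.
#' @export
find_defective_pixels <- function(refs, tolerance = NULL) {
  stopifnot(inherits(refs, "ref_frames"))
  if (is.null(tolerance))
    tolerance <- 1e-6 * diff(range(refs$white))
  refs$white - refs$dark <= tolerance
}

#' Flat-field reflectance calibration
#'
#' Converts raw sensor counts to relative reflectance in percent, per pixel
#' and band:
#' \deqn{R_s(\lambda) = \frac{I_s(\lambda) - I_d(\lambda)}
#'                           {I_r(\lambda) - I_d(\lambda)} \times 100\%}
#' where \eqn{I_s} is the measured cube, \eqn{I_d} the dark frame and
#' \eqn{I_r} the white reference. Pixels flagged defective (white and dark
#' responses coincide) are set to `NA` rather than producing infinities.
#' Specular glare can legitimately exceed the white reference, so output is
#' clipped to `clip` (default 0-150 percent) to keep downstream 8-bit
#' quantisation well defined; set `clip = NULL` to disable.
#'
#' @param raw a raw-kind [hypercube].
#' @param refs a [ref_frames] pair with matching spatial dimensions.
#' @param clip length-2 numeric clip bounds in percent, or `NULL`.
#' @param tolerance passed to [find_defective_pixels()].
#' @return A reflectance-kind [hypercube]; defective pixels are `NA`.
#' @examples
#' raw <- hypercube(array(60, c(4, 4, 2)), c(500, 600))
#' refs <- ref_frames(dark = matrix(20, 4, 4), white = matrix(100, 4, 4))
#' flat_field_correct(raw, refs)$data[1, 1, ]  # 50% everywhere
#' @export
flat_field_correct <- function(raw, refs, clip = c(0, 150), tolerance = NULL) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "ref_frames"))
  d <- dim(raw$data)
  if (!identical(d[1:2], dim(refs$dark)[1:2]))
    stop("spatial dimensions of cube and reference frames differ")
  nrb <- dim(refs$dark)[3L]
  if (nrb != 1L && nrb != d[3L])
    stop("reference frames must be 2-D or have one frame per band")
  defect <- find_defective_pixels(refs, tolerance)
  if (all(defect)) stop("all reference pixels are defective")
  out <- array(NA_real_, d)
  for (b in seq_len(d[3L])) {
    dk <- .ref_band(refs$dark, b); wh <- .ref_band(refs$white, b)
    df <- if (dim(defect)[3L] == 1L) defect[, , 1L] else defect[, , b]
    r <- (raw$data[, , b] - dk) / (wh - dk) * 100
    r[df] <- NA_real_
    out[, , b] <- r
  }
  if (!is.null(clip)) {
    out[out < clip[1]] <- clip[1]
    out[out > clip[2]] <- clip[2]
  }
  hypercube(out, raw$wavelengths, kind = "reflectance")
}
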