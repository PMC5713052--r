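#' Hyperspectral cube
#'
#' A hyperspectral cube is an M x N x L array of spatial pixels by spectral
#' bands, together with the centre wavelength of every band. Raw cubes hold
#' sensor counts; reflectance cubes hold relative reflectance in percent
#' (see [flat_field_correct()]).
#'
#' @param data numeric M x N x L array (rows x columns x bands). A matrix is
#'   accepted and treated as a single-band cube.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length L.
#' @param kind `"raw"` (sensor counts) or `"reflectance"` (percent).
#' @return An object of class `hypercube`: a list with elements `data`,
#'   `wavelengths` and `kind`.
#' @examples
#' cube <- hypercube(array(runif(8 * 8 * 4), c(8, 8, 4)),
#'                   wavelengths = c(450, 550, 650, 750))
#' dim(cube)
#' @export
hypercube <- function(data, wavelengths = NULL, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be an M x N x L array")
  nb <- dim(data)[3L]
  if (is.null(wavelengths)) wavelengths <- seq_len(nb)
  if (length(wavelengths) != nb)
    stop("length(wavelengths) must equal the number of bands (", nb, ")")
  if (nb > 1L && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths), kind = kind),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), kind: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' Extract one band image from a cube
#'
#' @param cube a [hypercube].
#' @param band band index (1-based).
#' @return The band image as a numeric matrix.
#' @export
band_image <- function(cube, band) {
  stopifnot(inherits(cube, "hypercube"))
  if (band < 1L || band > dim(cube$data)[3L]) stop("band index out of range")
  cube$data[, , band]
}

#' Read and write ENVI header + raw image pairs
#'
#' Minimal ENVI-format I/O for hyperspectral cubes: a plain-text `.hdr` file
#' describing dimensions, interleave and data type, alongside a raw binary
#' file. Band-sequential (BSQ) interleave, little-endian IEEE doubles or
#' floats are supported, which covers the cubes this package writes.
#'
#' @param path path to the `.hdr` file (the raw file drops the extension or
#'   uses `.raw`).
#' @return `read_envi` returns a [hypercube]; `write_envi` invisibly returns
#'   `path`.
#' @name envi_io
NULL

#' @param cube a [hypercube] to write.
#' @rdname envi_io
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  if (!grepl("\\.hdr$", path)) path <- paste0(path, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength = { %s }", paste(format(cube$wavelengths, trim = TRUE),
                                         collapse = ", "))
  )
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  # BSQ: band-major, row-major within band
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube$data[, , b])), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname envi_io
#' @export
read_envi <- function(path) {
  if (!grepl("\\.hdr$", path)) path <- paste0(path, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", path)
  if (!file.exists(raw_path)) raw_path <- sub("\\.hdr$", "", path)
  lines <- readLines(path, warn = FALSE)
  getv <- function(key) {
    ln <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(".*=", "", ln[1]))
  }
  ns <- as.integer(getv("samples")); nl <- as.integer(getv("lines"))
  nb <- as.integer(getv("bands"))
  dtype <- as.integer(getv("data type"))
  interleave <- tolower(getv("interleave"))
  if (!identical(interleave, "bsq")) stop("only BSQ interleave is supported")
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  wl_ln <- grep("wavelength\\s*=", lines)
  wl <- NULL
  if (length(wl_ln)) {
    txt <- paste(lines[wl_ln[1]:length(lines)], collapse = " ")
    txt <- sub(".*\\{", "", txt); txt <- sub("\\}.*", "", txt)
    wl <- as.numeric(strsplit(txt, ",")[[1]])
  }
  kind <- getv("cube kind"); if (is.null(kind)) kind <- "raw"
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = ns * nl * nb, size = size,
                  endian = "little")
  data <- array(NA_real_, c(nl, ns, nb))
  per <- ns * nl
  for (b in seq_len(nb))
    data[, , b] <- matrix(vals[((b - 1) * per + 1):(b * per)], nl, ns,
                          byrow = TRUE)
  hypercube(data, wavelengths = wl, kind = kind)
}

#' Read and write hyperspectral cubes as multi-page TIFF stacks
#'
#' Each band is stored as one 32-bit float TIFF page, in band order. The
#' wavelength grid is not representable in baseline TIFF and must be carried
#' separately (an equally spaced grid is reconstructed from `wavelengths`).
#'
#' @param cube a [hypercube].
#' @param path path to the `.tif` file.
#' @param wavelengths wavelength grid to attach on reading.
#' @return `read_cube_tiff` returns a [hypercube]; `write_cube_tiff`
#'   invisibly returns `path`.
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  pages <- lapply(seq_len(dim(cube$data)[3]), function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_cube_tiff <- function(path, wavelengths = NULL,
                           kind = c("raw", "reflectance")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  data <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) data[, , b] <- pages[[b]]
  hypercube(data, wavelengths = wavelengths, kind = match.arg(kind))
}
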