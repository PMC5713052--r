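#' Spectral model for synthetic cornea scenes
#'
#' Describes the reflectance spectrum of healthy corneal tissue and the
#' band-dependent offset that an epithelial abrasion adds to it. The base
#' curve is a smooth spline through a handful of control points: rising
#' through the visible 450-600 nm range and flattening to a plateau in the
#' near infrared, the shape typical of unstained corneal tissue. The injury
#' offset is a smooth bump concentrated on the green-orange window
#' (~503-625 nm) where injured and intact epithelium differ most; it is
#' small relative to the base curve because the two classes have very
#' similar spectral morphology.
#'
#' @param wavelengths wavelength grid in nm (default 256 bands, 400-1000 nm).
#' @param control_wl,control_refl control points (nm, percent reflectance)
#'   for the healthy base curve.
#' @param delta_amplitude peak of the injury offset in percent reflectance
#'   (negative: abraded tissue reflects less).
#' @param delta_center,delta_width centre (nm) and Gaussian width (nm) of
#'   the injury offset bump.
#' @param noise_sd per-pixel additive noise, in percent reflectance.
#' @return An object of class `spectrum_model` with elements `wavelengths`,
#'   `base_curve`, `injured_delta` and `noise_sd`.
#' @examples
#' m <- spectrum_model()
#' range(m$base_curve)
#' @export
spectrum_model <- function(wavelengths = seq(400, 1000, length.out = 256),
                           control_wl = c(400, 450, 500, 550, 600, 700, 850, 1000),
                           control_refl = c(8, 12, 25, 38, 45, 50, 52, 52),
                           delta_amplitude = -4,
                           delta_center = 560,
                           delta_width = 45,
                           noise_sd = 1.5) {
  stopifnot(length(control_wl) == length(control_refl),
            length(wavelengths) >= 8L)
  base <- stats::spline(control_wl, control_refl, xout = wavelengths,
                        method = "fmm")$y
  base <- pmin(pmax(base, 0), 100)
  delta <- delta_amplitude *
    exp(-(wavelengths - delta_center)^2 / (2 * delta_width^2))
  if (any(base + delta < 0 | base + delta > 100))
    stop("base_curve + injured_delta leaves [0, 100]")
  if (max(abs(delta) / pmax(base, .Machine$double.eps)) > 0.2)
    stop("injured_delta exceeds 20% of the base curve")
  structure(list(wavelengths = as.numeric(wavelengths), base_curve = base,
                 injured_delta = delta, noise_sd = noise_sd),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_model> %d bands (%.0f-%.0f nm), base %.1f-%.1f%%, ",
                     "peak injury offset %+.2f%%, noise sd %.2f%%\n"),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$base_curve), max(x$base_curve),
              x$injured_delta[which.max(abs(x$injured_delta))], x$noise_sd))
  invisible(x)
}

# disk mask helper (1-based centre, inclusive radius)
.disk_mask <- function(nr, nc, center, radius) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

# separable gaussian blur with reflected borders, used to round mask edges
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
  p <- img[pad_idx(nrow(img)), pad_idx(ncol(img))]
  p <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  p <- t(apply(p, 1, function(row) stats::filter(row, k, sides = 2)))
  p[r + seq_len(nrow(img)), r + seq_len(ncol(img))]
}

# smooth-edged connected injury blob: jittered disk, blurred, thresholded
.injury_blob <- function(nr, nc, center, radius, edge_sigma = 2) {
  base <- .disk_mask(nr, nc, center, radius)
  jitter <- matrix(stats::rnorm(nr * nc), nr, nc)
  jitter <- .gauss_blur(jitter, sigma = max(3, radius / 3))
  jitter <- jitter / max(abs(jitter), .Machine$double.eps)
  soft <- .gauss_blur(base + 0.35 * jitter * base, edge_sigma)
  soft >= 0.5
}

#' Generate one synthetic hyperspectral cornea scene
#'
#' Builds the full set of acquisition products for one eye: a raw sensor
#' cube, the dark-current and white-reference frames that generated it, and
#' ground-truth injury and glare masks. The forward model per pixel and band
#' is
#' `counts = dark + (reflectance / 100) * (white - dark) + noise`,
#' so noise-free scenes invert exactly under [flat_field_correct()].
#' Healthy tissue carries the model's base spectrum at every pixel; injured
#' scenes add the model's `injured_delta` inside a compact connected blob
#' with a smooth boundary. Specular glare is simulated as small disks pinned
#' at the sensor maximum in every band; the enhancement chain's ball-SE
#' erosion exists to remove exactly this artefact.
#'
#' @param model a [spectrum_model].
#' @param size spatial dimensions `c(rows, cols)`, at least 32 x 32.
#' @param label `"healthy"` or `"injured"`.
#' @param injury_geometry optional list with `center` (row, col) and
#'   `radius` in pixels; default places one blob covering roughly 10% of the
#'   image area, jittered by the seed. Must lie inside the image.
#' @param glare_count number of saturated glare disks (default 2).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param sensor_max saturation level of the simulated sensor, in counts.
#' @return An object of class `cornea_scene`: list with `cube` (raw
#'   [hypercube]), `dark`, `white` (matrices), `injury_mask`, `glare_mask`
#'   (logical matrices), `label` and `seed`.
#' @examples
#' sc <- make_scene(spectrum_model(noise_sd = 0), size = c(48, 48),
#'                  label = "healthy", glare_count = 0, seed = 1)
#' refl <- flat_field_correct(sc$cube, ref_frames(sc$dark, sc$white))
#' max(abs(refl$data[1, 1, ] - spectrum_model()$base_curve))
#' @export
make_scene <- function(model, size = c(100, 100),
                       label = c("healthy", "injured"),
                       injury_geometry = NULL, glare_count = 2L,
                       seed = 1L, sensor_max = 4095) {
  stopifnot(inherits(model, "spectrum_model"))
  label <- match.arg(label)
  nr <- size[1]; nc <- size[2]
  if (nr < 32L || nc < 32L) stop("scene size must be at least 32 x 32")
  nb <- length(model$wavelengths)
  set.seed(as.integer(seed))

  # reference frames: uniform dark offset, smoothly vignetted illumination
  dark <- matrix(100, nr, nc)
  rr <- (outer(seq_len(nr), rep(1, nc)) - (nr + 1) / 2) / nr
  cc <- (outer(rep(1, nr), seq_len(nc)) - (nc + 1) / 2) / nc
  white <- dark + 3900 * (0.90 + 0.10 * cos(pi * sqrt(rr^2 + cc^2)))

  injury_mask <- matrix(FALSE, nr, nc)
  if (label == "injured") {
    if (is.null(injury_geometry)) {
      radius <- sqrt(0.10 * nr * nc / pi)
      center <- c(round(nr / 2 + stats::runif(1, -0.12, 0.12) * nr),
                  round(nc / 2 + stats::runif(1, -0.12, 0.12) * nc))
      injury_geometry <- list(center = center, radius = radius)
    }
    g <- injury_geometry
    if (g$center[1] - g$radius < 1 || g$center[1] + g$radius > nr ||
        g$center[2] - g$radius < 1 || g$center[2] + g$radius > nc)
      stop("injury geometry extends outside the image bounds")
    injury_mask <- .injury_blob(nr, nc, g$center, g$radius)
  }

  glare_mask <- matrix(FALSE, nr, nc)
  if (glare_count > 0L) {
    for (i in seq_len(glare_count)) {
      gc_r <- stats::runif(1, 0.2, 0.8) * nr
      gc_c <- stats::runif(1, 0.2, 0.8) * nc
      glare_mask <- glare_mask | .disk_mask(nr, nc, c(gc_r, gc_c),
                                            stats::runif(1, 1.5, 3.5))
    }
  }

  gain <- white - dark
  cube <- array(NA_real_, c(nr, nc, nb))
  for (b in seq_len(nb)) {
    refl <- matrix(model$base_curve[b], nr, nc)
    if (label == "injured")
      refl[injury_mask] <- refl[injury_mask] + model$injured_delta[b]
    counts <- dark + (refl / 100) * gain
    if (model$noise_sd > 0)
      counts <- counts + (model$noise_sd / 100) * gain *
        matrix(stats::rnorm(nr * nc), nr, nc)
    counts[glare_mask] <- sensor_max
    cube[, , b] <- counts
  }
  structure(list(cube = hypercube(cube, model$wavelengths, kind = "raw"),
                 dark = dark, white = white,
                 injury_mask = injury_mask, glare_mask = glare_mask,
                 label = label, seed = as.integer(seed)),
            class = "cornea_scene")
}

#' @export
print.cornea_scene <- function(x, ...) {
  d <- dim(x$cube$data)
  cat(sprintf("<cornea_scene> %s, %d x %d x %d, injury %.1f%% of area, %d glare px (seed %d)\n",
              x$label, d[1], d[2], d[3], 100 * mean(x$injury_mask),
              sum(x$glare_mask), x$seed))
  invisible(x)
}

#' Generate a labelled cohort of synthetic scenes
#'
#' Labels are laid out healthy-first then shuffled by the master seed;
#' per-scene child seeds are `seed + index`, so any scene can be regenerated
#' independently.
#'
#' @param n_healthy,n_injured number of scenes per class.
#' @param model a [spectrum_model].
#' @param seed master integer seed.
#' @param ... passed to [make_scene()] (e.g. `size`, `glare_count`).
#' @return List of [make_scene()] scenes (possibly empty).
#' @export
make_cohort <- function(n_healthy, n_injured, model, seed = 1L, ...) {
  stopifnot(n_healthy >= 0, n_injured >= 0)
  n <- n_healthy + n_injured
  if (n == 0L) return(list())
  labels <- c(rep("healthy", n_healthy), rep("injured", n_injured))
  set.seed(as.integer(seed))
  labels <- labels[sample.int(n)]
  lapply(seq_len(n), function(i)
    make_scene(model, label = labels[i], seed = as.integer(seed) + i, ...))
}

#' The packaged 25-eye histogram-feature table
#'
#' Returns the printed four-feature table for 25 porcine eyes (11 healthy,
#' 14 with corneal epithelium injury): per eye, the mean, standard
#' deviation, skewness and kurtosis of the enhanced image's gray-level
#' histogram. This is the dataset on which the packaged SVM replication runs.
#'
#' @return A data.frame with columns `eye_id`, `label` (factor,
#'   healthy/injured), `mean`, `std`, `skewness`, `kurtosis`; 25 rows.
#' @examples
#' tab <- table3_features()
#' table(tab$label)
#' @export
table3_features <- function() {
  path <- system.file("extdata", "table3_features.csv", package = "corneaHSI",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- factor(tab$label, levels = c("healthy", "injured"))
  tab
}
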