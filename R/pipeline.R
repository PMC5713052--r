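#' CNR evaluation masks for a synthetic scene
#'
#' Region of interest = the ground-truth injury mask; background = the rest
#' of the image, excluding a dilated margin around the injury and any glare
#' pixels.
#'
#' @param scene a [make_scene()] scene.
#' @param margin safety margin (pixels) dilated around the injury.
#' @return List with logical matrices `roi` and `bg`.
#' @export
scene_cnr_masks <- function(scene, margin = 3L) {
  stopifnot(inherits(scene, "cornea_scene"))
  roi <- scene$injury_mask
  bg <- !binary_dilate(roi, margin) & !scene$glare_mask
  list(roi = roi, bg = bg)
}

# per-eye stage runner with error context
.run_stage <- function(eye_id, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("eye %s, stage %s: %s", eye_id, stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes calibrate -> locate ROI -> enhance -> extract features on every
#' eye, then cross-validates the SVM on the chosen feature pair. Input is
#' either a list of in-memory synthetic scenes ([make_cohort()]) or a
#' manifest data.frame with columns `eye_id`, `cube_path`, `dark_path`,
#' `white_path`, `label` pointing at ENVI cubes and TIFF reference frames.
#' With `template = NULL` the region of interest is the largest centred
#' square (identity when the scene is already at `out_size`); otherwise
#' FFT template matching locates it per eye.
#'
#' Identical inputs, configuration and seed give identical outputs. If
#' `out_dir` is given, the feature table (CSV), the evaluation report and a
#' provenance block (JSON) and the per-eye enhanced images (PNG) are
#' persisted there.
#'
#' @param scenes list of `cornea_scene` objects, or a manifest data.frame.
#' @param enhance_cfg an [enhance_config()].
#' @param features character vector of feature columns for classification.
#' @param C,sigma,k,seed,normalize classifier settings, see
#'   [cross_validate()].
#' @param template optional matrix for [match_template()] on band 100.
#' @param out_size ROI size.
#' @param out_dir optional output directory.
#' @return List of class `pipeline_result`: `features` (data.frame),
#'   `report` (`cv_report`), `enhanced` (list of `enhanced_image`),
#'   `provenance`.
#' @export
run_pipeline <- function(scenes, enhance_cfg = enhance_config(),
                         features = c("mean", "skewness"),
                         C = 500, sigma = 2.658, k = 10L, seed = 1L,
                         normalize = c("joint", "fold", "none"),
                         template = NULL, out_size = c(100, 100),
                         out_dir = NULL) {
  normalize <- match.arg(normalize)
  if (is.data.frame(scenes)) scenes <- .load_manifest(scenes)
  if (!length(scenes)) stop("empty manifest: nothing to process")
  labels <- vapply(scenes, function(s) s$label, character(1))
  eye_ids <- vapply(seq_along(scenes), function(i) {
    id <- scenes[[i]]$eye_id
    if (is.null(id)) as.character(i) else as.character(id)
  }, character(1))

  enhanced <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    refl <- .run_stage(eye_ids[i], "calibrate",
                       flat_field_correct(sc$cube, ref_frames(sc$dark, sc$white)))
    roi <- .run_stage(eye_ids[i], "roi", {
      d <- dim(refl$data)
      if (!is.null(template)) {
        band <- min(100L, d[3])
        tm <- match_template(refl$data[, , band], template)
        side <- min(nrow(template), ncol(template))
        crop_resize(refl, c(tm$peak_offset[1], tm$peak_offset[2],
                            min(side, d[1] - tm$peak_offset[1] + 1),
                            min(side, d[2] - tm$peak_offset[2] + 1)),
                    out_size)
      } else {
        side <- min(d[1], d[2])
        crop_resize(refl, c(floor((d[1] - side) / 2) + 1,
                            floor((d[2] - side) / 2) + 1, side, side),
                    out_size)
      }
    })
    enhanced[[i]] <- .run_stage(eye_ids[i], "enhance",
                                enhance_image(roi, enhance_cfg))
  }
  feats <- extract_features(enhanced, labels, eye_ids)
  X <- as.matrix(feats[, features, drop = FALSE])
  report <- cross_validate(X, feats$label, k = k, C = C, sigma = sigma,
                           seed = seed, normalize = normalize)
  prov <- list(package = "corneaHSI",
               version = as.character(utils::packageVersion("corneaHSI")),
               n_scenes = length(scenes), features = features,
               C = C, sigma = sigma, k = k, seed = seed,
               normalize = normalize,
               enhance_cfg = unclass(enhance_cfg))
  res <- structure(list(features = feats, report = report,
                        enhanced = enhanced, provenance = prov),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .persist_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d eyes (%d healthy, %d injured)\n",
              nrow(x$features), sum(x$features$label == "healthy"),
              sum(x$features$label == "injured")))
  print(x$report)
  invisible(x)
}

.load_manifest <- function(manifest) {
  need <- c("eye_id", "cube_path", "dark_path", "white_path", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    # reference frames are stored as counts / 65535 (see write_cohort)
    read_img <- function(p) {
      im <- tiff::readTIFF(p)
      if (length(dim(im)) == 3L) im <- im[, , 1]
      im * 65535
    }
    structure(list(cube = read_envi(row$cube_path),
                   dark = read_img(row$dark_path),
                   white = read_img(row$white_path),
                   injury_mask = NULL, glare_mask = NULL,
                   label = row$label, eye_id = row$eye_id,
                   seed = NA_integer_),
              class = "cornea_scene")
  })
}

.persist_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  rep <- res$report
  jsonlite::write_json(
    list(auc = rep$auc, mse = rep$mse, accuracy = rep$accuracy,
         confusion = as.list(rep$confusion), iterations = rep$iterations,
         seed = rep$seed, settings = rep$settings,
         roc = rep$roc, provenance = res$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (i in seq_along(res$enhanced))
    png::writePNG(res$enhanced[[i]]$image / 255,
                  file.path(out_dir, sprintf("enhanced_%s.png",
                                             res$features$eye_id[i])))
  invisible(out_dir)
}

#' Write a cohort of scenes to disk with a manifest
#'
#' Persists each scene as an ENVI cube plus TIFF reference frames and PNG
#' ground-truth masks, and returns (and writes) a manifest suitable for
#' [run_pipeline()].
#'
#' @param scenes list of [make_scene()] scenes.
#' @param dir output directory.
#' @return The manifest data.frame, invisibly; also written as
#'   `manifest.csv`.
#' @export
write_cohort <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    base <- file.path(dir, sprintf("eye%03d", i))
    write_envi(sc$cube, paste0(base, ".hdr"))
    # reference frames are counts; store scaled to [0,1] 32-bit float pages
    tiff::writeTIFF(sc$dark / 65535, paste0(base, "_dark.tif"),
                    bits.per.sample = 32L)
    tiff::writeTIFF(sc$white / 65535, paste0(base, "_white.tif"),
                    bits.per.sample = 32L)
    png::writePNG(sc$injury_mask * 1, paste0(base, "_injury.png"))
    data.frame(eye_id = sprintf("eye%03d", i),
               cube_path = paste0(base, ".hdr"),
               dark_path = paste0(base, "_dark.tif"),
               white_path = paste0(base, "_white.tif"),
               label = sc$label)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Replicate the feature-table classification grid
#'
#' Runs [cross_validate()] on a feature table for every combination of
#' feature set and (C, sigma) cell, over a set of fold seeds, and reports
#' the per-cell mean, minimum and maximum of the pooled AUC and MSE plus
#' the modal AUC. Leave-one-out (`k = n`) has no fold randomness, so its
#' output is seed-independent.
#'
#' @param features a feature table in the [table3_features()] layout.
#' @param feature_sets list of character vectors naming feature columns.
#' @param params list of `c(C = , sigma = )` cells.
#' @param k folds; `seeds` fold-assignment seeds.
#' @param normalize see [cross_validate()]; joint normalisation is the
#'   replication convention.
#' @return data.frame, one row per (feature set x cell).
#' @export
replicate_table4 <- function(features = table3_features(),
                             feature_sets = list(c("mean", "skewness")),
                             params = list(c(C = 1, sigma = 1),
                                           c(C = 500, sigma = 1.658),
                                           c(C = 500, sigma = 2.658)),
                             k = 10L, seeds = 1:20,
                             normalize = c("joint", "fold", "none")) {
  normalize <- match.arg(normalize)
  bad <- setdiff(unique(unlist(feature_sets)), names(features))
  if (length(bad)) stop("unknown feature names: ", paste(bad, collapse = ", "))
  y <- features$label
  rows <- list()
  for (fs in feature_sets) for (p in params) {
    X <- as.matrix(features[, fs, drop = FALSE])
    runs <- lapply(seeds, function(s)
      cross_validate(X, y, k = k, C = p[["C"]], sigma = p[["sigma"]],
                     seed = s, normalize = normalize))
    aucs <- vapply(runs, `[[`, numeric(1), "auc")
    mses <- vapply(runs, `[[`, numeric(1), "mse")
    tab <- sort(table(round(aucs, 6)), decreasing = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      features = paste(fs, collapse = "+"),
      C = p[["C"]], sigma = p[["sigma"]],
      auc_mean = mean(aucs), auc_min = min(aucs), auc_max = max(aucs),
      auc_modal = as.numeric(names(tab)[1]),
      mse_mean = mean(mses), mse_min = min(mses), mse_max = max(mses),
      iterations_mean = mean(vapply(runs, `[[`, numeric(1), "iterations")))
  }
  do.call(rbind, rows)
}
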