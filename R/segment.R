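#' Default segmentation parameters
#'
#' The segmentation recipe is a transparent standard pipeline: excess-green
#' index, thresholding (fixed or Otsu), morphological opening/closing, and
#' removal of small connected components. All knobs are exposed here.
#'
#' @param threshold `"otsu"` for automatic selection on the excess-green
#'   channel, or a fixed numeric threshold in excess-green units on the
#'   0–255 scale.
#' @param min_exg floor on the effective threshold (excess-green units);
#'   prevents Otsu from splitting noise on plant-free images.
#' @param open_radius,close_radius disc structuring-element radii in pixels
#'   for morphological opening and closing; 0 (the default) skips the step.
#'   Grass blades project at only 2-3 px width, so opening at radius 1
#'   erases them and closing bridges neighbouring blades; both stay off for
#'   silhouette work and are available for noisier real imagery.
#' @param min_size minimum connected-component size in pixels; all surviving
#'   components together form the plant (grass blades separate in
#'   projection, but each frame holds a single plant).
#' @param roi_exclude optional rectangle `c(row_min, row_max, col_min,
#'   col_max)` forced to background (e.g. a pot/carrier exclusion zone for
#'   real imagery).
#' @return a named list of parameters for [segment_plant()].
#' @export
segment_params <- function(threshold = "otsu", min_exg = 20,
                           open_radius = 0, close_radius = 0,
                           min_size = 15, roi_exclude = NULL) {
  list(threshold = threshold, min_exg = min_exg, open_radius = open_radius,
       close_radius = close_radius, min_size = min_size,
       roi_exclude = roi_exclude)
}

#' Segment the plant from an RGB view image
#'
#' Foreground is selected by the excess-green vegetation index
#' `ExG = 2G - R - B`: plant tissue is green-dominant, the pot and imaging
#' cabinet are neutral. The ExG channel is thresholded (fixed value or Otsu
#' with a floor), cleaned by morphological opening and closing with disc
#' structuring elements, and connected components smaller than `min_size`
#' pixels are removed. If nothing survives, an all-background mask is
#' returned with its `empty` attribute set (not an error), so batch runs can
#' record a missing observation and continue.
#'
#' @param image numeric array `H x W x 3` with values in \[0, 1\] (as read
#'   by [png::readPNG()]) or \[0, 255\].
#' @param params parameter list from [segment_params()].
#' @return logical `H x W` matrix (`TRUE` = plant) with attribute `empty`.
#' @export
segment_plant <- function(image, params = segment_params()) {
  if (length(dim(image)) == 2L) {
    stop("`image` must be an RGB array with 3 channels", call. = FALSE)
  }
  if (dim(image)[3] < 3L) stop("`image` must have 3 channels", call. = FALSE)
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) <= 1.001) img <- img * 255
  exg <- 2 * img[, , 2] - img[, , 1] - img[, , 3]
  if (!is.null(params$roi_exclude)) {
    r <- params$roi_exclude
    exg[r[1]:r[2], r[3]:r[4]] <- -510
  }

  th <- params$threshold
  if (identical(th, "otsu")) {
    norm <- (exg + 510) / 1020
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * 1020 - 510
  }
  th <- max(th, params$min_exg)
  mask <- exg > th

  if (any(mask)) {
    m <- EBImage::Image(mask * 1)
    if (params$open_radius > 0) {
      m <- EBImage::opening(m, EBImage::makeBrush(2L * params$open_radius + 1L, "disc"))
    }
    if (params$close_radius > 0) {
      m <- EBImage::closing(m, EBImage::makeBrush(2L * params$close_radius + 1L, "disc"))
    }
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= params$min_size)
    mask <- matrix(as.integer(lab) %in% keep, nrow = nrow(exg))
  }

  empty <- !any(mask)
  if (empty) ryenue_log("segmentation found no plant pixels; empty mask", "WARN")
  attr(mask, "empty") <- empty
  mask
}

#' Is a segmentation result empty?
#'
#' @param mask result of [segment_plant()].
#' @return `TRUE` when the mask carries the empty flag or has no foreground.
#' @export
is_empty_mask <- function(mask) {
  isTRUE(attr(mask, "empty")) || !any(mask)
}

#' Extract shape features for a directory tree of view images
#'
#' Walks the documented layout `<image_root>/<pot_id>/<day>/<view>.png`
#' (views `top`, `side-0`, `side-90`), segments every image and computes the
#' seven shape features. Unreadable files and empty segmentations do not
#' abort the batch: their rows are flagged and logged. Row order is
#' deterministic: by `pot_id`, then numeric `day`, then view name.
#'
#' @param image_root root directory of the image tree.
#' @param params segmentation parameters ([segment_params()]).
#' @param save_masks optional directory; segmentation masks are written
#'   there as single-channel PNGs mirroring the input layout.
#' @return `data.frame` with columns `pot_id`, `day`, `view`, the seven
#'   features, `empty_flag`, `read_error`.
#' @export
batch_extract <- function(image_root, params = segment_params(),
                          save_masks = NULL) {
  files <- list.files(image_root, pattern = "\\.(png|PNG)$", recursive = TRUE,
                      full.names = FALSE)
  if (!length(files)) stop("no PNG images found under ", image_root, call. = FALSE)
  parts <- strsplit(files, "/")
  ok <- lengths(parts) == 3L
  if (any(!ok)) ryenue_log(sprintf("%d file(s) outside <pot>/<day>/<view>.png layout skipped",
                                   sum(!ok)), "WARN")
  parts <- parts[ok]; files <- files[ok]
  meta <- data.frame(
    pot_id = vapply(parts, `[`, "", 1L),
    day = as.numeric(vapply(parts, `[`, "", 2L)),
    view = sub("\\.(png|PNG)$", "", vapply(parts, `[`, "", 3L)),
    file = files, stringsAsFactors = FALSE
  )
  meta <- meta[order(meta$pot_id, meta$day, meta$view), ]

  feat_na <- extract_features(matrix(TRUE, 1, 1))[0, ]
  rows <- lapply(seq_len(nrow(meta)), function(k) {
    path <- file.path(image_root, meta$file[k])
    base <- meta[k, c("pot_id", "day", "view")]
    img <- tryCatch(png::readPNG(path), error = function(e) NULL)
    if (is.null(img)) {
      ryenue_log(paste("unreadable image:", path), "WARN")
      return(cbind(base, na_features(), empty_flag = NA, read_error = TRUE))
    }
    mask <- segment_plant(img, params)
    if (!is.null(save_masks)) {
      out <- file.path(save_masks, meta$pot_id[k], format(meta$day[k]))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(mask * 1, file.path(out, paste0(meta$view[k], ".png")))
    }
    if (is_empty_mask(mask)) {
      return(cbind(base, na_features(), empty_flag = TRUE, read_error = FALSE))
    }
    cbind(base, extract_features(mask), empty_flag = FALSE, read_error = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

na_features <- function() {
  data.frame(area = NA_real_, caliper_length = NA_real_, compactness = NA_real_,
             convex_hull_area = NA_real_, convex_hull_circumference = NA_real_,
             width = NA_real_, height = NA_real_)
}
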