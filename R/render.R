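# Procedural silhouette model of a potted ryegrass plant. Tillers are
# tapered, gently drooping blades radiating from a crown; occlusion is
# irrelevant for binary silhouettes (painter's order). Photorealism is a
# non-goal: the renderer exists to give the segmentation and feature stages
# a ground-truthed input, so plant pixels are green-dominant by construction
# (G >= R + 30 and G >= B + 30 on the 0-255 scale).

#' Procedural plant specification
#'
#' Draws a random set of tillers (grass blades) for one plant: per tiller a
#' blade length, basal width, droop curvature, azimuth and elevation angle.
#' All linear dimensions are in pixels. A fully explicit `tillers` data
#' frame may be supplied instead of random draws (useful for forcing
#' degenerate geometries in tests).
#'
#' @param n_tillers number of blades (>= 1).
#' @param length_range,width_range blade length and basal width ranges, px.
#' @param curvature_range droop fraction in \[0, 1\): 0 = straight blade,
#'   larger values bend the tip further from the initial elevation.
#' @param elevation_range initial blade elevation above horizontal, degrees.
#' @param seed integer seed.
#' @param tillers optional `data.frame` with columns `length`, `width`,
#'   `curvature`, `azimuth` (radians), `elevation` (radians) overriding the
#'   random draws.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(n_tillers = 12, length_range = c(45, 85),
                       width_range = c(3, 5.5), curvature_range = c(0.15, 0.55),
                       elevation_range = c(55, 85), seed = 1L, tillers = NULL) {
  if (is.null(tillers)) {
    n_tillers <- check_count(n_tillers, "n_tillers")
    tillers <- with_seed(seed, data.frame(
      length = runif(n_tillers, length_range[1], length_range[2]),
      width = runif(n_tillers, width_range[1], width_range[2]),
      curvature = runif(n_tillers, curvature_range[1], curvature_range[2]),
      azimuth = runif(n_tillers, 0, 2 * pi),
      elevation = runif(n_tillers, elevation_range[1], elevation_range[2]) * pi / 180
    ))
  }
  stopifnot(nrow(tillers) >= 1L, all(tillers$length > 0), all(tillers$width > 0))
  structure(list(tillers = tillers, seed = seed), class = "plant_spec")
}

# 3D centerline samples of one tiller: the blade starts at the crown with
# the given elevation and droops so the local elevation decays with arc
# length; width tapers towards the tip. Returns per-sample (x, y, z, halfw).
tiller_samples <- function(tl, step = 0.6) {
  n <- max(2L, ceiling(tl$length / step))
  s <- seq(0, tl$length, length.out = n)
  theta <- tl$elevation * (1 - tl$curvature * s / tl$length)
  ds <- diff(c(0, s))
  dx <- cumsum(ds * cos(theta) * cos(tl$azimuth))
  dy <- cumsum(ds * cos(theta) * sin(tl$azimuth))
  dz <- cumsum(ds * sin(theta))
  halfw <- pmax(tl$width / 2 * (1 - 0.75 * s / tl$length), 1.1)
  cbind(x = dx, y = dy, z = dz, halfw = halfw)
}

# Project 3D samples to the pixel plane of a view. side-90 is the side-0
# geometry rotated 90 degrees about the vertical axis (x, y) -> (y, -x).
project_view <- function(pts, view) {
  switch(view,
    "top" = cbind(u = pts[, "x"], v = pts[, "y"], halfw = pts[, "halfw"]),
    "side-0" = cbind(u = pts[, "x"], v = pts[, "z"], halfw = pts[, "halfw"]),
    "side-90" = cbind(u = pts[, "y"], v = pts[, "z"], halfw = pts[, "halfw"]),
    stop("unknown view: ", view, call. = FALSE)
  )
}

#' Render one view of a synthetic plant
#'
#' Rasterizes the plant silhouette of `spec` into an RGB image with a
#' neutral imaging-cabinet background and a white pot, and returns the
#' exact set of rendered plant pixels as the ground-truth mask. Rendering
#' is deterministic: the same spec, view, size and seed give bit-identical
#' output. If any part of the projected plant falls outside the frame an
#' overflow error is raised — silhouettes are never silently cropped.
#'
#' @param spec a [plant_spec()].
#' @param view `"top"`, `"side-0"` or `"side-90"`.
#' @param image_size image height = width in pixels.
#' @param background `"cabinet"` (neutral grey + white pot) or `"white"`.
#' @param seed integer seed for the per-pixel green shading.
#' @return list with `image` (`H x W x 3` array in \[0, 1\]) and `mask`
#'   (logical `H x W`, `TRUE` = plant pixel).
#' @export
render_plant <- function(spec, view = c("side-0", "side-90", "top"),
                         image_size = 192, background = c("cabinet", "white"),
                         seed = 1L) {
  view <- match.arg(view)
  background <- match.arg(background)
  H <- W <- check_count(image_size, "image_size")
  mask <- render_mask(spec, view, H, W)

  img <- array(0, dim = c(H, W, 3))
  if (background == "cabinet") {
    img[, , 1] <- img[, , 2] <- img[, , 3] <- 200 / 255
    # white pot: trapezoid at the bottom for side views, disc for top view
    pot_h <- round(0.16 * H); cx <- (W + 1) / 2
    if (view == "top") {
      rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      pot <- (rr - (H + 1) / 2)^2 + (cc - cx)^2 <= (0.42 * W)^2
    } else {
      rows <- (H - pot_h + 1L):H
      pot <- matrix(FALSE, H, W)
      half_top <- 0.30 * W; half_bot <- 0.26 * W
      for (r in rows) {
        f <- (r - (H - pot_h)) / pot_h
        half <- half_top + (half_bot - half_top) * f
        cols <- max(1L, floor(cx - half)):min(W, ceiling(cx + half))
        pot[r, cols] <- TRUE
      }
    }
    for (ch in 1:3) { p <- img[, , ch]; p[pot] <- 247 / 255; img[, , ch] <- p }
  } else {
    img[, , 1] <- img[, , 2] <- img[, , 3] <- 1
  }

  n_fg <- sum(mask)
  with_seed(seed, {
    shade <- runif(n_fg, 0, 60) / 255       # per-pixel green variation
    g <- 140 / 255 + shade
    r <- g - (35 + runif(n_fg, 0, 25)) / 255
    b <- g - (40 + runif(n_fg, 0, 30)) / 255
    p <- img[, , 1]; p[mask] <- pmax(r, 0); img[, , 1] <- p
    p <- img[, , 2]; p[mask] <- pmin(g, 1); img[, , 2] <- p
    p <- img[, , 3]; p[mask] <- pmax(b, 0); img[, , 3] <- p
  })
  list(image = img, mask = mask)
}

# Rasterize the ground-truth silhouette only. Crown position: image centre
# (top view) or centred horizontally on top of the pot (side views).
render_mask <- function(spec, view, H, W) {
  pot_h <- round(0.16 * H)
  crown_u <- (W + 1) / 2
  crown_v <- if (view == "top") (H + 1) / 2 else H - pot_h  # row of the crown
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(spec$tillers))) {
    pr <- project_view(tiller_samples(spec$tillers[k, ]), view)
    px <- crown_u + pr[, "u"]
    py <- if (view == "top") crown_v + pr[, "v"] else crown_v - pr[, "v"]
    lo_x <- px - pr[, "halfw"]; hi_x <- px + pr[, "halfw"]
    lo_y <- py - pr[, "halfw"]; hi_y <- py + pr[, "halfw"]
    if (any(lo_x < 0.5) || any(hi_x > W + 0.5) || any(lo_y < 0.5) || any(hi_y > H + 0.5)) {
      stop(sprintf("plant projection exceeds the %dx%d frame in view %s; increase image_size",
                   H, W, view), call. = FALSE)
    }
    for (m in seq_along(px)) {
      cols <- max(1L, ceiling(lo_x[m])):min(W, floor(hi_x[m]))
      rows <- max(1L, ceiling(lo_y[m])):min(H, floor(hi_y[m]))
      hw2 <- pr[m, "halfw"]^2
      for (r in rows) {
        dy2 <- (r - py[m])^2
        sel <- cols[(cols - px[m])^2 + dy2 <= hw2]
        if (length(sel)) mask[r, sel] <- TRUE
      }
    }
  }
  mask
}

#' Scale a plant spec towards a target side-view silhouette area
#'
#' Generates a random [plant_spec()] and rescales blade widths (and, if
#' needed, lengths) so that its rendered side-0 silhouette area approximates
#' `target_area` pixels. Used by the pipeline to couple rendered imagery to
#' simulated growth trajectories; the match is approximate (blade overlap
#' makes area sublinear in width), which simply adds realistic rendering
#' noise on top of the trajectory.
#'
#' @param target_area target side-view projected area, pixels.
#' @param image_size frame size used for the calibration raster.
#' @param seed integer seed for the underlying random spec.
#' @param n_tillers number of blades.
#' @return a [plant_spec()].
#' @export
plant_spec_for_area <- function(target_area, image_size = 192, seed = 1L,
                                n_tillers = 12) {
  check_positive(target_area, "target_area")
  sp <- plant_spec(n_tillers = n_tillers, seed = seed)
  for (it in 1:2) {
    a <- sum(render_mask(sp, "side-0", image_size, image_size))
    f <- target_area / a
    sp$tillers$width <- pmin(pmax(sp$tillers$width * f, 2.4), 14)
    if (f > 2.5) sp$tillers$length <- pmin(sp$tillers$length * min(sqrt(f / 2.5), 1.4),
                                           0.42 * image_size)
  }
  sp
}
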