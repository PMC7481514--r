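# Exact pixel-corner geometry for silhouette shape features.
#
# Convention: pixel (row i, col j) occupies the unit square
# [j-1, j] x [i-1, i] in (x, y) image coordinates. All hull-based features
# (convex hull area, circumference, caliper length) are computed over the
# four corner points of every foreground pixel. This guarantees
# area <= convex_hull_area (the pixel squares are inside their own hull),
# so compactness = area / hull_area is always in (0, 1], with equality for
# filled rectangles; a hull over pixel *centers* can violate that bound on
# thin shapes.

# 4 corner points per foreground pixel, deduplicated. Returns an n x 2
# matrix of (x, y).
pixel_corners <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 2))
  i <- idx[, 1]; j <- idx[, 2]
  x <- c(j - 1, j, j - 1, j)
  y <- c(i - 1, i - 1, i, i)
  pts <- unique(cbind(x, y))
  dimnames(pts) <- NULL
  pts
}

# Convex hull vertices in counter-clockwise order with collinear vertices
# dropped. Vertex finding is delegated to grDevices::chull.
hull_vertices <- function(pts) {
  if (nrow(pts) == 1L) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  P <- pts[h, , drop = FALSE]
  if (signed_area2(P) < 0) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  drop_collinear(P)
}

signed_area2 <- function(P) {
  n <- nrow(P)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])
}

drop_collinear <- function(P) {
  n <- nrow(P)
  if (n < 3L) return(P)
  keep <- logical(n)
  for (k in seq_len(n)) {
    a <- P[if (k == 1L) n else k - 1L, ]
    b <- P[k, ]
    c <- P[if (k == n) 1L else k + 1L, ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    keep[k] <- abs(cr) > 1e-9
  }
  P[keep, , drop = FALSE]
}

polygon_area <- function(P) abs(signed_area2(P)) / 2

polygon_perimeter <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((P[j, 1] - P[, 1])^2 + (P[j, 2] - P[, 2])^2))
}

# Rotating-calipers diameter of a convex polygon (counter-clockwise,
# no collinear vertices): for each edge, advance the antipodal vertex while
# the triangle area keeps growing; the diameter is realized by one of the
# edge-endpoint / antipode pairs visited.
calipers_diameter <- function(P) {
  n <- nrow(P)
  if (n == 1L) return(0)
  d2 <- function(a, b) (P[a, 1] - P[b, 1])^2 + (P[a, 2] - P[b, 2])^2
  if (n == 2L) return(sqrt(d2(1L, 2L)))
  tri2 <- function(i, j, k) {
    abs((P[j, 1] - P[i, 1]) * (P[k, 2] - P[i, 2]) -
        (P[j, 2] - P[i, 2]) * (P[k, 1] - P[i, 1]))
  }
  nxt <- function(i) if (i == n) 1L else i + 1L
  best <- 0
  k <- 2L
  for (i in seq_len(n)) {
    j <- nxt(i)
    while (tri2(i, j, nxt(k)) > tri2(i, j, k)) k <- nxt(k)
    best <- max(best, d2(i, k), d2(j, k))
  }
  sqrt(best)
}

#' Shape features of a binary plant mask
#'
#' Computes the seven silhouette features used in image-based ryegrass
#' phenotyping, all in pixel units, under an exact pixel-corner convention:
#' \describe{
#'   \item{area}{foreground pixel count (projected plant area).}
#'   \item{caliper_length}{longest dimension of the silhouette = maximum
#'     distance between any two convex-hull vertices (rotating calipers).}
#'   \item{compactness}{`area / convex_hull_area`, in (0, 1]; 1 exactly for
#'     pixel sets that are convex under the corner convention (e.g. filled
#'     rectangles).}
#'   \item{convex_hull_area}{polygon area of the convex hull of the four
#'     unit-square corner points of every foreground pixel.}
#'   \item{convex_hull_circumference}{perimeter of that hull polygon.}
#'   \item{width, height}{horizontal / vertical extent of the foreground
#'     bounding box, in whole pixels, axis-aligned in the camera frame.}
#' }
#'
#' @param mask logical matrix (`TRUE` = plant), e.g. from [segment_plant()].
#' @return a one-row `data.frame` with the seven features.
#' @examples
#' m <- matrix(FALSE, 120, 120); m[11:110, 11:110] <- TRUE
#' extract_features(m)  # area 10000, compactness 1, caliper 100*sqrt(2)
#' @export
extract_features <- function(mask) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  if (!is.logical(mask)) mask <- mask > 0.5
  if (isTRUE(attr(mask, "empty")) || !any(mask)) {
    stop("cannot extract shape features from an empty mask", call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  pts <- pixel_corners(mask)
  H <- hull_vertices(pts)
  hull_area <- if (nrow(H) >= 3L) polygon_area(H) else 0
  data.frame(
    area = nrow(idx),
    caliper_length = calipers_diameter(H),
    compactness = nrow(idx) / hull_area,
    convex_hull_area = hull_area,
    convex_hull_circumference = polygon_perimeter(H),
    width = diff(range(idx[, 2])) + 1L,
    height = diff(range(idx[, 1])) + 1L
  )
}
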