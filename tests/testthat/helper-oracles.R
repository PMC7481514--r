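# Independent brute-force oracles for the silhouette geometry, plus small
# fixture generators. These deliberately share no code with the package's
# hull/caliper implementation.

options(ryeNUE.quiet = TRUE)

# corner points of a mask, duplicated per pixel is fine for the oracles
oracle_corners <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  unique(cbind(x = c(j - 1, j, j - 1, j), y = c(i - 1, i - 1, i, i)))
}

# O(n^2) caliper: maximum pairwise distance over all corner points
oracle_caliper <- function(mask) {
  p <- oracle_corners(mask)
  if (nrow(p) == 1L) return(0)
  dm <- as.matrix(stats::dist(p))
  max(dm)
}

# gift-wrapping (Jarvis march) convex hull, counter-clockwise
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  # leftmost (lowest y as tie-break)
  ord <- order(pts[, 1], pts[, 2])
  start <- ord[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == cur || k == cand) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_cand <- sum((pts[cand, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < -1e-12 || (abs(cr) <= 1e-12 && d_k > d_cand)) cand <- k
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  pts[hull, , drop = FALSE]
}

oracle_hull_area <- function(mask) {
  P <- oracle_hull(oracle_corners(mask))
  n <- nrow(P)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])) / 2
}

oracle_hull_perimeter <- function(mask) {
  P <- oracle_hull(oracle_corners(mask))
  n <- nrow(P)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((P[j, 1] - P[, 1])^2 + (P[j, 2] - P[, 2])^2))
}

# random connected-ish blob mask of roughly n_px pixels on an sz x sz grid
random_mask <- function(sz = 30, n_px = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, sz, sz)
  r <- sz %/% 2; c <- sz %/% 2
  m[r, c] <- TRUE
  for (k in seq_len(n_px - 1L)) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample.int(nrow(idx), 1L), ]
    dr <- sample(c(-1L, 0L, 1L), 1L); dc <- sample(c(-1L, 0L, 1L), 1L)
    nr <- min(max(p[1] + dr, 1L), sz); nc <- min(max(p[2] + dc, 1L), sz)
    m[nr, nc] <- TRUE
  }
  m
}

# mask with a filled disk of radius r
disk_mask <- function(r, pad = 4L) {
  sz <- 2L * r + 2L * pad
  ctr <- sz / 2
  rr <- matrix(seq_len(sz), sz, sz)
  cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= r^2
}

# small synthetic trial used by several statistics tests
tiny_trial <- function(G = 8, R = 3, seed = 1, ...) {
  d <- generate_design(G, 2, R, G, seed = seed)
  tr <- growth_truth(d, seed = seed + 1, ...)
  traj <- simulate_growth(d, tr, seed = seed + 2)
  h <- simulate_harvests(traj, tr, seed = seed + 3)
  list(design = d, truth = tr, traj = traj, harvests = h)
}

add_impulse_noise <- function(img, frac = 0.01, seed = 1) {
  set.seed(seed)
  npx <- dim(img)[1] * dim(img)[2]
  n <- round(frac * npx)
  idx <- sample(npx, n)
  val <- sample(c(0, 1), n, replace = TRUE)
  for (ch in 1:3) { p <- img[, , ch]; p[idx] <- val; img[, , ch] <- p }
  img
}
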