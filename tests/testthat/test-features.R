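test_that("filled rectangle features match the corner-point convention exactly", {
  m <- matrix(FALSE, 120, 130)
  m[11:110, 21:120] <- TRUE          # 100 x 100 square
  f <- extract_features(m)
  expect_equal(f$area, 10000)
  expect_equal(f$convex_hull_area, 10000)
  expect_equal(f$compactness, 1)
  expect_equal(f$convex_hull_circumference, 400)
  expect_equal(f$caliper_length, 100 * sqrt(2))
  expect_equal(f$width, 100)
  expect_equal(f$height, 100)
})

test_that("a single pixel is a unit square", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  f <- extract_features(m)
  expect_equal(f$area, 1)
  expect_equal(f$convex_hull_area, 1)
  expect_equal(f$compactness, 1)
  expect_equal(f$caliper_length, sqrt(2))
  expect_equal(f$width, 1)
  expect_equal(f$height, 1)
})

test_that("caliper, hull area and perimeter match brute-force oracles on random masks", {
  for (s in 1:60) {
    m <- random_mask(sz = 24, n_px = 20 + (s %% 7) * 30, seed = s)
    f <- extract_features(m)
    expect_equal(f$caliper_length, oracle_caliper(m), tolerance = 1e-12)
    expect_equal(f$convex_hull_area, oracle_hull_area(m), tolerance = 1e-12)
    expect_equal(f$convex_hull_circumference, oracle_hull_perimeter(m), tolerance = 1e-12)
    expect_gt(f$compactness, 0)
    expect_lte(f$compactness, 1)
    expect_gte(f$caliper_length, max(f$width, f$height))
  }
})

test_that("adding pixels never shrinks area, hull, caliper, width or height", {
  m <- random_mask(sz = 28, n_px = 80, seed = 77)
  f1 <- extract_features(m)
  m2 <- m
  set.seed(78)
  off <- which(!m2)
  m2[sample(off, 25)] <- TRUE
  f2 <- extract_features(m2)
  for (v in c("area", "convex_hull_area", "caliper_length", "width", "height")) {
    expect_gte(f2[[v]], f1[[v]])
  }
})

test_that("features are invariant under translation within the frame", {
  m <- matrix(FALSE, 40, 40)
  m[5:18, 6:14] <- TRUE
  m[10:25, 12:20] <- TRUE
  f1 <- extract_features(m)
  m2 <- matrix(FALSE, 40, 40)
  m2[(5:18) + 9, (6:14) + 13] <- TRUE
  m2[(10:25) + 9, (12:20) + 13] <- TRUE
  f2 <- extract_features(m2)
  expect_equal(f1, f2)
})

test_that("disk masks behave like disks under rotation of the calipers", {
  # corner-point hulls circumscribe the digital disk, inflating hull area by
  # roughly (1 + 0.55/r)^2, so the compactness bound needs a radius where
  # that bias is below 2%
  for (r in c(30, 45, 60, 80)) {
    f <- extract_features(disk_mask(r))
    expect_gte(f$caliper_length, 2 * r)
    expect_lte(f$caliper_length, 2 * r + 3)
    expect_gte(f$compactness, 1 / (1 + 0.55 / r)^2 - 0.005)
    if (r >= 60) expect_gte(f$compactness, 0.98)
  }
})

test_that("empty masks raise an explicit error", {
  expect_error(extract_features(matrix(FALSE, 5, 5)), "empty")
})

test_that("segmentation recovers noiseless renders at IoU >= 0.99", {
  for (s in 1:5) {
    rp <- render_plant(plant_spec(seed = s), "side-0", image_size = 192, seed = s)
    mk <- segment_plant(rp$image)
    iou <- sum(mk & rp$mask) / sum(mk | rp$mask)
    expect_gte(iou, 0.99)
  }
})

test_that("segmentation tolerates 1% impulse noise at IoU >= 0.95", {
  for (s in 1:10) {
    rp <- render_plant(plant_spec(seed = s), "side-0", image_size = 192, seed = s)
    img <- add_impulse_noise(rp$image, 0.01, seed = s + 100)
    mk <- segment_plant(img)
    iou <- sum(mk & rp$mask) / sum(mk | rp$mask)
    expect_gte(iou, 0.95)
  }
})

test_that("plant-free images yield an empty-flagged mask, not an error", {
  white <- array(1, dim = c(60, 60, 3))
  mk <- segment_plant(white)
  expect_true(is_empty_mask(mk))
  expect_false(any(mk))
})

test_that("a fixed threshold and the ROI exclusion zone are honoured", {
  rp <- render_plant(plant_spec(seed = 4), "side-0", image_size = 192, seed = 4)
  mk_fix <- segment_plant(rp$image, segment_params(threshold = 40))
  expect_gte(sum(mk_fix & rp$mask) / sum(mk_fix | rp$mask), 0.99)
  rows <- range(which(rowSums(rp$mask) > 0))
  mk_roi <- segment_plant(rp$image,
                          segment_params(roi_exclude = c(rows[1], rows[2], 1, 192)))
  expect_true(is_empty_mask(mk_roi))
})
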