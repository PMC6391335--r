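# Candidate generation, weighted voting and RGB/HSV refinement.

scene_one_disk <- function(ctr = c(100, 120), rad = 50, size = c(200, 240),
                           seed = 1, ...) {
  render_scene(scene_spec(
    image_size = size, pupil_center = ctr,
    pupil_radius = rad, seed = seed, ...
  ))
}

test_that("the Hough detector pinpoints a clean disk to within a pixel", {
  sc <- scene_one_disk()
  cands <- hough_circle_candidates(sc$image, radius_range = c(30, 70))
  expect_gt(nrow(cands), 0)
  expect_lte(abs(cands$row[1] - 100), 1)
  expect_lte(abs(cands$col[1] - 120), 1)
  expect_lte(abs(cands$radius[1] - 50), 2)
  # independent oracle: exhaustive ring-contrast search on a window
  gray <- alcv:::to_gray(sc$image)
  best <- oracle_best_circle(gray,
    radii = c(46, 48, 50, 52, 54),
    rows = 90:110, cols = 110:130
  )
  expect_lte(abs(cands$row[1] - best["row"]), 2)
  expect_lte(abs(cands$col[1] - best["col"]), 2)
  expect_lte(abs(cands$radius[1] - best["radius"]), 4)
})

test_that("a blank image yields no candidates, not an error", {
  img <- rgb_image(array(128, dim = c(100, 100, 3)))
  expect_equal(nrow(hough_circle_candidates(img)), 0)
})

test_that("radius range restricts which disk is found", {
  # two disks: radius 30 at (60, 60), radius 60 elsewhere; search 50-70
  arr <- array(40, dim = c(220, 260, 3))
  img0 <- rgb_image(arr)
  d1 <- alcv:::disk_mask(c(220, 260), c(60, 60), 30)
  d2 <- alcv:::disk_mask(c(220, 260), c(140, 170), 60)
  for (ch in 1:3) {
    m <- arr[, , ch]
    m[d1] <- c(200, 70, 60)[ch]
    m[d2] <- c(200, 70, 60)[ch]
    arr[, , ch] <- m
  }
  img <- rgb_image(arr)
  cands <- hough_circle_candidates(img, radius_range = c(50, 70))
  expect_gt(nrow(cands), 0)
  expect_true(all(abs(cands$radius - 60) <= 10))
  expect_lte(sqrt(sum((c(cands$row[1], cands$col[1]) - c(140, 170))^2)), 2)
})

test_that("detection refuses undersized images and bad radius ranges", {
  img <- rgb_image(array(0, dim = c(32, 32, 3)))
  expect_error(hough_circle_candidates(img), "64 x 64")
  big <- rgb_image(array(0, dim = c(100, 100, 3)))
  expect_error(hough_circle_candidates(big, radius_range = c(40, 60)), "radius")
})

test_that("color voting separates the red reflex from a gray distractor", {
  # equally sized disks with matched gray-level contrast against the
  # background (mean reflex gray is 110): only the color vote separates them
  arr <- array(40, dim = c(220, 260, 3))
  red <- alcv:::disk_mask(c(220, 260), c(60, 70), 45)
  gray <- alcv:::disk_mask(c(220, 260), c(150, 180), 45)
  for (ch in 1:3) {
    m <- arr[, , ch]
    m[red] <- c(200, 70, 60)[ch]
    m[gray] <- 110
    arr[, , ch] <- m
  }
  img <- rgb_image(arr)
  cands <- hough_circle_candidates(img, radius_range = c(35, 55))
  scored <- score_candidates(img, cands)
  expect_lte(sqrt(sum((c(scored$row[1], scored$col[1]) - c(60, 70))^2)), 2)
  gray_idx <- which(abs(scored$col - 180) < 3)[1]
  expect_gt(scored$color_score[1], scored$color_score[gray_idx])
})

test_that("scoring handles singletons and breaks ties deterministically", {
  sc <- scene_one_disk()
  expect_error(score_candidates(sc$image, NULL), "empty")
  one <- data.frame(row = 100, col = 120, radius = 50, response = 1)
  s1 <- score_candidates(sc$image, one)
  expect_equal(nrow(s1), 1)
  two <- rbind(
    data.frame(row = 101, col = 120, radius = 50, response = 1),
    data.frame(row = 100, col = 120, radius = 50, response = 1)
  )
  s2 <- score_candidates(sc$image, two)
  # equal totals sort by (row, col, radius)
  if (abs(s2$total_score[1] - s2$total_score[2]) < 1e-12) {
    expect_lt(s2$row[1], s2$row[2])
  }
})

test_that("contrast score never decreases with interior/exterior contrast", {
  scores <- vapply(c(90, 130, 170, 210), function(level) {
    sc <- render_scene(scene_spec(
      image_size = c(160, 160),
      pupil_reflex_color = c(level, 40, 40),
      background_color = c(40, 40, 40), seed = 1
    ))
    cand <- data.frame(row = 80, col = 80, radius = 45, response = 1)
    distract <- data.frame(row = 30, col = 30, radius = 12, response = 0.5)
    s <- score_candidates(sc$image, rbind(cand, distract))
    s$contrast_score[s$radius == 45]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("refinement recovers a clean disk almost exactly", {
  sc <- scene_one_disk()
  p <- detect_pupil(sc$image, radius_range = c(30, 70))
  jac <- sum(p$mask & sc$truth$pupil_mask) / sum(p$mask | sc$truth$pupil_mask)
  expect_gte(jac, 0.95)
  expect_false(p$fallback)
  # mask stays inside the dilated candidate disk and is one component
  dil <- alcv:::disk_mask(dim(sc$image)[1:2],
    c(p$candidate$row, p$candidate$col), 1.2 * p$candidate$radius)
  expect_true(all(dil[p$mask]))
  lab <- alcv:::label_components(p$mask)
  expect_equal(max(lab), 1)
  expect_gt(p$area, 0)
})

test_that("an eyelid-like bite is excluded from the refined mask", {
  sc <- scene_one_disk()
  arr <- unclass(sc$image)
  # darken a bite: everything above a chord through the upper pupil
  bite <- alcv:::disk_mask(c(200, 240), c(100, 120), 50) &
    row(matrix(0, 200, 240)) < 65
  for (ch in 1:3) {
    m <- arr[, , ch]
    m[bite] <- 30
    arr[, , ch] <- m
  }
  img <- rgb_image(arr)
  cand <- data.frame(row = 100, col = 120, radius = 50, response = 1)
  p <- refine_pupil_mask(img, cand)
  truth <- alcv:::disk_mask(c(200, 240), c(100, 120), 50) & !bite
  jac <- sum(p$mask & truth) / sum(p$mask | truth)
  expect_gte(jac, 0.90)
  expect_lt(sum(p$mask & bite), 0.05 * sum(bite))
})

test_that("refinement collapse falls back to the raw disk and flags it", {
  arr <- array(10, dim = c(160, 160, 3)) # all dark: nothing passes thresholds
  img <- rgb_image(arr)
  cand <- data.frame(row = 80, col = 80, radius = 40, response = 1)
  p <- refine_pupil_mask(img, cand)
  expect_true(p$fallback)
  expect_equal(
    sum(p$mask),
    sum(alcv:::disk_mask(c(160, 160), c(80, 80), 40))
  )
})
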