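# Skeletonization, branch decomposition, widths, lengths, tortuosity.

mask_vmap <- function(mask, pupil = NULL) {
  if (is.null(pupil)) pupil <- matrix(TRUE, nrow(mask), ncol(mask))
  structure(
    list(
      mask = mask, pupil = list(mask = pupil),
      params_used = list(low = NA, high = NA, min_object_px = 0)
    ),
    class = "vessel_map"
  )
}

test_that("a filled rectangle skeletonizes to one branch with two endpoints", {
  m <- matrix(FALSE, 60, 60)
  m[30:32, 10:49] <- TRUE
  bs <- skeletonize_map(mask_vmap(m))
  expect_equal(length(bs$branches), 1)
  expect_equal(nrow(bs$endpoints), 2)
  expect_equal(nrow(bs$junctions), 0)
  bs <- measure_branches(bs, mask_vmap(m))
  expect_gte(bs$branches[[1]]$length, 38)
  expect_lte(bs$branches[[1]]$length, 42)
})

test_that("a Y of three arms gives three branches around one junction", {
  ctr <- c(80, 80)
  tree <- lapply(
    list(c(-30, 0), c(22, -22), c(22, 22)),
    function(a) branch_spec(rbind(ctr, ctr + a), width = 3)
  )
  sc <- render_scene(scene_spec(vessel_tree = tree, seed = 1))
  vm <- gt_vessel_map(sc)
  bs <- skeletonize_map(vm)
  expect_equal(length(bs$branches), 3)
  expect_equal(nrow(bs$endpoints), 3)
  expect_gte(nrow(bs$junctions), 1)
  # partition: every skeleton pixel is accounted to exactly one branch
  expect_equal(sum(bs$owned_counts), sum(bs$skeleton))
})

test_that("an empty mask yields an empty branch set, not an error", {
  bs <- skeletonize_map(mask_vmap(matrix(FALSE, 20, 20)))
  expect_equal(length(bs$branches), 0)
  f <- compute_features(bs, mask_vmap(matrix(FALSE, 20, 20)))
  expect_equal(f$n_branches, 0)
  expect_equal(f$density, 0)
})

test_that("distance-transform widths track rendered stroke width", {
  w5 <- matrix(FALSE, 60, 60)
  w5[28:32, 10:49] <- TRUE
  b5 <- measure_branches(skeletonize_map(mask_vmap(w5)), mask_vmap(w5))
  expect_gte(b5$branches[[1]]$mean_width, 4)
  expect_lte(b5$branches[[1]]$mean_width, 6)
  w9 <- matrix(FALSE, 60, 60)
  w9[24:32, 10:49] <- TRUE
  b9 <- measure_branches(skeletonize_map(mask_vmap(w9)), mask_vmap(w9))
  expect_gt(b9$branches[[1]]$mean_width, b5$branches[[1]]$mean_width)
  line <- matrix(FALSE, 30, 60)
  line[15, 10:49] <- TRUE
  b1 <- measure_branches(skeletonize_map(mask_vmap(line)), mask_vmap(line))
  expect_true(all(b1$branches[[1]]$width_profile >= 1 &
    b1$branches[[1]]$width_profile <= 2))
})

test_that("box counting: straight lines ~1, filled blocks ~2, sentinels", {
  line <- cbind(1, 1:64)
  expect_equal(as.numeric(box_counting_dimension(line)), 1, tolerance = 0.05)
  diag_line <- cbind(1:64, 1:64)
  expect_equal(as.numeric(box_counting_dimension(diag_line)), 1,
    tolerance = 0.05
  )
  block <- as.matrix(expand.grid(1:64, 1:64))
  expect_equal(as.numeric(box_counting_dimension(block)), 2, tolerance = 0.05)
  tiny <- cbind(1:5, 1) # < 8 pixels
  expect_equal(as.numeric(box_counting_dimension(tiny)), 1)
  expect_true(attr(box_counting_dimension(tiny), "degenerate"))
  clump <- as.matrix(expand.grid(1:3, 1:3)) # spans < 8 px
  expect_true(attr(box_counting_dimension(clump), "degenerate"))
})

test_that("box counting exceeds the straight-line value on its chord", {
  b <- make_branch_sinusoid(c(40, 10), c(40, 74),
    amplitude = 12, cycles = 6,
    width = 1
  )
  wavy <- unique(round(b$path))
  straight <- cbind(40, 10:74)
  expect_gt(
    as.numeric(box_counting_dimension(wavy)),
    as.numeric(box_counting_dimension(straight))
  )
})

test_that("box counting is translation and 90-degree rotation invariant", {
  set.seed(9)
  b <- make_branch_sinusoid(c(30, 10), c(50, 90), amplitude = 7, cycles = 4)
  px <- unique(round(b$path))
  base <- as.numeric(box_counting_dimension(px))
  shifted <- px + matrix(rep(c(13, 29), each = nrow(px)), ncol = 2)
  expect_equal(as.numeric(box_counting_dimension(shifted)), base,
    tolerance = 1e-12
  )
  rot <- cbind(px[, 2], -px[, 1]) # 90 degrees
  expect_equal(as.numeric(box_counting_dimension(rot)), base,
    tolerance = 0.02
  )
})

test_that("tortuosity is non-decreasing in sinusoid amplitude", {
  fds <- vapply(c(0, 2, 4, 8, 12), function(A) {
    b <- make_branch_sinusoid(c(80, 48), c(80, 112),
      amplitude = A, cycles = 6,
      width = 2
    )
    sc <- render_scene(scene_spec(
      image_size = c(160, 160), pupil_radius = 70,
      vessel_tree = list(b), seed = 1
    ))
    vm <- gt_vessel_map(sc)
    bs <- measure_branches(skeletonize_map(vm), vm)
    max(vapply(bs$branches, `[[`, numeric(1), "tortuosity_fd"))
  }, numeric(1))
  expect_true(all(diff(fds) >= 0))
  expect_true(all(fds >= 1 & fds <= 2))
})

test_that("feature extrema, density bounds and aggregation are correct", {
  spec <- make_test_tree(2)
  sc <- render_scene(spec)
  vm <- gt_vessel_map(sc)
  bs <- measure_branches(skeletonize_map(vm), vm)
  f <- compute_features(bs, vm)
  expect_gte(f$branch_length_max, f$branch_length_min)
  expect_gte(f$branch_width_max, f$branch_width_min)
  expect_gte(f$tortuosity_max, f$tortuosity_min)
  expect_true(f$density >= 0 && f$density <= 100)
  # pathological: vessel mask equals pupil mask
  full <- mask_vmap(matrix(TRUE, 30, 30))
  ff <- compute_features(skeletonize_map(full) |> measure_branches(full), full)
  expect_equal(ff$density, 100)
  expect_error(
    compute_features(bs, mask_vmap(sc$truth$vessel_mask,
      pupil = matrix(FALSE, 160, 160)
    )),
    "pupil"
  )
  # aggregation is a plain field-wise mean
  expect_equal(aggregate_session(list(f)), f)
  f2 <- f
  f2$density <- f$density + 2
  f2$branch_length_max <- 60
  f$branch_length_max <- 30
  agg <- aggregate_session(list(f, f2))
  expect_equal(agg$density, f$density + 1)
  expect_equal(agg$branch_length_max, 45)
  expect_error(aggregate_session(list()), "empty")
})

test_that("morphometry recovers synthetic tree parameters", {
  # scaled-down version of the acceptance sweep: 6 seeded trees
  for (seed in 1:6) {
    spec <- make_test_tree(seed)
    sc <- render_scene(spec)
    vm <- gt_vessel_map(sc)
    bs <- measure_branches(skeletonize_map(vm), vm)
    f <- compute_features(bs, vm)
    expect_equal(f$n_branches, length(spec$vessel_tree))
    lens_t <- sort(vapply(spec$vessel_tree, `[[`, numeric(1), "length"))
    lens_m <- sort(vapply(bs$branches, `[[`, numeric(1), "length"))
    expect_true(all(abs(lens_m - lens_t) <= 0.05 * lens_t + 2))
    wids_t <- sort(vapply(
      spec$vessel_tree,
      function(b) mean(b$width), numeric(1)
    ))
    wids_m <- sort(vapply(bs$branches, `[[`, numeric(1), "mean_width"))
    expect_true(all(abs(wids_m - wids_t) <= 1))
    expect_lte(abs(f$density - sc$truth$density), 1)
    expect_equal(sum(bs$owned_counts), sum(bs$skeleton))
  }
})
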