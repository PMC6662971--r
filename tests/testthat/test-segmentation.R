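test_that("median projection removes transients covering < 50% of frames", {
  const <- matrix(50, 20, 30)
  expect_equal(median_projection(rep(list(const), 5))$values, const)
  # one pixel with temporal values {10, 200, 12} -> 12
  fr <- rep(list(const), 3)
  fr[[1]][3, 4] <- 10; fr[[2]][3, 4] <- 200; fr[[3]][3, 4] <- 12
  expect_equal(median_projection(fr)$values[3, 4], 12)
  # bright disk sweeping over a constant background, < 50% occupancy/pixel
  n <- 11
  frames <- lapply(seq_len(n), function(f) {
    m <- const
    cx <- 3 * f  # disk centre moves 3 px/frame; radius 4 -> <= 3 hits/pixel
    px <- as.matrix(expand.grid(y = 1:20, x = 1:30))
    hit <- (px[, "x"] - cx)^2 + (px[, "y"] - 10)^2 <= 16
    m[px[hit, , drop = FALSE]] <- 250
    m
  })
  mp <- median_projection(frames)
  expect_equal(mp$values, const)
  expect_equal(mp$n_frames_used, n)
  # per-pixel sort oracle on random small stacks, odd and even counts
  set.seed(5)
  for (n in c(4, 7)) {
    fr <- lapply(seq_len(n), function(i) matrix(runif(24, 0, 255), 4, 6))
    oracle <- apply(simplify2array(fr), c(1, 2),
                    function(v) sort(v)[(n + 1) %/% 2])
    expect_equal(median_projection(fr)$values, oracle)
  }
  expect_error(median_projection(list()), "at least one")
})

test_that("background subtraction is an absolute difference", {
  bg <- median_projection(list(matrix(100, 5, 5)))
  expect_equal(subtract_background(matrix(100, 5, 5), bg), matrix(0, 5, 5))
  expect_equal(subtract_background(matrix(110, 5, 5), bg), matrix(10, 5, 5))
  expect_equal(subtract_background(matrix(60, 5, 5), bg), matrix(40, 5, 5))
  expect_error(subtract_background(matrix(0, 4, 5), bg), "dimensions")
})

test_that("intermodes threshold: two-delta, Gaussian modes, unimodal error", {
  h <- integer(256); h[11] <- 40; h[21] <- 60  # spikes at levels 10 and 20
  expect_identical(intermodes_threshold(h), 15L)
  # two well-separated Gaussian modes at 50 and 200, sigma 10, equal mass
  set.seed(9)
  v <- c(rnorm(20000, 50, 10), rnorm(20000, 200, 10))
  hist2 <- gray_histogram(matrix(v, ncol = 1))
  thr <- intermodes_threshold(hist2)
  expect_lte(abs(thr - 125), 2)
  expect_error(intermodes_threshold(rep(10L, 256L)), "not bimodal")
  expect_error(intermodes_threshold(integer(256)), "empty")
})

test_that("segment_frame finds size-gated blobs at the right centroids", {
  set.seed(2)
  diff <- matrix(abs(rnorm(200 * 150, 0, 1.5)), 150, 200)
  px <- rect_pixels(60, 89, 40, 59)  # 30 x 20 blob = 600 px
  diff[px[, c(2, 1)]] <- 120
  dets <- segment_frame(diff, median_radius = 2, min_area = 100,
                        max_area = 10000, frame_index = 7L)
  expect_length(dets, 1L)
  expect_equal(dets[[1]]$frame, 7L)
  expect_lt(abs(dets[[1]]$centroid[["x"]] - 74.5), 1)
  expect_lt(abs(dets[[1]]$centroid[["y"]] - 49.5), 1)
  expect_equal(dets[[1]]$area, nrow(dets[[1]]$pixels))
  # five 4-px specks survive the threshold but not the size gate
  for (x in seq(10, 50, by = 10)) diff[cbind(100:101, c(x, x + 1))] <- 120
  dets2 <- segment_frame(diff, median_radius = 0, min_area = 100,
                         max_area = 10000)
  expect_length(dets2, 1L)
  # two non-touching blobs -> two detections
  diff3 <- matrix(0, 100, 100)
  diff3[rect_pixels(10, 29, 10, 19)[, c(2, 1)]] <- 150
  diff3[rect_pixels(60, 79, 60, 69)[, c(2, 1)]] <- 150
  expect_length(segment_frame(diff3, median_radius = 1, min_area = 50,
                              max_area = 1000), 2L)
  expect_error(segment_frame(diff3, min_area = 10, max_area = 5), "min_area")
})

test_that("component labelling matches a flood-fill brute force", {
  set.seed(13)
  for (i in 1:25) {
    mask <- matrix(runif(64) < 0.4, 8, 8)
    lab <- label_components(mask)
    oracle <- flood_fill_labels(mask)
    expect_equal(max(lab), max(oracle))
    # same partition: labels agree up to renaming
    if (max(lab) > 0) {
      for (l in seq_len(max(lab)))
        expect_length(unique(oracle[lab == l]), 1L)
    }
    expect_equal(lab > 0, mask)
  }
})

test_that("binary median filter is idempotent on filtered convex blobs", {
  # disk: one pass reaches the fixed point
  mask <- matrix(FALSE, 60, 60)
  px <- as.matrix(expand.grid(x = 1:60, y = 1:60))
  mask[px[(px[, 1] - 30)^2 + (px[, 2] - 30)^2 <= 15^2, c(2, 1)]] <- TRUE
  once <- median_filter_mask(mask, 2)
  expect_equal(median_filter_mask(once, 2), once)
  # sharp rectangle corners erode for a few passes but reach a fixed
  # point (strict-majority filtering rounds corners, then stabilises)
  m <- matrix(FALSE, 40, 40)
  m[rect_pixels(8, 30, 10, 25)[, c(2, 1)]] <- TRUE
  prev <- median_filter_mask(m, 2)
  for (i in 1:10) {
    nxt <- median_filter_mask(prev, 2)
    if (identical(nxt, prev)) break
    prev <- nxt
  }
  expect_lt(i, 10)
  # radius 0 is the identity
  expect_identical(median_filter_mask(mask, 0), mask)
})

test_that("detections conserve the threshold and size-gate invariants", {
  set.seed(21)
  diff <- matrix(abs(rnorm(120 * 90, 0, 2)), 90, 120)
  diff[rect_pixels(20, 49, 30, 49)[, c(2, 1)]] <- 100
  diff[rect_pixels(70, 110, 10, 24)[, c(2, 1)]] <- 100
  thr <- intermodes_threshold(gray_histogram(diff))
  filtered <- median_filter_mask(diff > thr, 2)
  dets <- segment_frame(diff, median_radius = 2, min_area = 100,
                        max_area = 10000)
  for (d in dets) {
    expect_true(all(d$area >= 100, d$area <= 10000))
    expect_true(all(filtered[d$pixels[, c(2, 1)]]))
    # centroid inside the pixel bounding box
    expect_true(d$centroid[["x"]] >= min(d$pixels[, 1]) &&
                d$centroid[["x"]] <= max(d$pixels[, 1]))
    expect_true(d$centroid[["y"]] >= min(d$pixels[, 2]) &&
                d$centroid[["y"]] <= max(d$pixels[, 2]))
  }
})
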