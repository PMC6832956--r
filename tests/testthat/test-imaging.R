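test_that("8-bit conversion rescales range endpoints and is idempotent", {
  img16 <- matrix(c(0L, 65535L, 0L, 65535L), 2, 2)
  out <- to_grayscale8(img16)
  expect_equal(sort(unique(as.vector(out))), c(0L, 255L))
  full <- matrix(as.integer(seq(0, 255, length.out = 64)), 8, 8)
  expect_equal(to_grayscale8(full), full)
  expect_true(all(to_grayscale8(matrix(7, 4, 4)) == 0L))
})

test_that("8-bit conversion of a linear ramp matches the direct rescale", {
  ramp <- matrix(0:1023, 32, 32)
  out <- to_grayscale8(ramp)
  direct <- round((0:1023) / 1023 * 255)
  expect_true(all(abs(as.vector(out) - direct) <= 1))
  expect_true(all(diff(as.vector(out)) >= 0))
})

test_that("RGB input is reduced by luminance weighting before rescale", {
  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 1   # pure red
  rgb[1, 1, ] <- 0  # one black pixel to span the range
  out <- to_grayscale8(rgb)
  expect_equal(out[1, 1], 0L)
  expect_equal(out[2, 2], 255L)  # max after rescale
})

test_that("two well-separated populations threshold between them", {
  img <- matrix(c(rep(50L, 128), rep(200L, 128)), 16, 16)
  th <- histogram_threshold(img)
  expect_false(th$degenerate)
  expect_true(th$threshold >= 50 && th$threshold < 200)
})

test_that("threshold equals the exhaustive between-class-variance search", {
  set.seed(101)
  images <- list(
    matrix(as.integer(pmin(pmax(round(c(rnorm(300, 60, 12),
                                        rnorm(724, 190, 20))), 0), 255)),
           32, 32),
    to_grayscale8(generate_fov_image(
      fov_design(n_particles = 4, min_separation = 40, noise_sd = 0.02,
                 seed = 8))$fov$image),
    matrix(as.integer(sample(0:255, 900, replace = TRUE)), 30, 30),
    matrix(as.integer(sample(c(10:20, 240:250), 400, replace = TRUE)),
           20, 20))
  for (img in images) {
    expect_equal(histogram_threshold(img)$threshold, oracle_otsu(img))
  }
})

test_that("a constant image is a degenerate threshold with empty foreground", {
  img <- matrix(42L, 8, 8)
  th <- histogram_threshold(img)
  expect_true(th$degenerate)
  expect_equal(sum(foreground_mask(img, th)), 0)
})

test_that("size filtering keeps exactly the in-range components", {
  img <- matrix(FALSE, 120, 120)
  img[2:3, 2:4] <- TRUE                    # area 6
  img[20:29, 20:31] <- TRUE                # area 120
  img[50:119, 50:119] <- TRUE              # area 4900
  out <- remove_particles_by_size(img, 50, 2000)
  labs <- oracle_label(out)
  expect_equal(max(labs), 1)
  expect_equal(sum(out), 120)
  expect_equal(remove_particles_by_size(img, 0, Inf), img)
})

test_that("size filtering agrees with a brute-force labeling oracle", {
  set.seed(77)
  for (rep in 1:3) {
    img <- matrix(runif(40 * 40) < 0.35, 40, 40)
    out <- remove_particles_by_size(img, 4, 30)
    labs <- oracle_label(img)
    areas <- tabulate(labs[labs > 0])
    keep <- which(areas >= 4 & areas <= 30)
    oracle <- matrix(labs %in% keep, 40, 40)
    expect_equal(out, oracle)
  }
})

test_that("hole filling closes an annulus into a solid disk", {
  img <- matrix(FALSE, 41, 41)
  xy <- expand.grid(r = 1:41, c = 1:41)
  d2 <- (xy$r - 21)^2 + (xy$c - 21)^2
  img[d2 <= 10^2 & d2 > 3^2] <- TRUE       # disk with a 3-px hole
  out <- fill_holes_and_dilate(img, fill_iterations = 3,
                               dilate_iterations = 0)
  expect_true(out[21, 21])                  # hole center now foreground
  expect_true(all(out[matrix(c(xy$r, xy$c), ncol = 2)[d2 <= 10^2, ]]))
  expect_true(all(out[img]))                # monotone growth
})

test_that("zero morphology iterations is the identity", {
  set.seed(5)
  img <- matrix(runif(100) < 0.3, 10, 10)
  expect_equal(fill_holes_and_dilate(img, 0, 0), img)
})

test_that("dilation equals the iterated shift-union oracle", {
  set.seed(13)
  for (iters in c(1, 2, 4)) {
    img <- matrix(runif(30 * 25) < 0.2, 30, 25)
    oracle <- img
    for (i in seq_len(iters)) oracle <- oracle_dilate3x3(oracle)
    expect_equal(fill_holes_and_dilate(img, 0, iters), oracle)
  }
})

test_that("blob analysis recovers a centered disk and sorts by (y, x)", {
  img <- matrix(FALSE, 128, 64)
  xy <- expand.grid(r = 1:128, c = 1:64)
  keep <- (xy$r - 1 - 64)^2 + (xy$c - 1 - 32)^2 <= 10^2
  img[matrix(c(xy$r, xy$c), ncol = 2)[keep, ]] <- TRUE
  blobs <- blob_analysis(img)
  expect_equal(nrow(blobs), 1)
  expect_lt(abs(blobs$y - 64), 0.5)
  expect_lt(abs(blobs$x - 32), 0.5)
  expect_equal(nrow(blob_analysis(matrix(FALSE, 10, 10))), 0)
})

test_that("blob centroids match generator ground truth within one pixel", {
  g <- generate_fov_image(fov_design(n_particles = 6, min_separation = 50,
                                     image_shape = c(320, 320), seed = 17))
  gray8 <- to_grayscale8(g$fov$image)
  mask <- foreground_mask(gray8, histogram_threshold(gray8))
  blobs <- blob_analysis(mask)
  expect_equal(nrow(blobs), 6)
  truth <- g$truth[order(g$truth$y, g$truth$x), ]
  expect_true(all(sqrt((blobs$x - truth$x)^2 +
                         (blobs$y - truth$y)^2) <= 1))
})

test_that("the localization pipeline finds exactly the in-range disks", {
  g <- generate_fov_image(fov_design(n_particles = 5, min_separation = 45,
                                     seed = 23))
  blobs <- localize_pollen(g$fov)
  expect_equal(nrow(blobs), 5)
  # speckles below the minimum area must not add detections
  img <- g$fov$image
  set.seed(42)
  for (i in 1:20) {
    r <- sample(5:250, 1); c <- sample(5:250, 1)
    img[r, c] <- 0.2
  }
  blobs2 <- localize_pollen(fov_image(img, 1.0))
  expect_equal(nrow(blobs2), 5)
  expect_equal(nrow(localize_pollen(fov_image(matrix(0.9, 64, 64), 1.0))),
               0)
})

test_that("pixel-to-stage mapping is affine and invertible", {
  blobs <- data.frame(x = c(0, 50), y = c(0, 50))
  id <- stage_transform()
  expect_equal(pixel_to_stage(blobs, id),
               data.frame(stage_x = c(0, 50), stage_y = c(0, 50)))
  tr <- stage_transform(diag(2) * 0.1, offset = c(100, 200))
  st <- pixel_to_stage(data.frame(x = 50, y = 50), tr)
  expect_equal(st$stage_x, 105.0)
  expect_equal(st$stage_y, 205.0)
  set.seed(31)
  for (rep in 1:10) {
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    tr <- stage_transform(A, offset = rnorm(2, 0, 100))
    px <- data.frame(x = runif(5, 0, 512), y = runif(5, 0, 512))
    st <- pixel_to_stage(px, tr, frame_index = c(2, 3), frame_pitch = 300)
    back <- stage_to_pixel(st, tr, frame_index = c(2, 3),
                           frame_pitch = 300)
    expect_true(max(abs(back$x - px$x), abs(back$y - px$y)) < 1e-9)
  }
  expect_error(stage_transform(matrix(c(1, 2, 2, 4), 2, 2)), "singular")
})

test_that("noise-free detection is exact over many seeded frames", {
  # well-separated disks: separation at least 4x the maximum radius
  errs <- numeric(0)
  for (seed in 1:25) {
    g <- generate_fov_image(fov_design(n_particles = 4,
                                       radius_range = c(8, 12),
                                       min_separation = 48,
                                       image_shape = c(256, 256),
                                       seed = seed))
    blobs <- localize_pollen(g$fov)
    expect_equal(nrow(blobs), nrow(g$truth))
    truth <- g$truth[order(g$truth$y, g$truth$x), ]
    errs <- c(errs, sqrt((blobs$x - truth$x)^2 + (blobs$y - truth$y)^2))
  }
  expect_true(all(errs <= 1))
})
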