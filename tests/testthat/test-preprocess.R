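test_that("hypha segmentation recovers the capsule area within 5%", {
  spec <- synthetic_spec(seed = 2)           # full-size default hypha
  sim <- generate_hypha_image(spec)
  mask <- estimate_hypha_mask(sim$image)
  expect_equal(mask$area_um2, sim$ground_truth$hypha_mask$area_um2,
               tolerance = 0.05)
  # single connected component
  expect_equal(max(EBImage::bwlabel(mask$mask)), 1)
})

test_that("segmentation fails cleanly on degenerate input", {
  zero <- image2d(matrix(0, 64, 64), 0.1)
  expect_error(estimate_hypha_mask(zero), "segmentation failure")
})

test_that("mask area is invariant under intensity scaling", {
  sim <- generate_hypha_image(mid_spec(seed = 3))
  m1 <- estimate_hypha_mask(sim$image)
  scaled <- image2d(sim$image$pixels * 7.3, sim$image$pixel_size_um)
  m2 <- estimate_hypha_mask(scaled)
  expect_identical(m1$mask, m2$mask)
})

test_that("background estimate is the outside-mask mean", {
  px <- matrix(10, 8, 8)
  mk <- matrix(FALSE, 8, 8); mk[3:6, 3:6] <- TRUE
  px[mk] <- 99
  img <- image2d(px, 1)
  expect_equal(estimate_background(img, hypha_mask(mk, 1)), 10)

  # equal numbers of 0 and 20 outside -> arithmetic mean 10
  px2 <- px
  out_idx <- which(!mk)
  px2[out_idx[seq(1, length(out_idx), 2)]] <- 0
  px2[out_idx[seq(2, length(out_idx), 2)]] <- 20
  expect_equal(estimate_background(image2d(px2, 1), hypha_mask(mk, 1)), 10)

  # no outside pixels -> error
  expect_error(estimate_background(img, hypha_mask(matrix(TRUE, 8, 8), 1)),
               "outside")
})

test_that("background estimate on synthetic noise matches the known level", {
  spec <- mid_spec(seed = 4, noise = "gaussian")
  sim <- generate_hypha_image(spec)
  gt_mask <- sim$ground_truth$hypha_mask
  b <- estimate_background(sim$image, gt_mask)
  n_out <- sum(!gt_mask$mask)
  # b = background_level +- 3 se (wall tails bleed just outside the true
  # capsule mask, so allow a small positive bias on top of the noise term)
  se <- spec$noise_sd / sqrt(n_out)
  expect_gt(b, spec$background_level - 3 * se)
  expect_lt(b, spec$background_level + 3 * se + 3e-3)
})

test_that("re-estimated subtraction reaches its fixed point on clean input", {
  px <- matrix(5, 16, 16)
  mk <- matrix(FALSE, 16, 16); mk[5:12, 5:12] <- TRUE
  px[mk] <- 50
  img <- image2d(px, 1)
  hm <- hypha_mask(mk, 1)
  one <- subtract_background(img, hm, 1)
  expect_true(all(one$pixels[!mk] == 0))
  expect_true(all(one$pixels[mk] == 45))
  more <- subtract_background(img, hm, 10)
  expect_equal(more$pixels, one$pixels)   # further iterations change nothing
  # identity at zero iterations
  expect_equal(subtract_background(img, hm, 0)$pixels, px)
})

test_that("subtraction output is bounded by input and by zero", {
  sim <- generate_hypha_image(mid_spec(seed = 5))
  mask <- estimate_hypha_mask(sim$image)
  for (mode in c("reestimate", "fixed")) {
    sub <- subtract_background(sim$image, mask, 7, mode = mode)
    expect_true(all(sub$pixels <= sim$image$pixels + 1e-12))
    expect_true(all(sub$pixels >= 0))
  }
})

test_that("re-estimated subtraction composes additively in iterations", {
  sim <- generate_hypha_image(mid_spec(seed = 6))
  mask <- estimate_hypha_mask(sim$image)
  a <- subtract_background(subtract_background(sim$image, mask, 3), mask, 4)
  b <- subtract_background(sim$image, mask, 7)
  expect_equal(a$pixels, b$pixels, tolerance = 1e-12)
})

test_that("fixed-mode subtraction removes n times the initial background", {
  sim <- generate_hypha_image(mid_spec(seed = 7))
  mask <- estimate_hypha_mask(sim$image)
  b0 <- estimate_background(sim$image, mask)
  sub <- subtract_background(sim$image, mask, 20, mode = "fixed")
  expect_equal(sub$pixels, pmax(sim$image$pixels - 20 * b0, 0),
               tolerance = 1e-12)
  # explicit background override gives the same result
  sub2 <- subtract_background(sim$image, mask, 20, background = b0)
  expect_equal(sub$pixels, sub2$pixels)
})

test_that("twenty subtractions suppress the wall below 5% of droplet peak", {
  spec <- synthetic_spec(seed = 8)           # wall at 10% of droplet peak
  sim <- generate_hypha_image(spec)
  mask <- estimate_hypha_mask(sim$image)
  wall <- sim$ground_truth$wall_mask
  for (mode in c("reestimate", "fixed")) {
    sub <- subtract_background(sim$image, mask, 20, mode = mode)
    expect_lt(mean(sub$pixels[wall]), 0.05 * spec$droplet_peak)
  }
})

test_that("crop_wall zeros outside and rejects over-erosion", {
  sim <- generate_hypha_image(mid_spec(seed = 9))
  mask <- estimate_hypha_mask(sim$image)
  crop0 <- crop_wall(sim$image, mask, 0)
  expect_true(all(crop0$pixels[!mask$mask] == 0))
  expect_equal(crop0$pixels[mask$mask], sim$image$pixels[mask$mask])
  expect_error(crop_wall(sim$image, mask, 10), "emptied")
  expect_error(crop_wall(sim$image, mask, -1), ">= 0")
})

test_that("auto subtraction count converges quickly on clean input", {
  # droplets only, background-free: the first subtraction removes nothing
  spec <- mid_spec(seed = 10, noise = "none", wall_peak = 1e-9,
                   cytoplasm_level = 0, background_level = 0)
  sim <- generate_hypha_image(spec)
  mask <- sim$ground_truth$hypha_mask
  res <- auto_subtraction_count(sim$image, mask, max_iter = 10)
  expect_s3_class(res, "subtraction_trace")
  expect_equal(res$n_iterations, 1L)
  expect_equal(res$trace$n_ld[2], res$trace$n_ld[1], tolerance = 0.05)
})

test_that("auto subtraction count stays within 20 on the control regime", {
  spec <- mid_spec(seed = 11)
  sim <- generate_hypha_image(spec)
  mask <- estimate_hypha_mask(sim$image)
  res <- auto_subtraction_count(sim$image, mask, max_iter = 40,
                                rel_tol = 0.05)
  expect_lte(res$n_iterations, 20L)
  # the count trace settles: late relative changes are small
  n <- res$trace$n_ld
  k <- length(n)
  expect_lt(abs(n[k] - n[k - 1]) / n[k - 1], 0.05)
})
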