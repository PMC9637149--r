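test_that("to_pow2_square crops or pads to the expected side", {
  img <- image2d(matrix(runif(64 * 64), 64), 0.1)
  expect_identical(to_pow2_square(img)$pixels, img$pixels)   # already 2^n

  odd <- image2d(matrix(1:9000 * 1.0, 100, 90), 0.1)
  crop <- to_pow2_square(odd, "crop_center")
  expect_equal(dim(crop), c(64L, 64L))
  expect_equal(crop$pixels, odd$pixels[19:82, 14:77])        # centred

  small <- image2d(matrix(2, 30, 30), 0.1)
  pad <- to_pow2_square(small, "pad_zero")
  expect_equal(dim(pad), c(32L, 32L))
  expect_equal(sum(pad$pixels), sum(small$pixels))           # content kept
  expect_equal(pad$pixels[1, 1], 0)
})

test_that("constant image has zero correlation, empty image errors", {
  flat <- image2d(matrix(3, 16, 16), 0.1)
  g <- autocorrelate(flat)$g
  expect_true(all(abs(g) < 1e-12))
  expect_error(autocorrelate(image2d(matrix(0, 16, 16), 0.1)), "mean")
  expect_error(autocorrelate(image2d(matrix(runif(15 * 16), 15, 16), 0.1)),
               "2\\^n")
})

test_that("single bright pixel gives G(0,0) = N^2 - 1 exactly", {
  for (n in c(8L, 16L)) {
    m <- matrix(0, n, n); m[3, 5] <- 7
    surf <- autocorrelate(image2d(m, 0.1))
    c0 <- n / 2 + 1
    expect_equal(surf$g[c0, c0], n^2 - 1, tolerance = 1e-12)
    # zero lag is the global maximum
    expect_equal(which.max(surf$g), (c0 - 1) * n + c0)
  }
})

test_that("transform-based correlation equals the brute-force oracle", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(256, 0.1, 1), 16, 16)
    surf <- autocorrelate(image2d(m, 0.1))
    expect_equal(surf$g, brute_autocorr(m), tolerance = 1e-10)
  }
})

test_that("correlation is invariant under positive intensity scaling", {
  set.seed(32)
  m <- matrix(runif(64 * 64, 0.1, 1), 64)
  g1 <- autocorrelate(image2d(m, 0.1))$g
  g2 <- autocorrelate(image2d(m * 41.7, 0.1))$g
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("correlation surface is point-symmetric", {
  set.seed(33)
  m <- matrix(runif(32 * 32, 0.1, 1), 32)
  g <- autocorrelate(image2d(m, 0.1))$g
  # lag (i, j) vs (-i, -j): indices 2..32 mirror around the centre 17
  core <- g[2:32, 2:32]
  expect_equal(core, core[31:1, 31:1], tolerance = 1e-10)
})

test_that("g-curve extraction picks the central profile", {
  m <- matrix(0.2, 32, 32); m[10, 20] <- 5
  surf <- autocorrelate(image2d(m, 0.1))
  for (mode in c("horizontal", "vertical", "radial_mean")) {
    cur <- extract_g_curve(surf, mode)
    expect_equal(cur$values[cur$lags_pix == 0], max(cur$values))
  }
  hor <- extract_g_curve(surf, "horizontal")
  expect_equal(sum(hor$lags_pix == 0), 1L)
  # symmetric values at opposite lags (periodic surface)
  v <- hor$values[match(c(-5, 5), hor$lags_pix)]
  expect_equal(v[1], v[2], tolerance = 1e-10)
  # radial mean at lag 0 is the zero-lag value itself
  rad <- extract_g_curve(surf, "radial_mean")
  expect_equal(rad$values[rad$lags_pix == 0], surf$g[17, 17])
})

test_that("Lorentzian fit recovers exact model samples", {
  x <- -20:20
  y <- 2 * 9 / (x^2 + 9)
  cur <- structure(list(lags_pix = as.numeric(x), values = y),
                   class = "g_curve")
  p <- fit_lorentzian(cur)
  expect_equal(p$g0, 2, tolerance = 1e-8)
  expect_equal(p$w_pix, 3, tolerance = 1e-8)
  expect_equal(p$offset, 0, tolerance = 1e-8)
  expect_equal(p$fwhm_pix, 2 * p$w_pix)
  expect_equal(p$r_pix, p$w_pix)

  # additive offset shifts only the offset parameter
  cur2 <- structure(list(lags_pix = as.numeric(x), values = y + 0.5),
                    class = "g_curve")
  p2 <- fit_lorentzian(cur2)
  expect_equal(p2$g0, 2, tolerance = 1e-8)
  expect_equal(p2$w_pix, 3, tolerance = 1e-8)
  expect_equal(p2$offset, 0.5, tolerance = 1e-8)

  # including the zero-lag sample uses all points
  p3 <- fit_lorentzian(cur, exclude_zero_lag = FALSE)
  expect_equal(p3$g0, 2, tolerance = 1e-8)
})

test_that("Lorentzian fit rejects peakless input", {
  flat <- structure(list(lags_pix = as.numeric(-10:10), values = rep(1, 21)),
                    class = "g_curve")
  expect_error(fit_lorentzian(flat), "peak|fit")
  short <- structure(list(lags_pix = c(-1, 0, 1), values = c(1, 2, 1)),
                     class = "g_curve")
  expect_error(fit_lorentzian(short), "5 points")
})

test_that("count_lds reproduces the counting formula verbatim", {
  msk <- hypha_mask(matrix(TRUE, 4, 4), 1)     # area 16 um^2
  mkp <- function(g0, w) structure(
    list(g0 = g0, w_pix = w, offset = 0, r_pix = w, fwhm_pix = 2 * w),
    class = "lorentzian_params")
  cases <- list(list(n = 128, r = 2, g0 = 1),
                list(n = 256, r = 4, g0 = 0.5),
                list(n = 1024, r = 3.3, g0 = 12.8))
  for (cs in cases) {
    q <- count_lds(mkp(cs$g0, cs$r), cs$n, msk, 0.1)
    expect_equal(q$n_ld, cs$n^2 / (cs$r^2 * pi * cs$g0), tolerance = 1e-12)
    expect_equal(q$density_per_um2, q$n_ld / 16, tolerance = 1e-12)
    expect_equal(q$mean_diameter_um, 2 * cs$r * 0.1, tolerance = 1e-12)
    expect_equal(q$method, "ICS")
  }
  expect_equal(count_lds(mkp(1, 2), 128, msk, 0.1)$n_ld, 1303.797, tolerance = 1e-4)
  bad <- mkp(1, 2); bad$g0 <- -1
  expect_error(count_lds(bad, 128, msk, 0.1), "positive")
})

test_that("single-droplet G-curve width matches the droplet size", {
  d_um <- 0.8
  spec <- small_spec(seed = 12, n_droplets = 1L, diameter_mean_um = d_um,
                     diameter_sd_um = 1e-9, wall_peak = 1e-9,
                     cytoplasm_level = 0, background_level = 0)
  sim <- generate_hypha_image(spec)
  surf <- autocorrelate(to_pow2_square(sim$image))
  p <- fit_lorentzian(extract_g_curve(surf))
  d_true <- sim$ground_truth$droplet_diameters_um[1]
  expected_px <- sqrt((d_true / spec$pixel_size_um)^2 +
                      (2.355 * spec$psf_sigma_um / spec$pixel_size_um)^2)
  expect_equal(p$fwhm_pix, expected_px, tolerance = 0.3)
})

test_that("fitted amplitude scales inversely with droplet number", {
  ratios <- vapply(1:6, function(sd) {
    g0s <- vapply(c(10L, 20L), function(n) {
      spec <- mid_spec(seed = 100 + sd, n_droplets = n,
                       diameter_sd_um = 0.05)
      sim <- generate_hypha_image(spec)
      q <- ics_quantify(sim$image, mask = sim$ground_truth$hypha_mask)
      q$fit_params$g0
    }, 0)
    g0s[1] / g0s[2]
  }, 0)
  expect_gt(median(ratios), 2 * 0.8)
  expect_lt(median(ratios), 2 * 1.2)
})

test_that("estimated diameter tracks the true droplet diameter", {
  med_diam <- function(d) {
    median(vapply(1:5, function(sd) {
      spec <- mid_spec(seed = 200 + sd, n_droplets = 8L,
                       diameter_mean_um = d, diameter_sd_um = 0.05)
      sim <- generate_hypha_image(spec)
      ics_quantify(sim$image,
                   mask = sim$ground_truth$hypha_mask)$mean_diameter_um
    }, 0))
  }
  est <- vapply(c(0.9, 0.7, 0.5), med_diam, 0)
  expect_true(all(diff(est) < 0))   # strictly decreasing with true diameter
})
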