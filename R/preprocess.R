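#' Segment the hypha and measure its area
#'
#' Smooths the image with a Gaussian, thresholds it by Otsu's method, closes
#' and hole-fills the binary result, and keeps the largest connected
#' component. Otsu's split is applied in two stages: the first split
#' separates the bright droplet class from everything else, and a second
#' split of the remaining (sub-droplet) intensities separates the hypha body
#' (cytoplasm plus wall) from the surrounding medium; the lower of the two
#' thresholds segments the cell. On an image whose strongest contrast
#' already is hypha-versus-medium the second split would land inside the
#' medium noise, so the stage-two threshold is only used when it produces a
#' plausible foreground (less than half the frame).
#'
#' @param image An [image2d] containing one hypha-scale bright region.
#' @param smooth_sigma_um Gaussian smoothing sigma before thresholding, in
#'   micrometres. The default (0.6 um) suppresses pixel noise well below
#'   the hypha/medium contrast at any realistic pixel size while staying
#'   much smaller than the hypha width. Thresholding low on the flank of
#'   the smoothed wall rim dilates the segmented support by roughly this
#'   scale, so the filled mask is eroded by the same amount afterwards.
#' @param close_um Diameter of the disc used for morphological closing, in
#'   micrometres.
#' @return A [hypha_mask].
#' @export
estimate_hypha_mask <- function(image, smooth_sigma_um = 0.6, close_um = 1.0) {
  assert_image2d(image)
  px <- image$pixel_size_um
  m <- image$pixels
  if (max(m) == min(m)) stop("segmentation failure: constant image")
  sm <- .gauss_blur(m, smooth_sigma_um / px)
  otsu01 <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(NA_real_)
    v01 <- (v - rng[1]) / (rng[2] - rng[1])
    EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1)), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
  }
  t1 <- otsu01(as.vector(sm))
  t2 <- otsu01(as.vector(sm)[sm < t1])
  th <- if (!is.na(t2) && mean(sm >= t2) < 0.5) t2 else t1
  bin <- sm >= th

  # opening removes isolated noise speckle that the threshold lets through
  # before closing could weld it into spurious regions
  open_px <- max(3L, 2L * floor(0.25 * close_um / px) + 1L)
  bin <- EBImage::opening(bin * 1, EBImage::makeBrush(open_px, "disc")) > 0

  brush_px <- max(3L, 2L * floor(close_um / px / 2) + 1L)
  kern <- EBImage::makeBrush(brush_px, shape = "disc")
  bin <- EBImage::closing(bin * 1, kern)
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) stop("segmentation failure: empty mask")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- lab == keep
  erode_px <- 2L * floor(1.5 * smooth_sigma_um / px) + 1L
  if (erode_px >= 3L) {
    kern2 <- EBImage::makeBrush(erode_px, shape = "disc")
    er <- EBImage::erode(mask * 1, kern2) > 0
    if (any(er)) mask <- er
  }
  frac <- mean(mask)
  if (frac > 0.99) stop("segmentation failure: mask covers the whole frame")
  hypha_mask(mask, px)
}

#' Mean intensity outside the hypha
#'
#' The background estimate used by the subtraction procedure: the average
#' pixel intensity over the region outside the hypha mask.
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask] of the same shape.
#' @return The mean outside-mask intensity (scalar).
#' @export
estimate_background <- function(image, mask) {
  assert_image2d(image)
  outside <- !mask$mask
  n_out <- sum(outside)
  if (n_out == 0L) stop("no pixels outside the mask")
  if (n_out < 0.01 * length(outside))
    warning("fewer than 1% of pixels outside the mask; background estimate unstable")
  mean(image$pixels[outside])
}

#' Iterated background subtraction (cell-wall suppression)
#'
#' Repeats `n_iterations` times: subtract the background estimate from every
#' pixel and clip negative values to zero. Two variants of the iteration are
#' offered, differing in where the background value comes from:
#'
#' * `mode = "reestimate"` (default): the outside-mask mean is recomputed on
#'   the current image before every subtraction. Because clipping keeps the
#'   outside mean slightly positive while any structure remains there, the
#'   per-iteration step shrinks rapidly; the cumulative subtraction
#'   saturates a little above the background level plus a couple of noise
#'   standard deviations.
#' * `mode = "fixed"`: the outside-mask mean is measured once on the input
#'   image (or supplied via `background`) and the same value is subtracted
#'   at every iteration, for a cumulative removal of
#'   `n_iterations * background`. After the default 20 iterations
#'   everything dimmer than twenty times the background -- medium noise,
#'   cytoplasm and the wall rim -- is driven to exactly zero, while the much
#'   brighter droplets survive; this is the variant that makes the wall
#'   disappear and is what the downstream correlation pipeline uses (see
#'   [ics_quantify()]).
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask]; held fixed across iterations.
#' @param n_iterations Number of subtraction passes (>= 0).
#' @param mode `"reestimate"` or `"fixed"`, see above.
#' @param background Optional fixed background value overriding the
#'   outside-mask estimate (useful after [crop_wall()], whose output has an
#'   artificially zeroed outside region). Implies `mode = "fixed"`.
#' @return The subtracted [image2d] (same shape and pixel size).
#' @export
subtract_background <- function(image, mask, n_iterations = 20L,
                                mode = c("reestimate", "fixed"),
                                background = NULL) {
  assert_image2d(image)
  mode <- match.arg(mode)
  if (!is.null(background)) mode <- "fixed"
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  m <- image$pixels
  outside <- !mask$mask
  if (sum(outside) == 0L) stop("no pixels outside the mask")
  if (mode == "fixed") {
    b <- if (is.null(background)) mean(m[outside]) else background
    if (n_iterations > 0) m <- pmax(m - n_iterations * b, 0)
  } else {
    for (i in seq_len(n_iterations)) {
      b <- mean(m[outside])
      m <- pmax(m - b, 0)
    }
  }
  image2d(m, image$pixel_size_um, image$channel)
}

#' Data-driven number of background subtractions
#'
#' Applies subtractions one at a time and recomputes the ICS droplet count
#' after each; stops at the first iteration `k` whose count changes by less
#' than `rel_tol` relative to the previous iteration (the "cessation of a
#' significant reduction" stopping rule). Returns the chosen `k` along with
#' the full count-versus-iteration trace.
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask].
#' @param max_iter Maximum subtractions to try (>= 2).
#' @param rel_tol Relative change in the ICS count below which the procedure
#'   is considered converged.
#' @param mode Subtraction variant, see [subtract_background()]; the default
#'   matches the [ics_quantify()] pipeline.
#' @param ... Passed to [ics_quantify()] (profile mode etc.); subtraction is
#'   disabled internally since this function performs it.
#' @return A list of class `subtraction_trace`: `n_iterations` (the chosen
#'   k, or `max_iter` if the tolerance was never met) and `trace`, a data
#'   frame with columns `iteration`, `background`, `n_ld`.
#' @export
auto_subtraction_count <- function(image, mask, max_iter = 40L,
                                   rel_tol = 0.05,
                                   mode = c("fixed", "reestimate"), ...) {
  assert_image2d(image)
  mode <- match.arg(mode)
  if (max_iter < 2L) stop("max_iter must be >= 2")
  outside <- !mask$mask
  m <- image$pixels
  px <- image$pixel_size_um
  b_fixed <- mean(m[outside])

  count_now <- function(mm, k) {
    img <- image2d(mm, px, image$channel)
    q <- tryCatch(
      ics_quantify(img, mask = mask, n_subtractions = 0L, ...),
      error = function(e)
        stop(sprintf("ICS failed at subtraction %d: %s", k,
                     conditionMessage(e)))
    )
    q$n_ld
  }

  ns <- numeric(max_iter + 1L)
  bgs <- numeric(max_iter + 1L)
  bgs[1] <- mean(m[outside])
  ns[1] <- count_now(m, 0L)
  chosen <- NA_integer_
  for (k in seq_len(max_iter)) {
    b <- if (mode == "fixed") b_fixed else mean(m[outside])
    m <- pmax(m - b, 0)
    bgs[k + 1L] <- b
    ns[k + 1L] <- count_now(m, k)
    if (is.na(chosen) &&
        abs(ns[k + 1L] - ns[k]) / ns[k] < rel_tol) {
      chosen <- k
      break
    }
  }
  used <- if (is.na(chosen)) max_iter else chosen
  kept <- seq_len(used + 1L)
  structure(
    list(n_iterations = used,
         trace = data.frame(iteration = kept - 1L,
                            background = bgs[kept],
                            n_ld = ns[kept])),
    class = "subtraction_trace"
  )
}

#' @export
print.subtraction_trace <- function(x, ...) {
  cat(sprintf("<subtraction_trace> converged at k = %d subtractions\n",
              x$n_iterations))
  print(utils::head(x$trace, 10))
  invisible(x)
}

#' Crop the cell wall by eroding the hypha mask
#'
#' Emulates manual delineation-and-cropping of the wall: every pixel outside
#' the mask eroded by `erode_um` is set to zero, removing the wall ribbon
#' (and anything outside) in one stroke.
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask].
#' @param erode_um Erosion depth in micrometres (>= 0). Choose it larger
#'   than the wall thickness to remove the rim entirely.
#' @return The cropped [image2d].
#' @export
crop_wall <- function(image, mask, erode_um) {
  assert_image2d(image)
  if (erode_um < 0) stop("erode_um must be >= 0")
  px <- image$pixel_size_um
  keep <- mask$mask
  if (erode_um > 0) {
    brush_px <- 2L * floor(erode_um / px) + 1L
    if (brush_px >= 3L) {
      kern <- EBImage::makeBrush(brush_px, shape = "disc")
      keep <- EBImage::erode(keep * 1, kern) > 0
    }
  }
  if (!any(keep)) stop("erosion emptied the mask")
  m <- image$pixels
  m[!keep] <- 0
  image2d(m, px, image$channel)
}
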