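#' Crop or pad an image to a square power-of-two side
#'
#' The discrete-transform autocorrelation operates on 2^n x 2^n frames.
#' `crop_center` (default) takes the largest centred 2^n square that fits;
#' `pad_zero` embeds the image centred in the next 2^n square of zeros.
#'
#' @param image An [image2d].
#' @param mode `"crop_center"` or `"pad_zero"`.
#' @return An [image2d] with side 2^n.
#' @export
to_pow2_square <- function(image, mode = c("crop_center", "pad_zero")) {
  assert_image2d(image)
  mode <- match.arg(mode)
  d <- dim(image$pixels)
  if (mode == "crop_center") {
    side <- 2L^floor(log2(min(d)))
    r0 <- floor((d[1] - side) / 2)
    c0 <- floor((d[2] - side) / 2)
    m <- image$pixels[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)]
  } else {
    side <- 2L^ceiling(log2(max(d)))
    m <- matrix(0, side, side)
    r0 <- floor((side - d[1]) / 2)
    c0 <- floor((side - d[2]) / 2)
    m[(r0 + 1):(r0 + d[1]), (c0 + 1):(c0 + d[2])] <- image$pixels
  }
  image2d(m, image$pixel_size_um, image$channel)
}

# circular shift putting lag 0 at index n/2 + 1
.fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Spatial intensity-fluctuation autocorrelation of an image
#'
#' Computes the normalised fluctuation autocorrelation
#' \deqn{G(\xi, \eta) = \frac{\langle \delta I(x, y)\,
#'   \delta I(x + \xi, y + \eta)\rangle}{\langle I \rangle^2},\qquad
#'   \delta I = I - \langle I \rangle,}
#' evaluated with forward/inverse discrete Fourier transforms (periodic
#' lags), and shifts the result so zero lag sits at the central pixel
#' `(n/2 + 1, n/2 + 1)`. For sparse bright particles the zero-lag amplitude
#' G(0,0) is inversely proportional to the number of particles in the frame,
#' which is what ICS counting exploits.
#'
#' @param image An [image2d] with a 2^n square pixel grid and positive mean.
#' @return An object of class `autocorr_surface`: list with `g` (the shifted
#'   lag grid), `lags_pix` (lag values along either axis, `-n/2 ... n/2-1`),
#'   `n_pix` (frame side) and `pixel_size_um`.
#' @export
autocorrelate <- function(image) {
  assert_image2d(image)
  m <- image$pixels
  d <- dim(m)
  if (d[1] != d[2] || bitwAnd(d[1], d[1] - 1L) != 0L)
    stop("autocorrelate requires a 2^n x 2^n image; see to_pow2_square()")
  mu <- mean(m)
  if (mu <= 0) stop("image mean must be positive (all-zero image?)")
  n_tot <- length(m)
  dm <- m - mu
  f <- stats::fft(dm)
  corr <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / n_tot  # sum over x
  g <- .fftshift2(corr / n_tot / mu^2)                         # average, normalise
  side <- d[1]
  structure(
    list(g = g,
         lags_pix = seq.int(-side / 2, side / 2 - 1),
         n_pix = side,
         pixel_size_um = image$pixel_size_um),
    class = "autocorr_surface"
  )
}

#' Extract the central G curve from an autocorrelation surface
#'
#' The 1D profile through zero lag that is fitted downstream. `horizontal`
#' (default) and `vertical` take the central row/column of the surface;
#' `radial_mean` azimuthally averages in 1-pixel radial bins and mirrors the
#' result onto negative lags (droplets are isotropic, so radial averaging is
#' a variance-reduction option).
#'
#' @param surface An `autocorr_surface` from [autocorrelate()].
#' @param mode `"horizontal"`, `"vertical"` or `"radial_mean"`.
#' @return An object of class `g_curve`: list with `lags_pix` (ordered,
#'   spanning negative through 0 to positive) and `values`.
#' @export
extract_g_curve <- function(surface,
                            mode = c("horizontal", "vertical", "radial_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "autocorr_surface"))
  n <- surface$n_pix
  c0 <- n / 2 + 1
  if (mode == "horizontal") {
    vals <- surface$g[c0, ]
    lags <- surface$lags_pix
  } else if (mode == "vertical") {
    vals <- surface$g[, c0]
    lags <- surface$lags_pix
  } else {
    lag2 <- outer(surface$lags_pix^2, surface$lags_pix^2, `+`)
    rad <- round(sqrt(t(lag2)))   # symmetric; orientation irrelevant
    prof <- tapply(as.vector(surface$g), as.vector(rad), mean)
    rr <- as.integer(names(prof))
    keep <- rr <= n / 2 - 1
    rr <- rr[keep]; prof <- prof[keep]
    lags <- c(-rev(rr[rr > 0]), rr)
    vals <- c(rev(prof[rr > 0]), prof)
  }
  structure(list(lags_pix = as.numeric(lags), values = as.numeric(vals)),
            class = "g_curve")
}

#' Fit a Lorentzian to a G curve
#'
#' Least-squares fit of
#' \deqn{L(\xi) = G(0)\, \frac{w^2}{\xi^2 + w^2} + \mathrm{offset}}
#' to the central autocorrelation profile. `w` is the half width at half
#' maximum; the droplet radius estimate is `r = w = FWHM / 2`. The additive
#' offset absorbs the residual pedestal that incompletely suppressed
#' wall/cytoplasm signal leaves under the droplet peak. By default the
#' single zero-lag sample is excluded: uncorrelated (shot/read) noise
#' contributes a spike at zero lag only, and the fitted -- not sampled --
#' amplitude is used as G(0).
#'
#' @param curve A `g_curve`.
#' @param exclude_zero_lag Drop the lag-0 sample before fitting (default
#'   TRUE).
#' @return An object of class `lorentzian_params`: `g0`, `w_pix`, `offset`,
#'   `r_pix` (= `w_pix`), `fwhm_pix` (= `2 * w_pix`), and `fit` (the
#'   underlying [minpack.lm::nls.lm] object). Several starting points are
#'   tried and the converged fit with the lowest deviance is kept.
#' @export
fit_lorentzian <- function(curve, exclude_zero_lag = TRUE) {
  stopifnot(inherits(curve, "g_curve"))
  x <- curve$lags_pix
  y <- curve$values
  if (exclude_zero_lag) {
    keep <- x != 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 5L) stop("need at least 5 points to fit")
  n_half <- max(abs(x))

  off0 <- stats::median(y[abs(x) >= 0.75 * n_half])
  g00 <- max(y) - off0
  if (g00 <= 0) stop("fit failure: no peak above the tail level")
  half_idx <- which(y - off0 <= g00 / 2 & abs(x) > 0)
  w0 <- if (length(half_idx)) max(min(abs(x[half_idx])), 1) else 2

  resid_fn <- function(p) y - (p[1] * p[2]^2 / (x^2 + p[2]^2) + p[3])
  lower <- c(1e-12, 1e-3, -Inf)
  upper <- c(Inf, n_half / 2, Inf)
  starts <- list(c(g00, w0, off0),
                 c(g00, max(2, 2 * w0), off0),
                 c(max(y) - min(y), 1.5, min(y)),
                 c(g00 / 2, 5, off0))
  best <- NULL
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:4)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best))
    stop(sprintf("Lorentzian fit failed to converge [init g0=%.3g w=%.3g off=%.3g]",
                 g00, w0, off0))
  p <- best$par
  if (p[2] <= 0 || p[1] <= 0)
    stop("Lorentzian fit failed: non-positive amplitude or width")
  structure(
    list(g0 = p[1], w_pix = p[2], offset = p[3], r_pix = p[2],
         fwhm_pix = 2 * p[2], fit = best),
    class = "lorentzian_params"
  )
}

#' @export
print.lorentzian_params <- function(x, ...) {
  cat(sprintf("<lorentzian_params> G(0) = %.4g, w = %.3f px (FWHM %.3f px), offset = %.4g\n",
              x$g0, x$w_pix, x$fwhm_pix, x$offset))
  invisible(x)
}

#' Droplet count, density and size from fitted ICS parameters
#'
#' Applies the ICS counting formula
#' \deqn{N_{LD} = \frac{N_{pix} \cdot N_{pix}}{r^2 \pi \, G(0)}}
#' where `N_pix` is the side of the analysed 2^n square, `r` is the mean
#' droplet radius taken as half the FWHM of the fitted G curve (in pixels,
#' the same unit as `N_pix`), and `G(0)` is the fitted amplitude. The count
#' is converted to a per-area density with the hypha area, and the reported
#' mean diameter is `FWHM * pixel_size_um`.
#'
#' @param params A `lorentzian_params`.
#' @param n_pix Side of the analysed image in pixels.
#' @param mask The [hypha_mask] providing the normalising area.
#' @param pixel_size_um Micrometres per pixel of the analysed image.
#' @return A `quant_result`: `n_ld`, `density_per_um2`, `mean_diameter_um`,
#'   `method = "ICS"`.
#' @examples
#' p <- structure(list(g0 = 1, w_pix = 2, r_pix = 2, fwhm_pix = 4,
#'                     offset = 0), class = "lorentzian_params")
#' msk <- hypha_mask(matrix(TRUE, 10, 10), 1)
#' count_lds(p, n_pix = 128, mask = msk, pixel_size_um = 0.1)$n_ld
#' # 128^2 / (2^2 * pi * 1) = 1303.8
#' @export
count_lds <- function(params, n_pix, mask, pixel_size_um) {
  stopifnot(inherits(params, "lorentzian_params"))
  if (params$g0 <= 0 || params$r_pix <= 0)
    stop("count_lds requires positive G(0) and r")
  n_ld <- n_pix^2 / (params$r_pix^2 * pi * params$g0)
  quant_result(
    n_ld = n_ld,
    density_per_um2 = n_ld / mask$area_um2,
    mean_diameter_um = params$fwhm_pix * pixel_size_um,
    method = "ICS"
  )
}

#' Construct a quantification result
#'
#' @param n_ld Droplet count (may be fractional for ICS).
#' @param density_per_um2 Count per hypha area.
#' @param mean_diameter_um Mean droplet diameter in micrometres (`NA` when
#'   no particles were found).
#' @param method `"ICS"` or `"PSA"`.
#' @return A `quant_result` list.
#' @export
quant_result <- function(n_ld, density_per_um2, mean_diameter_um, method) {
  structure(
    list(n_ld = n_ld, density_per_um2 = density_per_um2,
         mean_diameter_um = mean_diameter_um,
         method = match.arg(method, c("ICS", "PSA"))),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result/%s> N = %.1f, density = %.3g um^-2 (%.1f x 1e-3), mean diameter = %.3g um\n",
              x$method, x$n_ld, x$density_per_um2,
              1e3 * x$density_per_um2,
              x$mean_diameter_um))
  invisible(x)
}

#' Full ICS quantification of one image
#'
#' Convenience pipeline: (optional) hypha segmentation, iterated background
#' subtraction, centred power-of-two crop, autocorrelation, central-profile
#' extraction, Lorentzian fit and droplet counting. By default the 20
#' subtractions use the fixed-background variant of
#' [subtract_background()], which removes the wall rim and all sub-wall
#' structure completely -- the precondition for the correlation amplitude to
#' reflect droplet fluctuations alone. When `crop_um` is given, the wall is
#' additionally cropped away geometrically ([crop_wall()]) before the
#' subtractions, with the background value measured on the uncropped image.
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask], or `NULL` to segment with
#'   [estimate_hypha_mask()].
#' @param n_subtractions Background subtractions to apply before
#'   correlation (default 20).
#' @param subtract_mode Variant of [subtract_background()] to use
#'   (default `"fixed"`).
#' @param crop_um If non-`NULL`, erode the mask by this many micrometres
#'   and zero everything outside before subtracting (the manual
#'   wall-cropping route).
#' @param profile G-curve extraction mode, see [extract_g_curve()].
#' @param exclude_zero_lag See [fit_lorentzian()].
#' @param square_mode See [to_pow2_square()].
#' @return A `quant_result` with the fitted `lorentzian_params` attached as
#'   `$fit_params` and the `g_curve` as `$g_curve`.
#' @export
ics_quantify <- function(image, mask = NULL, n_subtractions = 20L,
                         subtract_mode = "fixed", crop_um = NULL,
                         profile = "horizontal", exclude_zero_lag = TRUE,
                         square_mode = "crop_center") {
  assert_image2d(image)
  if (is.null(mask)) mask <- estimate_hypha_mask(image)
  work <- image
  bg <- NULL
  if (!is.null(crop_um)) {
    bg <- estimate_background(image, mask)   # before cropping zeroes it
    work <- crop_wall(image, mask, crop_um)
  }
  sub <- if (n_subtractions > 0)
    subtract_background(work, mask, n_subtractions, mode = subtract_mode,
                        background = bg)
  else work
  sq <- to_pow2_square(sub, mode = square_mode)
  surf <- autocorrelate(sq)
  curve <- extract_g_curve(surf, mode = profile)
  params <- fit_lorentzian(curve, exclude_zero_lag = exclude_zero_lag)
  res <- count_lds(params, n_pix = surf$n_pix, mask = mask,
                   pixel_size_um = image$pixel_size_um)
  res$fit_params <- params
  res$g_curve <- curve
  res
}
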