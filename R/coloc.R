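#' Pearson correlation between two channels
#'
#' Sample Pearson correlation of pixel intensities over the in-mask region
#' (whole frame when no mask is given). An above-threshold variant
#' restricts the computation to pixels exceeding each channel's Otsu
#' threshold in either channel, for comparability with threshold-based
#' colocalization plugins.
#'
#' @param a,b Two [image2d] objects of identical shape.
#' @param mask Optional [hypha_mask] restricting the pixels used.
#' @param above_threshold If `TRUE`, keep only pixels above the per-channel
#'   Otsu threshold in at least one channel.
#' @return The correlation coefficient (scalar in \[-1, 1\]).
#' @export
coloc_pearson <- function(a, b, mask = NULL, above_threshold = FALSE) {
  assert_image2d(a); assert_image2d(b)
  if (!all(dim(a$pixels) == dim(b$pixels)))
    stop("channels must have identical shape")
  keep <- if (is.null(mask)) rep(TRUE, length(a$pixels)) else as.vector(mask$mask)
  if (above_threshold) {
    ta <- attr(threshold_mask(a, "otsu"), "threshold")
    tb <- attr(threshold_mask(b, "otsu"), "threshold")
    keep <- keep & (as.vector(a$pixels) >= ta | as.vector(b$pixels) >= tb)
  }
  va <- a$pixels[keep]; vb <- b$pixels[keep]
  if (length(va) < 2L) stop("need at least 2 pixels in scope")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("Pearson correlation undefined for a constant channel")
  stats::cor(va, vb)
}

# cross-correlation surface G_ab, same normalisation/shift as autocorrelate()
.crosscorrelate <- function(a, b) {
  ma <- a$pixels; mb <- b$pixels
  d <- dim(ma)
  if (d[1] != d[2] || bitwAnd(d[1], d[1] - 1L) != 0L)
    stop("cross-correlation requires 2^n x 2^n images")
  mua <- mean(ma); mub <- mean(mb)
  if (mua <= 0 || mub <= 0) stop("channel means must be positive")
  n_tot <- length(ma)
  fa <- stats::fft(ma - mua)
  fb <- stats::fft(mb - mub)
  corr <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / n_tot
  g <- .fftshift2(corr / n_tot / (mua * mub))
  structure(
    list(g = g, lags_pix = seq.int(-d[1] / 2, d[1] / 2 - 1),
         n_pix = d[1], pixel_size_um = a$pixel_size_um),
    class = "autocorr_surface"
  )
}

#' ICCS interacting-cluster fraction of two channels
#'
#' Image cross-correlation spectroscopy: computes the auto-correlations
#' G_aa and G_bb and the cross-correlation
#' \deqn{G_{ab}(\xi,\eta) = \frac{\langle \delta I_a(x,y)\,
#'   \delta I_b(x+\xi, y+\eta)\rangle}{\langle I_a\rangle
#'   \langle I_b\rangle},}
#' fits a Lorentzian to each central profile, and forms amplitude ratios:
#' the fraction of a-channel clusters interacting with the b channel is
#' `G_ab(0) / G_bb(0)` (and symmetrically for b with a). Both channels must
#' already be preprocessed (background-subtracted, square power-of-two
#' frames with positive mean).
#'
#' @param a,b Preprocessed [image2d] channels of identical 2^n shape.
#' @param profile Central-profile mode, see [extract_g_curve()].
#' @param exclude_zero_lag Applied identically to all three fits (so that
#'   `iccs_fraction(a, a)` is exactly 1 up to fit tolerance).
#' @return A `coloc_result`: `pearson_r`, `iccs_fraction` (a with b),
#'   `fraction_a_with_b`, `fraction_b_with_a`, `n_pixels_used`, and the
#'   three fitted amplitudes `g_aa0`, `g_bb0`, `g_ab0`. Fractions far above
#'   1 are flagged with a warning (fit pathology).
#' @export
iccs_fraction <- function(a, b, profile = "horizontal",
                          exclude_zero_lag = TRUE) {
  assert_image2d(a); assert_image2d(b)
  if (!all(dim(a$pixels) == dim(b$pixels)))
    stop("channels must have identical shape")
  fit_one <- function(surface, which) {
    curve <- extract_g_curve(surface, mode = profile)
    tryCatch(fit_lorentzian(curve, exclude_zero_lag = exclude_zero_lag),
             error = function(e)
               stop(sprintf("ICCS fit failed for %s: %s", which,
                            conditionMessage(e))))
  }
  p_aa <- fit_one(autocorrelate(a), "G_aa")
  p_bb <- fit_one(autocorrelate(b), "G_bb")
  p_ab <- fit_one(.crosscorrelate(a, b), "G_ab")

  f_ab <- p_ab$g0 / p_bb$g0
  f_ba <- p_ab$g0 / p_aa$g0
  if (f_ab > 1.5 || f_ba > 1.5)
    warning("ICCS fraction far above 1: likely fit pathology")
  structure(
    list(pearson_r = coloc_pearson(a, b),
         iccs_fraction = f_ab,
         fraction_a_with_b = f_ab,
         fraction_b_with_a = f_ba,
         n_pixels_used = length(a$pixels),
         g_aa0 = p_aa$g0, g_bb0 = p_bb$g0, g_ab0 = p_ab$g0),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> Pearson r = %.3f; ICCS fraction a|b = %.3f, b|a = %.3f\n",
              x$pearson_r, x$fraction_a_with_b, x$fraction_b_with_a))
  invisible(x)
}

#' Full colocalization analysis of a raw two-channel pair
#'
#' Segments the hypha on channel A, applies the same iterated background
#' subtraction to both channels, crops both to the centred power-of-two
#' square, and reports Pearson correlation (whole-mask and above-threshold
#' variants) together with the ICCS interacting fractions.
#'
#' @param a,b Raw [image2d] channels of identical shape.
#' @param n_subtractions Background subtractions per channel (default 20).
#' @param ... Passed to [iccs_fraction()].
#' @return A `coloc_result` with the extra element
#'   `pearson_above_threshold`.
#' @export
coloc_quantify <- function(a, b, n_subtractions = 20L, ...) {
  mask <- estimate_hypha_mask(a)
  pa <- to_pow2_square(subtract_background(a, mask, n_subtractions,
                                           mode = "fixed"))
  pb <- to_pow2_square(subtract_background(b, mask, n_subtractions,
                                           mode = "fixed"))
  res <- iccs_fraction(pa, pb, ...)
  res$pearson_above_threshold <- coloc_pearson(a, b, mask = mask,
                                               above_threshold = TRUE)
  res$pearson_r <- coloc_pearson(a, b, mask = mask)
  res
}
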