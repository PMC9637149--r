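#' Threshold an image to a binary particle mask
#'
#' @param image An [image2d].
#' @param method `"otsu"` (default), `"fixed"` or `"percentile"`.
#' @param value Threshold intensity for `"fixed"`; percentile in \[0, 100\]
#'   for `"percentile"`.
#' @return A logical matrix, `TRUE` where intensity >= threshold, with the
#'   threshold used recorded in attribute `"threshold"`.
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed", "percentile"),
                           value = NULL) {
  assert_image2d(image)
  method <- match.arg(method)
  m <- image$pixels
  th <- switch(method,
    otsu = {
      rng <- range(m)
      if (rng[1] == rng[2]) stop("Otsu thresholding needs a non-constant image")
      m01 <- (m - rng[1]) / (rng[2] - rng[1])
      EBImage::otsu(EBImage::Image(m01), range = c(0, 1)) *
        (rng[2] - rng[1]) + rng[1]
    },
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold 'value'")
      value
    },
    percentile = {
      if (is.null(value)) stop("method 'percentile' needs a percentile 'value'")
      stats::quantile(m, value / 100, names = FALSE)
    })
  structure(m >= th, dim = dim(m), threshold = th)
}

# 8-connected labelling of a binary mask (ImageJ's connectivity) via graph
# components over foreground-pixel adjacency.
.label8 <- function(mask) {
  n_r <- nrow(mask); n_c <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, n_r, n_c)
  if (length(fg) == 0L) return(lab)
  id <- matrix(0L, n_r, n_c)
  id[fg] <- seq_along(fg)
  row_i <- ((fg - 1L) %% n_r) + 1L
  col_i <- ((fg - 1L) %/% n_r) + 1L
  edges <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row_i + sh[1]; c2 <- col_i + sh[2]
    ok <- r2 >= 1L & r2 <= n_r & c2 >= 1L & c2 <= n_c
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has))
      edges <- c(edges, rbind(id[fg][ok][has], nb[has]))
  }
  comp <- igraph::components(
    igraph::make_graph(edges = edges, n = length(fg), directed = FALSE))
  lab[fg] <- comp$membership
  lab
}

#' Connected-component particle analysis of a binary mask
#'
#' Labels the mask with 8-connectivity, discards components whose physical
#' area falls outside `[min_area_um2, max_area_um2]`, and measures each
#' remaining particle: area, equivalent-circle diameter
#' (`2 * sqrt(area / pi)`), centroid and circularity
#' (`4 * pi * area / perimeter^2`, capped at 1 to absorb rasterization
#' bias on few-pixel particles).
#'
#' @param mask Logical matrix (e.g. from [threshold_mask()]).
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2,max_area_um2 Physical area filter. The default
#'   minimum corresponds to 2 pixels (hot-pixel rejection); no maximum.
#' @param hypha_area_um2 Optional hypha area to attach for normalisation.
#' @return A `particle_table`: a data frame with columns `label`,
#'   `area_um2`, `equivalent_diameter_um`, `centroid_x`, `centroid_y`
#'   (continuous pixel coordinates), `circularity`; the hypha area is kept
#'   in attribute `"hypha_area_um2"`.
#' @export
analyze_particles <- function(mask, pixel_size_um,
                              min_area_um2 = 2 * pixel_size_um^2,
                              max_area_um2 = Inf,
                              hypha_area_um2 = NA_real_) {
  if (!is.logical(mask)) mask <- mask > 0
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (min_area_um2 < 0 || min_area_um2 >= max_area_um2)
    stop("need 0 <= min_area_um2 < max_area_um2")
  lab <- .label8(mask)
  n_lab <- max(lab)
  empty <- particle_table(
    data.frame(label = integer(0), area_um2 = numeric(0),
               equivalent_diameter_um = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               circularity = numeric(0)),
    hypha_area_um2)
  if (n_lab == 0L) return(empty)

  px_area <- pixel_size_um^2
  counts <- tabulate(lab[lab > 0L], nbins = n_lab)
  areas <- counts * px_area
  keep <- which(areas >= min_area_um2 & areas <= max_area_um2)
  if (length(keep) == 0L) return(empty)

  # relabel kept components contiguously from 1
  remap <- integer(n_lab)
  remap[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  lab2[nz] <- remap[lab[nz]]

  idx <- which(lab2 > 0L)
  l <- lab2[idx]
  rows <- ((idx - 1L) %% nrow(lab2)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab2)) + 1L
  cx <- tapply(cols - 0.5, l, mean)
  cy <- tapply(rows - 0.5, l, mean)

  shp <- EBImage::computeFeatures.shape(lab2)
  per <- shp[, "s.perimeter"]
  area_px <- counts[keep]
  circ <- pmin(1, 4 * pi * area_px / pmax(per, 1)^2)

  particle_table(
    data.frame(label = seq_along(keep),
               area_um2 = area_px * px_area,
               equivalent_diameter_um = 2 * sqrt(area_px * px_area / pi),
               centroid_x = as.numeric(cx),
               centroid_y = as.numeric(cy),
               circularity = as.numeric(circ)),
    hypha_area_um2)
}

particle_table <- function(df, hypha_area_um2) {
  attr(df, "hypha_area_um2") <- hypha_area_um2
  class(df) <- c("particle_table", "data.frame")
  df
}

#' Summarise a particle table into a quantification result
#'
#' @param table A `particle_table` from [analyze_particles()].
#' @param hypha_area_um2 Hypha area; defaults to the one attached to the
#'   table.
#' @return A `quant_result` with `method = "PSA"`. An empty table yields a
#'   count of 0 and `NA` mean diameter.
#' @export
summarize_psa <- function(table, hypha_area_um2 = attr(table, "hypha_area_um2")) {
  stopifnot(inherits(table, "particle_table"))
  if (is.na(hypha_area_um2) || hypha_area_um2 <= 0)
    stop("a positive hypha_area_um2 is required")
  n <- nrow(table)
  quant_result(
    n_ld = n,
    density_per_um2 = n / hypha_area_um2,
    mean_diameter_um = if (n > 0) mean(table$equivalent_diameter_um) else NA_real_,
    method = "PSA"
  )
}

#' Full PSA quantification of one image
#'
#' Thresholds the image, runs particle analysis restricted to the hypha
#' mask, and summarises counts and sizes. With the default Otsu rule the
#' threshold is computed from the in-hypha pixel histogram (the region of
#' interest an analyst thresholds on), which separates the bright droplets
#' from the cytoplasm/wall background; on the whole frame the dominant
#' hypha/medium contrast would capture the Otsu split instead.
#'
#' @param image An [image2d].
#' @param mask A [hypha_mask], or `NULL` to segment automatically.
#' @param method,value Thresholding rule, see [threshold_mask()].
#' @param min_area_um2,max_area_um2 Particle area filter.
#' @return A `quant_result` (method `"PSA"`) with the `particle_table`
#'   attached as `$particles` and the threshold used as `$threshold`.
#' @export
psa_quantify <- function(image, mask = NULL,
                         method = "otsu", value = NULL,
                         min_area_um2 = 2 * image$pixel_size_um^2,
                         max_area_um2 = Inf) {
  assert_image2d(image)
  if (is.null(mask)) mask <- estimate_hypha_mask(image)
  if (method == "otsu" && is.null(value)) {
    v <- image$pixels[mask$mask]
    rng <- range(v)
    if (rng[1] == rng[2]) stop("Otsu thresholding needs a non-constant image")
    v01 <- matrix((v - rng[1]) / (rng[2] - rng[1]), ncol = 1)
    th <- EBImage::otsu(EBImage::Image(v01), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
    bin <- image$pixels >= th
  } else {
    bin <- threshold_mask(image, method = method, value = value)
    th <- attr(bin, "threshold")
  }
  bin <- bin & mask$mask
  tab <- analyze_particles(bin, image$pixel_size_um,
                           min_area_um2 = min_area_um2,
                           max_area_um2 = max_area_um2,
                           hypha_area_um2 = mask$area_um2)
  res <- summarize_psa(tab)
  res$particles <- tab
  res$threshold <- th
  res
}

#' Ordinary least-squares concordance of ICS against PSA counts
#'
#' Fits `ICS count ~ PSA count` across a batch of images analysed by both
#' methods; a slope near 1 with high R^2 indicates the two estimators agree.
#'
#' @param batch A list of pairs, each a list with elements `ics` and `psa`
#'   (two `quant_result`s), or a data frame with numeric columns `ics` and
#'   `psa`.
#' @return A list with `slope`, `intercept` and `r_squared`.
#' @export
compare_methods <- function(batch) {
  if (is.data.frame(batch)) {
    ics <- batch$ics; psa <- batch$psa
  } else {
    ics <- vapply(batch, function(p) p$ics$n_ld, 0)
    psa <- vapply(batch, function(p) p$psa$n_ld, 0)
  }
  if (length(ics) < 3L) stop("need at least 3 ICS/PSA pairs")
  if (stats::var(psa) == 0) stop("PSA counts are degenerate (zero variance)")
  fit <- stats::lm(ics ~ psa)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
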