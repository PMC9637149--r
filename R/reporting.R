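#' Group-level summary of per-image quantification results
#'
#' Collects the per-image droplet densities and the pooled droplet
#' diameters of one experimental group (e.g. control or N-starved at a
#' given time point), with the summed hypha area used for area-normalised
#' histograms.
#'
#' @param group Group label.
#' @param time_point_h Time since start of treatment, hours.
#' @param densities Numeric vector of per-image `density_per_um2`.
#' @param diameters_um Pooled droplet diameters of the group, micrometres.
#' @param total_hypha_area_um2 Sum of the member hypha areas.
#' @return A `group_summary` list.
#' @export
group_summary <- function(group, time_point_h, densities, diameters_um,
                          total_hypha_area_um2) {
  if (total_hypha_area_um2 <= 0) stop("total hypha area must be positive")
  structure(
    list(group = group, time_point_h = time_point_h,
         densities = densities, diameters_um = diameters_um,
         total_hypha_area_um2 = total_hypha_area_um2),
    class = "group_summary"
  )
}

#' Area-normalised droplet-diameter histogram with propagated errors
#'
#' Pools the group's droplet diameters into contiguous 0.3 um bins
#' `(k*0.3, (k+1)*0.3]` (labelled by the upper bin limit), divides each bin
#' count by the summed hypha area of the group, and propagates the stated
#' relative errors: the relative error of the binned per-area count is the
#' sum of the relative errors of the density and of the area, and the
#' absolute error of a bin is that relative error times the bin's per-area
#' value.
#'
#' @param group A [group_summary()].
#' @param rel_err_density Relative error of the per-area droplet count.
#' @param rel_err_area Relative error of the hypha area.
#' @param bin_um Bin width (default 0.3 um).
#' @return A data frame with columns `bin_upper_um`, `count`,
#'   `count_per_area` (per um^2) and `abs_error`.
#' @export
diameter_histogram <- function(group, rel_err_density, rel_err_area,
                               bin_um = 0.3) {
  stopifnot(inherits(group, "group_summary"))
  d <- group$diameters_um
  if (length(d) == 0) stop("no diameters in group")
  if (rel_err_density < 0 || rel_err_area < 0)
    stop("relative errors must be >= 0")
  n_bins <- ceiling(max(d) / bin_um)
  edges <- seq(0, n_bins * bin_um, by = bin_um)
  counts <- as.integer(table(cut(d, breaks = edges, right = TRUE,
                                 include.lowest = FALSE)))
  per_area <- counts / group$total_hypha_area_um2
  data.frame(
    bin_upper_um = edges[-1],
    count = counts,
    count_per_area = per_area,
    abs_error = (rel_err_density + rel_err_area) * per_area
  )
}

#' Ratio of mean droplet densities, treated over control
#'
#' @param treated,control Two [group_summary()] objects.
#' @return `mean(treated densities) / mean(control densities)`.
#' @export
treatment_ratio <- function(treated, control) {
  stopifnot(inherits(treated, "group_summary"),
            inherits(control, "group_summary"))
  if (length(treated$densities) == 0 || length(control$densities) == 0)
    stop("both groups must be non-empty")
  mc <- mean(control$densities)
  if (mc == 0) stop("control group has zero mean density")
  mean(treated$densities) / mc
}

#' Run the full quantification pipeline over a batch of images
#'
#' For every entry the hypha is segmented once, then ICS (20-subtraction
#' route) and/or PSA are run, and one tidy row per image and method is
#' emitted. Per-image failures are caught, flagged in the `status` column,
#' and do not stop the batch.
#'
#' @param config Either a list with elements `images` (a list of records)
#'   and optional settings, or a path to a YAML/JSON file with the same
#'   structure. Each image record carries either `image` (an [image2d]) or
#'   `spec` (a [synthetic_spec()] or a plain list of its arguments), plus
#'   optional `id`, `group` and `time_point_h` metadata. Recognised
#'   settings: `methods` (default `c("ICS", "PSA")`), `n_subtractions`
#'   (default 20), `threshold` (default `"otsu"`), `profile`
#'   (default `"horizontal"`).
#' @return A data frame with one row per image x method: `id`, `group`,
#'   `time_point_h`, `method`, `n_ld`, `density_per_um2`,
#'   `mean_diameter_um`, `hypha_area_um2`, `g0`, `fwhm_pix`, `threshold`,
#'   `n_subtractions`, `status`.
#' @export
batch_run <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  methods <- config$methods %||% c("ICS", "PSA")
  n_sub <- config$n_subtractions %||% 20L
  thr <- config$threshold %||% "otsu"
  profile <- config$profile %||% "horizontal"

  rows <- list()
  for (i in seq_along(config$images)) {
    rec <- config$images[[i]]
    id <- rec$id %||% sprintf("image_%02d", i)
    group <- rec$group %||% NA_character_
    tp <- rec$time_point_h %||% NA_real_
    img <- rec$image
    if (is.null(img)) {
      spec <- rec$spec
      if (!inherits(spec, "synthetic_spec"))
        spec <- do.call(synthetic_spec, spec)
      img <- generate_hypha_image(spec)$image
    }
    mask <- tryCatch(estimate_hypha_mask(img), error = function(e) e)
    for (meth in methods) {
      row <- data.frame(id = id, group = group, time_point_h = tp,
                        method = meth, n_ld = NA_real_,
                        density_per_um2 = NA_real_,
                        mean_diameter_um = NA_real_,
                        hypha_area_um2 = NA_real_,
                        g0 = NA_real_, fwhm_pix = NA_real_,
                        threshold = NA_real_,
                        n_subtractions = if (meth == "ICS") n_sub else 0L,
                        status = "ok", stringsAsFactors = FALSE)
      if (inherits(mask, "error")) {
        row$status <- paste("segmentation failed:", conditionMessage(mask))
        rows[[length(rows) + 1L]] <- row
        next
      }
      row$hypha_area_um2 <- mask$area_um2
      q <- tryCatch({
        if (meth == "ICS")
          ics_quantify(img, mask = mask, n_subtractions = n_sub,
                       profile = profile)
        else
          psa_quantify(img, mask = mask, method = thr)
      }, error = function(e) e)
      if (inherits(q, "error")) {
        row$status <- conditionMessage(q)
      } else {
        row$n_ld <- q$n_ld
        row$density_per_um2 <- q$density_per_um2
        row$mean_diameter_um <- q$mean_diameter_um
        if (meth == "ICS") {
          row$g0 <- q$fit_params$g0
          row$fwhm_pix <- q$fit_params$fwhm_pix
        } else {
          row$threshold <- q$threshold
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
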