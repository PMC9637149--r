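#' Specification of a synthetic hypha image
#'
#' Bundles every parameter of the synthetic THG-image generator. The defaults
#' describe a realistic control-condition hypha: a capsule-shaped cell about
#' 10 um wide and 80 um long in a 1024 x 1024 frame at 0.1 um/pixel, a thin
#' bright chitinous wall along the boundary, a dim cytoplasm, and sparse
#' bright lipid droplets whose peak signal is 10x the wall signal. Droplet
#' diameters are drawn from a normal distribution truncated to
#' [0.2, 2.0] um. The point-spread function is a lateral Gaussian of
#' sigma = 0.3 um FWHM / 2.355 ~ 0.127 um.
#'
#' @param image_size_pix Side of the square frame; must be a power of two
#'   (>= 16).
#' @param pixel_size_um Micrometres per pixel.
#' @param hypha_length_um,hypha_width_um Capsule length (tip to tip) and
#'   width in micrometres; length must exceed width.
#' @param n_droplets Number of droplets to place.
#' @param diameter_mean_um,diameter_sd_um Mean and sd of the truncated-normal
#'   droplet diameter distribution (truncation at 0.2 and 2.0 um).
#' @param droplet_peak Peak droplet intensity before blurring (arbitrary
#'   units).
#' @param wall_peak Peak wall intensity; must be <= droplet_peak / 10 by
#'   default construction (droplets are ~10x brighter than the wall).
#' @param wall_thickness_um Wall ribbon thickness (FWHM of its Gaussian
#'   cross-profile), rendered just inside the capsule boundary.
#' @param cytoplasm_level Mean extra intensity of the cytoplasm inside the
#'   hypha. The interior of a living cell scatters slightly more than the
#'   surrounding medium, but far less than wall or droplets; the default
#'   keeps it within the noise band so that iterated background subtraction
#'   can fully erase it, as it does on real detector images.
#' @param psf_sigma_um Gaussian PSF sigma (lateral).
#' @param background_level Uniform background added everywhere.
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian read-noise sd (used when `noise = "gaussian"`).
#'   The default, 2% of the droplet peak, emulates analog photomultiplier
#'   detection after frame averaging.
#' @param noise_gain Photon gain for Poisson noise: the image is replaced by
#'   `rpois(gain * I) / gain` (used when `noise = "poisson"`).
#' @param seed Integer seed making the generated image reproducible.
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_hypha_image()], [generate_coloc_pair()]
#' @export
synthetic_spec <- function(image_size_pix = 1024L,
                           pixel_size_um = 0.1,
                           hypha_length_um = 80,
                           hypha_width_um = 10,
                           n_droplets = 12L,
                           diameter_mean_um = 0.74,
                           diameter_sd_um = 0.2,
                           droplet_peak = 1.0,
                           wall_peak = 0.1,
                           wall_thickness_um = 0.3,
                           cytoplasm_level = 0.01,
                           psf_sigma_um = 0.3 / 2.355,
                           background_level = 0.02,
                           noise = c("gaussian", "poisson", "none"),
                           noise_sd = 0.02,
                           noise_gain = 100,
                           seed = 1L) {
  noise <- match.arg(noise)
  spec <- structure(
    list(image_size_pix = as.integer(image_size_pix),
         pixel_size_um = pixel_size_um,
         hypha_length_um = hypha_length_um,
         hypha_width_um = hypha_width_um,
         n_droplets = as.integer(n_droplets),
         diameter_mean_um = diameter_mean_um,
         diameter_sd_um = diameter_sd_um,
         droplet_peak = droplet_peak,
         wall_peak = wall_peak,
         wall_thickness_um = wall_thickness_um,
         cytoplasm_level = cytoplasm_level,
         psf_sigma_um = psf_sigma_um,
         background_level = background_level,
         noise = noise,
         noise_sd = noise_sd,
         noise_gain = noise_gain,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  s <- spec$image_size_pix
  if (s < 16L || bitwAnd(s, s - 1L) != 0L)
    stop("image_size_pix must be a power of two >= 16")
  pos <- c("pixel_size_um", "hypha_length_um", "hypha_width_um",
           "diameter_mean_um", "diameter_sd_um", "droplet_peak",
           "wall_peak", "wall_thickness_um", "psf_sigma_um")
  for (f in pos)
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
      stop(sprintf("'%s' must be a positive number", f))
  if (spec$n_droplets < 0L) stop("n_droplets must be non-negative")
  if (spec$background_level < 0) stop("background_level must be >= 0")
  if (spec$cytoplasm_level < 0) stop("cytoplasm_level must be >= 0")
  if (spec$hypha_length_um <= spec$hypha_width_um)
    stop("hypha_length_um must exceed hypha_width_um")
  fov <- spec$image_size_pix * spec$pixel_size_um
  if (spec$hypha_length_um > 0.98 * fov)
    stop("hypha does not fit in the field of view")
  invisible(spec)
}

#' Area of a capsule (stadium) shape
#'
#' Closed-form area of a rectangle of length `length_um - width_um` and width
#' `width_um` capped by two semicircles of diameter `width_um`:
#' `W * (L - W) + pi * (W/2)^2`.
#'
#' @param length_um Tip-to-tip length in micrometres.
#' @param width_um Width in micrometres.
#' @return Area in square micrometres.
#' @examples
#' capsule_area(80, 10)  # 778.54 um^2
#' @export
capsule_area <- function(length_um, width_um) {
  width_um * (length_um - width_um) + pi * (width_um / 2)^2
}

# Distance (um) of every pixel centre to the capsule axis segment.
# The capsule is horizontal, centred in the frame; its axis runs from
# (cx - (L - W)/2, cy) to (cx + (L - W)/2, cy) in um.
.capsule_axis_dist <- function(n, pixel_size_um, length_um, width_um) {
  fov <- n * pixel_size_um
  cx <- fov / 2
  cy <- fov / 2
  half <- (length_um - width_um) / 2
  x <- ((seq_len(n)) - 0.5) * pixel_size_um        # columns
  y <- ((seq_len(n)) - 0.5) * pixel_size_um        # rows
  # clamp x to segment, then euclidean distance
  xc <- pmin(pmax(x, cx - half), cx + half)
  dx <- x - xc
  dy <- y - cy
  sqrt(outer(dy^2, dx^2, `+`))                      # rows = y, cols = x
}

# Distance of arbitrary (x, y) um points to the capsule axis.
.axis_dist_pts <- function(x, y, n, pixel_size_um, length_um, width_um) {
  fov <- n * pixel_size_um
  cx <- fov / 2; cy <- fov / 2
  half <- (length_um - width_um) / 2
  xc <- pmin(pmax(x, cx - half), cx + half)
  sqrt((x - xc)^2 + (y - cy)^2)
}

# Gaussian blur with a normalised kernel (periodic boundary via EBImage FFT
# filtering); conserves total intensity.
.gauss_blur <- function(m, sigma_pix) {
  if (sigma_pix <= 0) return(m)
  EBImage::gblur(m, sigma = sigma_pix)
}

# Area-weighted rasterization of a disk: per-pixel coverage approximated by
# clamp(r - dist_to_centre + 1/2, 0, 1), accurate to a few percent for the
# few-pixel radii used here.
.add_disk <- function(canvas, x_px, y_px, r_px, peak) {
  n_r <- nrow(canvas); n_c <- ncol(canvas)
  r0 <- max(1L, floor(y_px - r_px - 1)); r1 <- min(n_r, ceiling(y_px + r_px + 1))
  c0 <- max(1L, floor(x_px - r_px - 1)); c1 <- min(n_c, ceiling(x_px + r_px + 1))
  rows <- r0:r1; cols <- c0:c1
  dy2 <- ((rows - 0.5) - y_px)^2
  dx2 <- ((cols - 0.5) - x_px)^2
  d <- sqrt(outer(dy2, dx2, `+`))
  cov <- pmin(pmax(r_px - d + 0.5, 0), 1)
  canvas[rows, cols] <- pmax(canvas[rows, cols], peak * cov)
  canvas
}

.sample_diameters <- function(n, mean_um, sd_um, lo = 0.2, hi = 2.0) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    cand <- stats::rnorm(2L * (n - length(out)) + 8L, mean_um, sd_um)
    out <- c(out, cand[cand >= lo & cand <= hi])
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal diameter sampling failed")
  }
  out[seq_len(n)]
}

# Rejection-sample droplet centres uniformly in the capsule, keeping every
# centre at least one droplet radius away from the wall.
.sample_centers <- function(spec, diameters_um) {
  n <- length(diameters_um)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  fov <- spec$image_size_pix * spec$pixel_size_um
  cx <- fov / 2; cy <- fov / 2
  L <- spec$hypha_length_um; W <- spec$hypha_width_um
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    margin <- W / 2 - diameters_um[i] / 2
    if (margin <= 0)
      stop("droplet diameter exceeds hypha width; spec infeasible")
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      x <- stats::runif(1, cx - L / 2, cx + L / 2)
      y <- stats::runif(1, cy - W / 2, cy + W / 2)
      d <- .axis_dist_pts(x, y, spec$image_size_pix, spec$pixel_size_um, L, W)
      if (d <= margin) { xs[i] <- x; ys[i] <- y; ok <- TRUE; break }
    }
    if (!ok) stop("droplet placement failed: density too high for geometry")
  }
  cbind(x = xs, y = ys)
}

.apply_noise <- function(m, spec) {
  switch(spec$noise,
    none = m,
    gaussian = pmax(m + stats::rnorm(length(m), 0, spec$noise_sd), 0),
    poisson = {
      g <- spec$noise_gain
      matrix(stats::rpois(length(m), g * m) / g, nrow(m), ncol(m))
    })
}

# Run fn() under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic THG hypha image with ground truth
#'
#' Renders a capsule-shaped hypha centred in the frame: a wall ribbon with a
#' Gaussian cross-profile just inside the capsule boundary, a uniform dim
#' cytoplasm, and `n_droplets` bright disks at uniformly random in-hypha
#' positions (each centre kept at least one droplet radius from the wall).
#' The noise-free scene is convolved with a Gaussian PSF, a uniform
#' background is added everywhere, and noise is applied last. The same spec
#' (including its seed) always yields a bit-identical image.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{the generated [image2d];}
#'     \item{ground_truth}{a `ground_truth` list: `droplet_centers` (n x 2
#'       matrix, continuous pixel coordinates x = column, y = row),
#'       `droplet_diameters_um`, `hypha_mask` (a [hypha_mask] of the true
#'       capsule region), `wall_mask` (logical matrix of the wall ribbon),
#'       and `true_density_per_um2 = n_droplets / hypha area`.}
#'   }
#' @examples
#' sim <- generate_hypha_image(synthetic_spec(image_size_pix = 256,
#'   hypha_length_um = 20, hypha_width_um = 6, n_droplets = 4, seed = 7))
#' sim$ground_truth$true_density_per_um2
#' @export
generate_hypha_image <- function(spec) {
  validate_synthetic_spec(spec)
  .with_seed(spec$seed, function() .render_hypha(spec))
}

.render_hypha <- function(spec, centers = NULL, diameters = NULL,
                          with_wall = TRUE) {
  n <- spec$image_size_pix
  px <- spec$pixel_size_um
  L <- spec$hypha_length_um; W <- spec$hypha_width_um
  axis_d <- .capsule_axis_dist(n, px, L, W)
  inside <- axis_d <= W / 2

  if (is.null(diameters))
    diameters <- .sample_diameters(spec$n_droplets, spec$diameter_mean_um,
                                   spec$diameter_sd_um)
  if (is.null(centers)) centers <- .sample_centers(spec, diameters)

  # wall ribbon: Gaussian cross-profile centred just inside the boundary
  field <- matrix(0, n, n)
  if (with_wall && spec$wall_peak > 0) {
    ribbon_r <- W / 2 - spec$wall_thickness_um / 2
    sig_w <- spec$wall_thickness_um / 2.355
    field <- spec$wall_peak * exp(-(axis_d - ribbon_r)^2 / (2 * sig_w^2))
    field[axis_d > W / 2 + 2 * spec$wall_thickness_um] <- 0
  }
  field[inside] <- pmax(field[inside], spec$cytoplasm_level)

  if (nrow(centers) > 0) {
    r_px <- diameters / 2 / px
    for (i in seq_len(nrow(centers)))
      field <- .add_disk(field, centers[i, 1] / px, centers[i, 2] / px,
                         r_px[i], spec$droplet_peak)
  }

  blurred <- .gauss_blur(field, spec$psf_sigma_um / px)
  img <- pmax(blurred, 0) + spec$background_level
  img <- .apply_noise(img, spec)

  mask <- hypha_mask(inside, px)
  ribbon_r <- W / 2 - spec$wall_thickness_um / 2
  wall_mask <- abs(axis_d - ribbon_r) <= spec$wall_thickness_um / 2
  gt <- structure(
    list(droplet_centers = centers / px,
         droplet_diameters_um = diameters,
         hypha_mask = mask,
         wall_mask = wall_mask,
         true_density_per_um2 = nrow(centers) / mask$area_um2),
    class = "ground_truth"
  )
  list(image = image2d(img, px, "THG"), ground_truth = gt)
}

#' Generate a two-channel colocalization pair with known shared fraction
#'
#' Channel A is a standard synthetic THG image with all `n_droplets`
#' droplets. Channel B (a pseudo lipid-stain fluorescence channel, rendered
#' with the same wall and optics) keeps `round(shared_fraction * n_droplets)`
#' of channel A's droplets at identical positions and replaces the rest with
#' independently placed droplets, so both channels carry `n_droplets` in
#' total. Noise is drawn independently per channel.
#'
#' @param spec A [synthetic_spec()].
#' @param shared_fraction Fraction in \[0, 1\] of droplets common to both
#'   channels.
#' @param seed2 Seed for channel B's independent droplets and noise.
#' @return A list `channel_a`, `channel_b` (both [image2d]) and
#'   `ground_truth`, which extends the single-channel ground truth with
#'   `centers_b` (pixel coordinates of channel B droplets), `shared_indices`
#'   (rows of `droplet_centers` present in both channels) and `n_shared`.
#' @export
generate_coloc_pair <- function(spec, shared_fraction, seed2 = spec$seed + 1L) {
  validate_synthetic_spec(spec)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  sim_a <- generate_hypha_image(spec)
  gt <- sim_a$ground_truth
  n <- spec$n_droplets
  k <- round(shared_fraction * n)
  px <- spec$pixel_size_um

  shared_idx <- seq_len(k)   # placement order is already random
  b <- .with_seed(seed2, function() {
    d_new <- .sample_diameters(n - k, spec$diameter_mean_um,
                               spec$diameter_sd_um)
    c_new <- .sample_centers(spec, d_new)
    centers_b <- rbind(gt$droplet_centers[shared_idx, , drop = FALSE] * px,
                       c_new)
    diam_b <- c(gt$droplet_diameters_um[shared_idx], d_new)
    sim_b <- .render_hypha(spec, centers = centers_b, diameters = diam_b)
    sim_b
  })
  img_b <- b$image
  img_b$channel <- "TPEF"

  gt$centers_b <- b$ground_truth$droplet_centers
  gt$shared_indices <- shared_idx
  gt$n_shared <- k
  list(channel_a = sim_a$image, channel_b = img_b, ground_truth = gt)
}

#' Write a simulated image (or pair) with its ground-truth sidecar
#'
#' Saves the image(s) as a multi-page float TIFF and the ground truth
#' (droplet centres in pixels, diameters in um, the spec echo) as JSON next
#' to it.
#'
#' @param sim Result of [generate_hypha_image()] or [generate_coloc_pair()].
#' @param spec The [synthetic_spec()] used to generate it.
#' @param dir Output directory (created if missing).
#' @param stem File stem for `<stem>.tif` and `<stem>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_simulation <- function(sim, spec, dir, stem = "simulated_hypha") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tif"))
  json <- file.path(dir, paste0(stem, ".json"))
  imgs <- if (!is.null(sim$image)) list(sim$image)
          else list(sim$channel_a, sim$channel_b)
  write_image2d(imgs, tif)
  gt <- sim$ground_truth
  side <- list(
    spec = unclass(spec),
    droplet_centers_px = unname(gt$droplet_centers),
    droplet_diameters_um = gt$droplet_diameters_um,
    hypha_area_um2 = gt$hypha_mask$area_um2,
    true_density_per_um2 = gt$true_density_per_um2
  )
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, json))
}
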