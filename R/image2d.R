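#' Construct a 2D intensity image with physical pixel size
#'
#' The basic container used throughout the package: a matrix of non-negative
#' intensities (arbitrary units) with the physical pixel size in micrometres
#' per pixel and a free-text channel label (e.g. `"THG"`, `"TPEF"`).
#' The matrix is oriented rows = y, columns = x; continuous pixel coordinates
#' place the centre of pixel `(row, col)` at `(x, y) = (col - 0.5, row - 0.5)`
#' pixel units.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Positive scalar, micrometres per pixel (isotropic).
#' @param channel Character scalar labelling the acquisition channel.
#' @return An object of class `image2d`: a list with elements `pixels`,
#'   `pixel_size_um` and `channel`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8), pixel_size_um = 0.1)
#' dim(img)
#' @export
image2d <- function(pixels, pixel_size_um, channel = "THG") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("'pixels' must be finite everywhere")
  if (any(pixels < 0))
    stop("'pixels' must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a positive scalar")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = as.character(channel)[1L]),
    class = "image2d"
  )
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image2d> %d x %d px, %.4g um/px, channel '%s'\n",
              d[1], d[2], x$pixel_size_um, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "image2d")

assert_image2d <- function(x, arg = deparse(substitute(x))) {
  if (!is_image2d(x)) stop(sprintf("'%s' must be an image2d object", arg))
  invisible(x)
}

#' Construct a hypha mask
#'
#' A boolean grid marking in-hypha pixels, together with the hypha area used
#' to normalise droplet counts (area = number of TRUE pixels times the pixel
#' area).
#'
#' @param mask Logical matrix, `TRUE` inside the hypha.
#' @param pixel_size_um Positive scalar, micrometres per pixel.
#' @return An object of class `hypha_mask` with elements `mask`,
#'   `area_um2` and `pixel_size_um`.
#' @export
hypha_mask <- function(mask, pixel_size_um) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  structure(
    list(mask = mask,
         area_um2 = sum(mask) * pixel_size_um^2,
         pixel_size_um = pixel_size_um),
    class = "hypha_mask"
  )
}

#' @export
print.hypha_mask <- function(x, ...) {
  cat(sprintf("<hypha_mask> %d x %d px, %d in-mask px, area %.1f um^2\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$area_um2))
  invisible(x)
}

#' Read a single-channel image from a TIFF file
#'
#' Reads one plane of a TIFF file as an [image2d]. Integer TIFFs (8/16-bit)
#' are rescaled back to raw counts from the unit-range representation the
#' reader produces; float TIFFs are read as stored. The pixel size is not
#' recorded in plain TIFF tags, so it must be supplied.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Micrometres per pixel.
#' @param channel Channel label to attach.
#' @param plane Which plane of a multi-page TIFF to read (default 1).
#' @return An [image2d].
#' @export
read_image2d <- function(path, pixel_size_um, channel = "THG", plane = 1L) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (plane > length(planes)) stop("requested plane not present in TIFF")
  m <- planes[[plane]]
  info <- attr(m, "info")
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # collapse RGB-style storage
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else NULL
  fmt <- if (!is.null(info$sample.format)) info$sample.format else "uint"
  if (!is.null(bits) && identical(fmt, "uint"))
    m <- m * (2^bits - 1)                     # back to raw counts
  image2d(pmax(matrix(as.numeric(m), nrow(m), ncol(m)), 0),
          pixel_size_um, channel)
}

#' Write one or two images to a (multi-page) 32-bit float TIFF
#'
#' @param image An [image2d], or a list of them (written as pages).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image2d <- function(image, path) {
  imgs <- if (is_image2d(image)) list(image) else image
  mats <- lapply(imgs, function(im) {
    assert_image2d(im)
    m <- im$pixels
    # writeTIFF float expects [0,1]-ish but stores float32 verbatim when
    # reduce = FALSE; normalise defensively to the stored dynamic range.
    m
  })
  mx <- max(vapply(mats, max, 0), 1e-12)
  mats <- lapply(mats, function(m) m / mx)
  tiff::writeTIFF(mats, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
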