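#' Single-channel detector image
#'
#' The basic unit all arithmetic operates on: a 2-D grid of non-negative
#' detector counts together with the full-scale count of the detector
#' (`detector_max`, e.g. 255, 4095 or 65535). Intensities are kept as stored
#' counts; the 10%/90% exposure thresholds used elsewhere in the pipeline are
#' fractions of `detector_max`, not of the observed maximum. `detector_max`
#' is supplied by the user rather than inferred from the container bit depth,
#' because 12-bit data is commonly stored in 16-bit TIFFs.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param detector_max Full-scale detector count (> 0).
#' @param allow_overrange Permit values above `detector_max` (used internally
#'   for unclipped shading-corrected images).
#' @return An object of class `fret_image`: a list with elements `pixels`
#'   and `detector_max`.
#' @export
image2d <- function(pixels, detector_max, allow_overrange = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stopf("`pixels` contains non-finite values")
  if (any(pixels < 0))
    stopf("negative pixel values are not valid detector counts")
  if (!is.numeric(detector_max) || length(detector_max) != 1L || detector_max <= 0)
    stopf("`detector_max` must be a single positive number")
  if (!allow_overrange && max(pixels) > detector_max)
    stopf("pixel values exceed detector_max (%g > %g)", max(pixels), detector_max)
  structure(
    list(pixels = pixels, detector_max = as.numeric(detector_max)),
    class = "fret_image"
  )
}

#' @export
dim.fret_image <- function(x) dim(x$pixels)

#' @export
print.fret_image <- function(x, ...) {
  cat(sprintf("<fret_image> %d x %d, detector_max = %g, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$detector_max,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a fret_image or a bare matrix where only the counts matter.
as_pixels <- function(x) {
  if (inherits(x, "fret_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stopf("expected a fret_image or numeric matrix")
}

#' Read one grayscale channel from a single-plane TIFF
#'
#' Values are returned exactly as stored (no rescaling). Multi-channel (RGB)
#' images and values above `detector_max` are rejected.
#'
#' @param path Path to an 8- or 16-bit single-plane grayscale TIFF.
#' @param detector_max Full-scale detector count; must be at least the largest
#'   stored value.
#' @return A [image2d()] object.
#' @export
read_channel_image <- function(path, detector_max) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L)
    stopf("%s is a multi-channel (RGB) image; a single grayscale plane is required", path)
  px <- matrix(as.numeric(img), nrow = nrow(img), ncol = ncol(img))
  if (max(px) > detector_max)
    stopf("%s: stored maximum %g exceeds detector_max %g", path, max(px), detector_max)
  image2d(px, detector_max)
}

#' Write one channel as a lossless grayscale TIFF
#'
#' Integer counts round-trip exactly through [read_channel_image()]. The
#' container is 8-bit when `detector_max` fits in a byte, 16-bit otherwise.
#'
#' @param image A [image2d()] object with integer-valued counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(image, path) {
  px <- as_pixels(image)
  if (any(px != round_half_up(px)))
    stopf("channel TIFFs store integer counts; round or quantize first")
  bits <- if (image$detector_max <= 255) 8L else 16L
  scale <- 2^bits - 1
  if (max(px) > scale)
    stopf("counts exceed the %d-bit container", bits)
  tiff::writeTIFF(px / scale, path, bits.per.sample = bits)
  invisible(path)
}

#' Co-registered three-channel FRET acquisition
#'
#' Bundles the DD (donor excitation / donor emission), DA (donor excitation /
#' acceptor emission, the FRET channel) and AA (acceptor excitation / acceptor
#' emission) images of one acquisition. Channels must share shape and
#' detector range and are assumed co-registered; registration itself is out
#' of scope.
#'
#' @param dd,da,aa [image2d()] objects.
#' @param pixel_size_nm Optional physical pixel size in nanometres.
#' @param label Free-text identifier.
#' @return An object of class `fret_acquisition`.
#' @export
fret_acquisition <- function(dd, da, aa, pixel_size_nm = NULL, label = "") {
  chans <- list(dd = dd, da = da, aa = aa)
  for (nm in names(chans))
    if (!inherits(chans[[nm]], "fret_image"))
      stopf("channel %s must be a fret_image", toupper(nm))
  d0 <- dim(dd$pixels)
  for (nm in c("da", "aa")) {
    di <- dim(chans[[nm]]$pixels)
    if (!identical(d0, di))
      stopf("channel shape mismatch: DD is %dx%d but %s is %dx%d",
            d0[1], d0[2], toupper(nm), di[1], di[2])
  }
  if (da$detector_max != dd$detector_max || aa$detector_max != dd$detector_max)
    stopf("all channels must share one detector_max")
  structure(
    list(dd = dd, da = da, aa = aa,
         pixel_size_nm = pixel_size_nm, label = label),
    class = "fret_acquisition"
  )
}

#' @export
print.fret_acquisition <- function(x, ...) {
  cat(sprintf("<fret_acquisition> '%s': %d x %d, detector_max = %g\n",
              x$label, nrow(x$dd$pixels), ncol(x$dd$pixels), x$dd$detector_max))
  invisible(x)
}

#' Load a DD/DA/AA triplet from three TIFF files
#'
#' @param dd_path,da_path,aa_path Paths to the three channel TIFFs.
#' @param detector_max Shared full-scale detector count.
#' @param label Free-text identifier.
#' @return A [fret_acquisition()].
#' @export
load_acquisition <- function(dd_path, da_path, aa_path, detector_max, label = "") {
  fret_acquisition(
    dd = read_channel_image(dd_path, detector_max),
    da = read_channel_image(da_path, detector_max),
    aa = read_channel_image(aa_path, detector_max),
    label = label
  )
}

# Jet-style colormap used for all pseudocolor output: black-blue through
# cyan, green, yellow to red. v in [0,1] -> n x 3 matrix of [0,1] RGB.
pseudocolor_rgb <- function(v) {
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  cbind(
    r = clamp01(1.5 - abs(4 * v - 3)),
    g = clamp01(1.5 - abs(4 * v - 2)),
    b = clamp01(1.5 - abs(4 * v - 1))
  )
}

#' Write a result map as 16-bit grayscale TIFF or pseudocolor PNG
#'
#' Grayscale mode linearly maps `value_range` to the full 16-bit scale
#' (rounding half up); pseudocolor mode maps the same normalized values
#' through a fixed jet-style colormap (blue = low, red = high) into an 8-bit
#' PNG. Non-finite values are only permitted on pixels an accompanying mask
#' marks as unevaluated; they are written as 0 (grayscale) or black (PNG).
#'
#' @param path Output path.
#' @param values Numeric matrix (e.g. net FRET or efficiency).
#' @param mode `"grayscale"` or `"pseudocolor"`.
#' @param value_range Length-2 numeric giving the values mapped to the ends
#'   of the output scale.
#' @param mask Optional logical matrix, `TRUE` where the pixel was evaluated.
#' @return `path`, invisibly.
#' @export
write_map <- function(path, values, mode = c("grayscale", "pseudocolor"),
                      value_range = NULL, mask = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  bad <- !is.finite(values)
  if (any(bad)) {
    if (is.null(mask))
      stopf("map contains non-finite values but no mask marks them unevaluated")
    if (any(bad & mask))
      stopf("non-finite values on pixels the mask marks as evaluated")
  }
  if (is.null(value_range)) value_range <- range(values[!bad])
  if (value_range[2] <= value_range[1])
    stopf("value_range must be increasing")
  norm <- (values - value_range[1]) / (value_range[2] - value_range[1])
  norm <- pmin(pmax(norm, 0), 1)
  norm[bad] <- 0
  if (mode == "grayscale") {
    counts <- round_half_up(norm * 65535)
    tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  } else {
    rgbm <- pseudocolor_rgb(as.vector(norm))
    rgbm[as.vector(bad), ] <- 0
    arr <- array(rgbm, dim = c(nrow(values), ncol(values), 3L))
    png::writePNG(arr, path)
  }
  invisible(path)
}
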