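#' Flat-field shading model
#'
#' Wraps a shading reference image Y and its mean M for the correction
#' B' = B * (M / Y). Pixels of Y below 1 count are floored to 1 at correction
#' time to avoid unbounded amplification; their number is recorded here.
#'
#' @param y A [image2d()] shading reference image.
#' @return Object of class `fret_shading` with elements `y`, `m` (mean of Y)
#'   and `n_floored` (pixels of Y below 1 count).
#' @export
shading_model <- function(y) {
  if (!inherits(y, "fret_image")) stopf("`y` must be a fret_image")
  m <- mean(y$pixels)
  if (m <= 0) stopf("shading reference has non-positive mean")
  structure(list(y = y, m = m, n_floored = sum(y$pixels < 1)),
            class = "fret_shading")
}

#' Apply flat-field (shading) correction
#'
#' Computes B'(p) = B(p) * M / max(Y(p), 1) per pixel. The output is returned
#' unclipped (corrected values may exceed `detector_max`; their count is
#' attached as attribute `n_overrange` and a warning is raised if nonzero).
#'
#' @param b A [image2d()] to correct.
#' @param shading A [shading_model()] of identical shape.
#' @return Corrected [image2d()] (real-valued, unclipped).
#' @export
shading_correct <- function(b, shading) {
  if (!inherits(shading, "fret_shading")) stopf("`shading` must be a fret_shading")
  bp <- as_pixels(b)
  yp <- shading$y$pixels
  if (!identical(dim(bp), dim(yp)))
    stopf("image (%dx%d) and shading reference (%dx%d) differ in shape",
          nrow(bp), ncol(bp), nrow(yp), ncol(yp))
  out <- bp * shading$m / pmax(yp, 1)
  n_over <- sum(out > b$detector_max)
  if (n_over > 0)
    warning(sprintf("%d corrected pixels exceed detector_max (left unclipped)", n_over),
            call. = FALSE)
  res <- image2d(out, b$detector_max, allow_overrange = TRUE)
  attr(res, "n_overrange") <- n_over
  res
}

#' Estimate the background level from random squares
#'
#' Places `n_squares` axis-aligned squares of side `square_size` uniformly at
#' random (with replacement) over all positions where the square fits
#' entirely inside the image, and takes the square with the lowest mean count
#' as background. Ties on the minimum mean go to the first-drawn square. The
#' draw is reproducible from `seed`; all candidate squares are returned so
#' the selection can be re-checked by enumeration.
#'
#' @param image A [image2d()] at least `square_size` in both dimensions.
#' @param n_squares Number of candidate squares (default 30).
#' @param square_size Side length in pixels (default 15).
#' @param seed RNG seed used for the placement.
#' @return Object of class `fret_background`: `level` (mean count of the
#'   selected square), `square_origin` (top-left `(row, col)`, 1-based),
#'   `n_squares`, `square_size`, `seed` and a `candidates` data frame with
#'   one row per drawn square.
#' @export
estimate_background <- function(image, n_squares = 30L, square_size = 15L, seed = 1L) {
  px <- as_pixels(image)
  h <- nrow(px); w <- ncol(px); s <- as.integer(square_size)
  if (n_squares < 1L) stopf("n_squares must be at least 1")
  if (h < s || w < s)
    stopf("image (%dx%d) is smaller than the %dx%d background square", h, w, s, s)
  draws <- with_seed(seed, {
    list(row = sample.int(h - s + 1L, n_squares, replace = TRUE),
         col = sample.int(w - s + 1L, n_squares, replace = TRUE))
  })
  means <- vapply(seq_len(n_squares), function(i) {
    mean(px[draws$row[i]:(draws$row[i] + s - 1L),
            draws$col[i]:(draws$col[i] + s - 1L)])
  }, numeric(1))
  best <- which.min(means)  # first minimum wins ties
  structure(
    list(level = means[best],
         square_origin = c(row = draws$row[best], col = draws$col[best]),
         n_squares = as.integer(n_squares), square_size = s,
         seed = as.integer(seed),
         candidates = data.frame(row = draws$row, col = draws$col, mean = means)),
    class = "fret_background"
  )
}

#' Subtract a background level, flooring at zero
#'
#' @param image A [image2d()].
#' @param background A [estimate_background()] result or a single number.
#' @return [image2d()] with `max(value - level, 0)` per pixel.
#' @export
subtract_background <- function(image, background) {
  level <- if (inherits(background, "fret_background")) background$level else background
  if (!is.finite(level)) stopf("background level must be finite")
  image2d(pmax(as_pixels(image) - level, 0), image$detector_max)
}

# Shared ratio-of-sums bleed-through estimator: numerator / denominator
# summed over pixels whose reference channel lies inside the valid fraction
# of the detector dynamic range.
bt_ratio_of_sums <- function(reference, numerator, detector_max,
                             valid_low, valid_high, floor, what) {
  if (valid_low >= valid_high || valid_low < 0 || valid_high > 1)
    stopf("valid window must satisfy 0 <= valid_low < valid_high <= 1")
  lo <- max(valid_low * detector_max, floor)
  sel <- reference >= lo & reference <= valid_high * detector_max
  n <- sum(sel)
  if (n == 0L)
    stopf("no %s pixels inside the valid dynamic-range window [%g%%, %g%%]",
          what, 100 * valid_low, 100 * valid_high)
  denom <- sum(reference[sel])
  if (denom == 0) stopf("selected %s pixels sum to zero", what)
  list(bt = sum(numerator[sel]) / denom, n_pixels = n)
}

#' Calibrate donor bleed-through from a donor-only acquisition
#'
#' Donor bleed-through is the fraction of donor emission leaking into the
#' FRET (DA) channel: in cells expressing only the donor construct,
#' `bt_donor = sum(DA) / sum(DD)` over pixels whose DD signal lies within the
#' valid fraction of the detector dynamic range (defaults 10%-90%, endpoints
#' inclusive). The ratio-of-sums estimator is used, not the mean of per-pixel
#' ratios. Channels must already be background-subtracted (and
#' shading-corrected if a shading model applies).
#'
#' @param donor_only A [fret_acquisition()] from donor-only control cells.
#' @param valid_low,valid_high Valid window as fractions of `detector_max`.
#' @param floor Optional minimum DD intensity (autofluorescence floor,
#'   detector counts) applied in addition to the window; default 0 (off).
#' @return List with `bt_donor` and `n_pixels`.
#' @export
calibrate_donor_bt <- function(donor_only, valid_low = 0.10, valid_high = 0.90,
                               floor = 0) {
  r <- bt_ratio_of_sums(donor_only$dd$pixels, donor_only$da$pixels,
                        donor_only$dd$detector_max, valid_low, valid_high,
                        floor, "donor (DD)")
  list(bt_donor = r$bt, n_pixels = r$n_pixels)
}

#' Calibrate acceptor bleed-through from an acceptor-only acquisition
#'
#' Acceptor bleed-through is the fraction of the DA signal caused by direct
#' excitation of the acceptor with the donor laser:
#' `bt_acceptor = sum(DA) / sum(AA)` over pixels whose AA signal lies within
#' the valid dynamic-range window.
#'
#' @inheritParams calibrate_donor_bt
#' @param acceptor_only A [fret_acquisition()] from acceptor-only controls.
#' @param floor Optional minimum AA intensity (counts); default 0.
#' @return List with `bt_acceptor` and `n_pixels`.
#' @export
calibrate_acceptor_bt <- function(acceptor_only, valid_low = 0.10,
                                  valid_high = 0.90, floor = 0) {
  r <- bt_ratio_of_sums(acceptor_only$aa$pixels, acceptor_only$da$pixels,
                        acceptor_only$aa$detector_max, valid_low, valid_high,
                        floor, "acceptor (AA)")
  list(bt_acceptor = r$bt, n_pixels = r$n_pixels)
}

#' Bleed-through calibration container
#'
#' @param bt_donor,bt_acceptor Dimensionless crosstalk fractions (>= 0,
#'   typically < 1).
#' @param n_pixels_donor,n_pixels_acceptor Pixels used for each estimate.
#' @param valid_low,valid_high Fractional dynamic-range window used.
#' @return Object of class `fret_bleedthrough`.
#' @export
bleed_through <- function(bt_donor, bt_acceptor,
                          n_pixels_donor = NA_integer_,
                          n_pixels_acceptor = NA_integer_,
                          valid_low = 0.10, valid_high = 0.90) {
  if (bt_donor < 0 || bt_acceptor < 0)
    stopf("bleed-through fractions must be non-negative")
  structure(
    list(bt_donor = bt_donor, bt_acceptor = bt_acceptor,
         n_pixels_donor = n_pixels_donor, n_pixels_acceptor = n_pixels_acceptor,
         valid_low = valid_low, valid_high = valid_high),
    class = "fret_bleedthrough"
  )
}

#' @export
print.fret_bleedthrough <- function(x, ...) {
  cat(sprintf("<fret_bleedthrough> donor %.4f (n=%s), acceptor %.4f (n=%s), window [%g%%, %g%%]\n",
              x$bt_donor, format(x$n_pixels_donor), x$bt_acceptor,
              format(x$n_pixels_acceptor), 100 * x$valid_low, 100 * x$valid_high))
  invisible(x)
}

#' Serialize / restore a bleed-through calibration as JSON
#'
#' The JSON file is the contract between the `calibrate` and `analyze` steps
#' of the command-line workflow.
#'
#' @param bt A [bleed_through()] object.
#' @param path Output / input path.
#' @param background_seed Seed used for the background squares, recorded for
#'   reproducibility.
#' @return `path` invisibly; `read_calibration()` returns the
#'   [bleed_through()] object.
#' @export
write_calibration <- function(bt, path, background_seed = NA_integer_) {
  payload <- list(
    bt_donor = bt$bt_donor, bt_acceptor = bt$bt_acceptor,
    valid_low = bt$valid_low, valid_high = bt$valid_high,
    n_pixels_donor = bt$n_pixels_donor, n_pixels_acceptor = bt$n_pixels_acceptor,
    background_seed = background_seed,
    software_version = as.character(utils::packageVersion("fretmap"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stopf("calibration file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("bt_donor", "bt_acceptor", "valid_low", "valid_high"))
    if (is.null(j[[f]]) || !is.numeric(j[[f]]))
      stopf("calibration file %s lacks numeric field '%s'", path, f)
  bleed_through(j$bt_donor, j$bt_acceptor,
                j$n_pixels_donor %||% NA_integer_,
                j$n_pixels_acceptor %||% NA_integer_,
                j$valid_low, j$valid_high)
}
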