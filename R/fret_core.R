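#' Build the dynamic-range evaluability masks
#'
#' A pixel is underexposed if its DD or AA signal falls below
#' `low_frac * detector_max` (or an optional per-channel autofluorescence
#' floor), overexposed if DD or AA exceeds `high_frac * detector_max`, and
#' evaluable only if it is neither: FRET is quantified only where donor and
#' acceptor are co-localized within the reliable part of the detector
#' dynamic range.
#'
#' @param acq A [fret_acquisition()] (background-subtracted channels).
#' @param low_frac,high_frac Fractional thresholds of `detector_max`
#'   (defaults 0.10 and 0.90).
#' @param floor_dd,floor_aa Optional minimum intensities (detector counts)
#'   treated as additional underexposure criteria; default 0 (off).
#' @return Object of class `fret_masks` with logical matrices `underexposed`,
#'   `overexposed`, `evaluable` and the thresholds used.
#' @export
build_masks <- function(acq, low_frac = 0.10, high_frac = 0.90,
                        floor_dd = 0, floor_aa = 0) {
  if (low_frac >= high_frac || low_frac < 0 || high_frac > 1)
    stopf("need 0 <= low_frac < high_frac <= 1")
  dmax <- acq$dd$detector_max
  dd <- acq$dd$pixels; aa <- acq$aa$pixels
  under <- dd < low_frac * dmax | aa < low_frac * dmax |
    dd < floor_dd | aa < floor_aa
  over <- dd > high_frac * dmax | aa > high_frac * dmax
  structure(
    list(underexposed = under, overexposed = over,
         evaluable = !under & !over,
         low_frac = low_frac, high_frac = high_frac),
    class = "fret_masks"
  )
}

#' Per-pixel net FRET
#'
#' Subtracts both bleed-through contributions from the FRET channel:
#' `nF = DA - DD * bt_donor - AA * bt_acceptor`. Channels must already be
#' background-subtracted (and shading-corrected where a shading reference
#' was acquired). Negative values are preserved; masking happens later.
#'
#' @param acq A [fret_acquisition()].
#' @param bt A [bleed_through()] calibration.
#' @return Numeric matrix of net-FRET counts.
#' @export
compute_net_fret <- function(acq, bt) {
  if (!inherits(bt, "fret_bleedthrough")) stopf("`bt` must be a fret_bleedthrough")
  acq$da$pixels - acq$dd$pixels * bt$bt_donor - acq$aa$pixels * bt$bt_acceptor
}

#' Per-pixel FRET efficiency
#'
#' Computes `E = nF / (nF + alpha * DD)` on pixels that are evaluable and
#' have `nF > 0` and `DD > 0`; every other pixel is `NA` (unevaluated).
#' `alpha` is the quantum-yield/detection-efficiency ratio of the acceptor
#' and donor channels and defaults to 1. Pixels with `nF <= 0` are reported
#' as unevaluated rather than clamped to 0, so negative crosstalk noise does
#' not bias downstream curve means.
#'
#' @param nf Net-FRET matrix from [compute_net_fret()].
#' @param dd DD channel ([image2d()] or matrix).
#' @param masks A [build_masks()] result.
#' @param alpha Detection-correction factor (> 0, default 1).
#' @return Numeric matrix; values in (0, 1) where defined, `NA` elsewhere.
#' @export
compute_efficiency <- function(nf, dd, masks, alpha = 1) {
  if (alpha <= 0) stopf("alpha must be positive")
  ddp <- as_pixels(dd)
  if (!identical(dim(nf), dim(ddp)) || !identical(dim(nf), dim(masks$evaluable)))
    stopf("nf, dd and masks must share one shape")
  ok <- masks$evaluable & nf > 0 & ddp > 0
  e <- matrix(NA_real_, nrow(nf), ncol(nf))
  e[ok] <- nf[ok] / (nf[ok] + alpha * ddp[ok])
  e
}

#' Per-pixel acceptor/donor ratio
#'
#' `ratio = AA / DD` where `DD > 0`, `NA` elsewhere. AA and DD fluorescence
#' serve as proxies for acceptor and donor abundance; no gain normalization
#' is applied.
#'
#' @param acq A [fret_acquisition()] (background-subtracted).
#' @return Numeric matrix of ratios.
#' @export
compute_ratio <- function(acq) {
  dd <- acq$dd$pixels
  r <- matrix(NA_real_, nrow(dd), ncol(dd))
  pos <- dd > 0
  r[pos] <- acq$aa$pixels[pos] / dd[pos]
  r
}

#' Full per-pixel map set for one acquisition
#'
#' Convenience wrapper running masking, net FRET, efficiency and ratio in
#' one call.
#'
#' @inheritParams build_masks
#' @inheritParams compute_net_fret
#' @param alpha Detection-correction factor passed to [compute_efficiency()].
#' @return Object of class `fret_maps`: `nf`, `efficiency`, `ratio`, `masks`,
#'   `alpha` and `n_nonpositive_nf` (evaluable pixels dropped for `nF <= 0`).
#' @export
fret_maps <- function(acq, bt, low_frac = 0.10, high_frac = 0.90, alpha = 1,
                      floor_dd = 0, floor_aa = 0) {
  masks <- build_masks(acq, low_frac, high_frac, floor_dd, floor_aa)
  nf <- compute_net_fret(acq, bt)
  eff <- compute_efficiency(nf, acq$dd, masks, alpha)
  structure(
    list(nf = nf, efficiency = eff, ratio = compute_ratio(acq),
         masks = masks, alpha = alpha,
         n_nonpositive_nf = sum(masks$evaluable & nf <= 0)),
    class = "fret_maps"
  )
}

#' @export
print.fret_maps <- function(x, ...) {
  n_eval <- sum(x$masks$evaluable)
  cat(sprintf("<fret_maps> %d x %d, %d evaluable pixels (%d dropped for nF <= 0)\n",
              nrow(x$nf), ncol(x$nf), n_eval, x$n_nonpositive_nf))
  if (any(!is.na(x$efficiency)))
    cat(sprintf("  efficiency: median %.4f over %d pixels\n",
                stats::median(x$efficiency, na.rm = TRUE), sum(!is.na(x$efficiency))))
  invisible(x)
}

#' Write the three-color mask overview image
#'
#' Blue marks underexposed pixels, red overexposed, green the evaluable
#' co-localized area.
#'
#' @param masks A [build_masks()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_overview <- function(masks, path) {
  h <- nrow(masks$evaluable); w <- ncol(masks$evaluable)
  arr <- array(0, dim = c(h, w, 3L))
  arr[, , 1][masks$overexposed] <- 1   # red
  arr[, , 2][masks$evaluable] <- 1     # green
  arr[, , 3][masks$underexposed & !masks$overexposed] <- 1  # blue
  png::writePNG(arr, path)
  invisible(path)
}
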