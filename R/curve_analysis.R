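#' Logarithmically spaced ratio-bin edges
#'
#' The acceptor/donor ratio spans orders of magnitude across transfection
#' levels, so the curve defaults to log-spaced bins.
#'
#' @param from,to Positive range limits.
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
log_spaced_edges <- function(from, to, n_bins) {
  if (from <= 0 || to <= from) stopf("need 0 < from < to")
  exp(seq(log(from), log(to), length.out = n_bins + 1L))
}

# Histogram efficiencies on [0, 1] in bins of `width`; returns counts and
# centers. The small epsilon keeps values like 0.2 (not exactly
# representable) in the bin whose lower edge they nominally sit on.
e_histogram <- function(e, width) {
  n_bins <- as.integer(ceiling(1 / width))
  idx <- pmin(as.integer(floor(e / width + 1e-9)), n_bins - 1L) + 1L
  list(counts = tabulate(idx, n_bins),
       centers = (seq_len(n_bins) - 0.5) * width)
}

#' Frequency-weighted efficiency vs acceptor/donor-ratio curve
#'
#' For each ratio bin the pixel efficiencies are histogrammed in bins of
#' width `e_hist_bin_width` over `[0, 1]`; histogram bins whose count is
#' below `min_freq_frac` times the modal bin count are discarded, and the
#' bin's efficiency is the count-weighted mean of the retained bin centers.
#' Rare outlier efficiencies are thereby excluded instead of applying a hard
#' threshold cut-off (which merely shifts the mean toward the surviving
#' extremes). The plain per-bin mean is kept alongside for diagnostics.
#'
#' @param efficiency Efficiency matrix from [compute_efficiency()].
#' @param ratio Ratio matrix from [compute_ratio()].
#' @param masks Optional [build_masks()] result restricting the pixel set.
#' @param ratio_edges Strictly increasing bin edges (see
#'   [log_spaced_edges()]).
#' @param e_hist_bin_width Width of the efficiency histogram bins.
#' @param min_freq_frac Minimum relative frequency (fraction of the modal
#'   bin count) for an efficiency-histogram bin to be retained; 0 disables
#'   the filtering.
#' @return Object of class `fret_ratio_curve`: a data frame with columns
#'   `ratio_low`, `ratio_high`, `ratio_center` (geometric center),
#'   `weighted_mean_e`, `raw_mean_e`, `n_pixels`, with the weighting
#'   parameters as attributes.
#' @export
build_ratio_curve <- function(efficiency, ratio, masks = NULL, ratio_edges,
                              e_hist_bin_width = 0.01, min_freq_frac = 0.05) {
  if (any(diff(ratio_edges) <= 0)) stopf("ratio_edges must be strictly increasing")
  sel <- is.finite(efficiency) & is.finite(ratio)
  if (!is.null(masks)) sel <- sel & masks$evaluable
  if (!any(sel)) stopf("no evaluable pixels with defined efficiency and ratio")
  e <- efficiency[sel]; rho <- ratio[sel]
  n_bins <- length(ratio_edges) - 1L
  bin <- findInterval(rho, ratio_edges, rightmost.closed = TRUE)
  out <- data.frame(
    ratio_low = ratio_edges[seq_len(n_bins)],
    ratio_high = ratio_edges[-1L],
    ratio_center = sqrt(pmax(ratio_edges[seq_len(n_bins)], .Machine$double.xmin) *
                          ratio_edges[-1L]),
    weighted_mean_e = NA_real_, raw_mean_e = NA_real_, n_pixels = 0L
  )
  for (i in seq_len(n_bins)) {
    ei <- e[bin == i]
    if (!length(ei)) next
    hist <- e_histogram(ei, e_hist_bin_width)
    keep <- hist$counts > 0 & hist$counts >= min_freq_frac * max(hist$counts)
    out$weighted_mean_e[i] <-
      sum(hist$centers[keep] * hist$counts[keep]) / sum(hist$counts[keep])
    out$raw_mean_e[i] <- mean(ei)
    out$n_pixels[i] <- length(ei)
  }
  structure(out, class = c("fret_ratio_curve", "data.frame"),
            e_hist_bin_width = e_hist_bin_width, min_freq_frac = min_freq_frac)
}

#' Sigmoid efficiency model in the acceptor/donor ratio
#'
#' Hill-form sigmoid `E(rho) = e_max / (1 + (k / rho)^h)`: monotone, bounded
#' by the plateau `e_max`, with `k` the ratio at half-maximum and `h` the
#' slope exponent.
#'
#' @param rho Acceptor/donor ratio (positive).
#' @param e_max Plateau efficiency.
#' @param k Ratio at half-maximum (> 0).
#' @param h Slope exponent (> 0).
#' @return Efficiency values.
#' @export
sigmoid_efficiency <- function(rho, e_max, k, h) e_max / (1 + (k / rho)^h)

#' Fit the sigmoid efficiency curve
#'
#' Weighted least squares (weights = pixels per bin) of the Hill sigmoid to
#' the frequency-weighted curve, by Levenberg-Marquardt with a deterministic
#' multi-start grid: `k` over the quartiles of the bin centers, `h` over
#' {0.5, 1, 2, 4}, `e_max` started at the maximum observed efficiency. The
#' best start by residual sum of squares wins. Flat input (efficiency range
#' below 1e-8) is reported as a degenerate fit with `e_max` equal to the
#' weighted mean and `k`, `h` unidentifiable.
#'
#' @param curve A [build_ratio_curve()] result, or any data frame with
#'   columns `ratio`, `e` and optionally `n` (weights).
#' @return Object of class `fret_sigmoid`: `e_max`, `k`, `h`, `rss`,
#'   `n_bins_used`, `degenerate`.
#' @export
fit_sigmoid <- function(curve) {
  if (inherits(curve, "fret_ratio_curve")) {
    use <- curve$n_pixels > 0 & is.finite(curve$weighted_mean_e)
    pts <- data.frame(ratio = curve$ratio_center[use],
                      e = curve$weighted_mean_e[use],
                      n = curve$n_pixels[use])
  } else {
    if (!all(c("ratio", "e") %in% names(curve)))
      stopf("curve must have columns 'ratio' and 'e'")
    pts <- data.frame(ratio = curve$ratio, e = curve$e,
                      n = if ("n" %in% names(curve)) curve$n else rep(1, nrow(curve)))
  }
  if (nrow(pts) < 4L)
    stopf("sigmoid fit needs at least 4 non-empty bins, got %d", nrow(pts))
  if (diff(range(pts$e)) < 1e-8) {
    e0 <- stats::weighted.mean(pts$e, pts$n)
    return(structure(list(e_max = e0, k = NA_real_, h = NA_real_,
                          rss = sum(pts$n * (pts$e - e0)^2),
                          n_bins_used = nrow(pts), degenerate = TRUE),
                     class = "fret_sigmoid"))
  }
  starts <- expand.grid(
    k = unname(stats::quantile(pts$ratio, c(0.25, 0.5, 0.75))),
    h = c(0.5, 1, 2, 4)
  )
  e_start <- min(max(pts$e), 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        e ~ e_max / (1 + (k / ratio)^h), data = pts, weights = pts$n,
        start = list(e_max = e_start, k = starts$k[i], h = starts$h[i]),
        lower = c(e_max = 1e-6, k = 1e-9, h = 1e-3),
        upper = c(e_max = 1, k = Inf, h = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- stats::deviance(fit)
    if (is.null(best) || rss < best$rss) {
      p <- stats::coef(fit)
      best <- list(e_max = unname(p["e_max"]), k = unname(p["k"]),
                   h = unname(p["h"]), rss = rss)
    }
  }
  if (is.null(best)) stopf("sigmoid fit failed from every start")
  structure(c(best, list(n_bins_used = nrow(pts), degenerate = FALSE)),
            class = "fret_sigmoid")
}

#' @export
print.fret_sigmoid <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<fret_sigmoid> degenerate (flat): e_max = %.4f over %d bins\n",
                x$e_max, x$n_bins_used))
  else
    cat(sprintf("<fret_sigmoid> e_max = %.4f, k = %.4g, h = %.3g (rss %.3g, %d bins)\n",
                x$e_max, x$k, x$h, x$rss, x$n_bins_used))
  invisible(x)
}

#' Molecular separation from plateau FRET efficiency
#'
#' Inverts the Förster relation `E = 1 / (1 + (r/R0)^6)` to
#' `r = R0 * ((1 - E) / E)^(1/6)`, assuming energy transfer between exactly
#' one donor and one acceptor without competition. `R0` defaults to 4.9 nm
#' (ECFP/EYFP pair) and is recorded in the result, since the distance is
#' only meaningful conditional on it.
#'
#' @param e_plateau Plateau efficiency, strictly inside (0, 1).
#' @param r0_nm Förster radius in nm.
#' @return Object of class `fret_distance`: `r_nm`, `r0_nm`, `e_plateau`.
#' @export
estimate_distance <- function(e_plateau, r0_nm = 4.9) {
  if (!is.finite(e_plateau) || e_plateau <= 0 || e_plateau >= 1)
    stopf("e_plateau must lie strictly inside (0, 1)")
  if (r0_nm <= 0) stopf("r0_nm must be positive")
  structure(
    list(r_nm = r0_nm * ((1 - e_plateau) / e_plateau)^(1 / 6),
         r0_nm = r0_nm, e_plateau = e_plateau),
    class = "fret_distance"
  )
}

#' @export
print.fret_distance <- function(x, ...) {
  cat(sprintf("<fret_distance> r = %.2f nm (E = %.3f, R0 = %.2f nm)\n",
              x$r_nm, x$e_plateau, x$r0_nm))
  invisible(x)
}

#' Efficiency at a given separation (inverse of the distance estimate)
#'
#' @param r_nm Separation in nm.
#' @param r0_nm Förster radius in nm.
#' @return `1 / (1 + (r_nm / r0_nm)^6)`.
#' @export
distance_to_efficiency <- function(r_nm, r0_nm = 4.9) 1 / (1 + (r_nm / r0_nm)^6)

#' Compare a sample curve against a baseline (random-FRET) curve
#'
#' Computes the per-bin efficiency difference on shared ratio bins (bins
#' with matching edges and pixels in both curves) and summarizes whether the
#' sample shows specific interaction above the baseline: the sample plateau
#' must exceed the baseline plateau and the difference must be positive in
#' more than `majority_frac` of the shared bins. No p-value is produced.
#'
#' @param sample,baseline Lists with elements `fit` (a [fit_sigmoid()]
#'   result) and `curve` (a [build_ratio_curve()] result). Curves should be
#'   built on the same ratio edges.
#' @param majority_frac Fraction of shared bins that must show a positive
#'   difference (default 0.5).
#' @return Object of class `fret_comparison`: per-bin table `bins`,
#'   `e_max_difference`, `frac_bins_positive`, `specific`, `majority_frac`.
#' @export
compare_curves <- function(sample, baseline, majority_frac = 0.5) {
  sc <- sample$curve; bc <- baseline$curve
  key <- function(cv) paste(signif(cv$ratio_low, 12), signif(cv$ratio_high, 12))
  su <- sc[sc$n_pixels > 0, , drop = FALSE]
  bu <- bc[bc$n_pixels > 0, , drop = FALSE]
  m <- match(key(su), key(bu))
  shared <- which(!is.na(m))
  if (!length(shared))
    stopf("no overlapping ratio bins between sample and baseline curves")
  bins <- data.frame(
    ratio_low = su$ratio_low[shared], ratio_high = su$ratio_high[shared],
    e_sample = su$weighted_mean_e[shared],
    e_baseline = bu$weighted_mean_e[m[shared]]
  )
  bins$delta <- bins$e_sample - bins$e_baseline
  e_max_diff <- sample$fit$e_max - baseline$fit$e_max
  frac_pos <- mean(bins$delta > 0)
  structure(
    list(bins = bins, e_max_difference = e_max_diff,
         frac_bins_positive = frac_pos,
         specific = e_max_diff > 0 && frac_pos > majority_frac,
         majority_frac = majority_frac),
    class = "fret_comparison"
  )
}

#' @export
print.fret_comparison <- function(x, ...) {
  cat(sprintf("<fret_comparison> %d shared bins, e_max difference %+.4f, %0.f%% bins above baseline -> %s\n",
              nrow(x$bins), x$e_max_difference, 100 * x$frac_bins_positive,
              if (x$specific) "specific" else "not specific"))
  invisible(x)
}
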