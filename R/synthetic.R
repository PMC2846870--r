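#' Default synthetic cell layout
#'
#' Four non-overlapping elliptical cells whose donor and acceptor
#' concentrations (arbitrary units) span acceptor/donor ratios from roughly
#' 0.2 to beyond 3 at the default gains, so one scene populates the whole
#' ratio axis the curve needs. Each cell carries a linear concentration ramp
#' across its width.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param e Per-cell true-efficiency specification: a single number in
#'   `[0, 1)` or a list `list(e_max=, k=, h=)` applied to the gain-scaled
#'   concentration ratio.
#' @return List of cell descriptors for [scene_spec()].
#' @export
default_cells <- function(shape = c(256L, 256L),
                          e = list(e_max = 0.30, k = 1, h = 2)) {
  h <- shape[1]; w <- shape[2]
  ry <- round(0.17 * h); rx <- round(0.15 * w)
  # opposite donor/acceptor ramps sweep the acceptor/donor ratio ~3.5-fold
  # across each cell, so four cells cover the ratio axis continuously
  mk <- function(cy, cx, d, a) {
    list(center = c(round(cy * h), round(cx * w)), radii = c(ry, rx),
         d = d, a = a, ramp_d = c(1.2, 0.8), ramp_a = c(0.6, 1.4), e = e)
  }
  list(
    mk(0.25, 0.25, d = 900, a = 180),
    mk(0.25, 0.75, d = 900, a = 450),
    mk(0.75, 0.25, d = 700, a = 900),
    mk(0.75, 0.75, d = 450, a = 1200)
  )
}

#' Scene specification for the forward simulator
#'
#' Describes everything the forward model needs: cell geometry and
#' fluorophore concentrations, true per-pixel efficiency, channel gains,
#' true bleed-through fractions, background, multiplicative shading, noise
#' and quantization. With `gains$k_f == gains$k_d` the analysis identity
#' `E = nF / (nF + DD)` recovers the true efficiency exactly in the
#' noise-free, shading-free, background-free case.
#'
#' @param shape `c(rows, cols)`.
#' @param detector_max Full-scale detector count (default 4095, a 12-bit
#'   photomultiplier stored in 16-bit TIFFs).
#' @param cells List of cell descriptors (see [default_cells()]).
#' @param gains List `k_d`, `k_a`, `k_f`: detector counts per donor unit in
#'   DD, per acceptor unit in AA, and per transferred quantum in DA.
#' @param bt_donor,bt_acceptor True crosstalk fractions of the forward
#'   model.
#' @param background Named numeric `c(dd=, da=, aa=)` additive counts.
#' @param shading_amplitude Amplitude of the radial illumination falloff in
#'   `[0, 1)`; 0 disables shading.
#' @param noise `"none"`, `"poisson"`, or `"poisson_gaussian"` (Poisson plus
#'   Gaussian read noise of sd `read_sd`).
#' @param read_sd Read-noise standard deviation (counts).
#' @param quantize Round half up and clip to `[0, detector_max]` (the
#'   detector model); disable only for exact-identity checks.
#' @param seed RNG seed; fixed seed gives bit-identical scenes.
#' @return Object of class `fret_scene_spec`.
#' @export
scene_spec <- function(shape = c(256L, 256L), detector_max = 4095,
                       cells = NULL,
                       gains = list(k_d = 2, k_a = 2, k_f = 2),
                       bt_donor = 0.30, bt_acceptor = 0.12,
                       background = c(dd = 20, da = 20, aa = 20),
                       shading_amplitude = 0.15,
                       noise = c("poisson", "none", "poisson_gaussian"),
                       read_sd = 2, quantize = TRUE, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(cells)) cells <- default_cells(shape)
  if (bt_donor < 0 || bt_acceptor < 0) stopf("true bleed-through must be >= 0")
  if (any(unlist(gains) <= 0)) stopf("gains must be positive")
  if (shading_amplitude < 0 || shading_amplitude >= 1)
    stopf("shading_amplitude must lie in [0, 1)")
  for (cell in cells) {
    if (cell$d < 0 || cell$a < 0) stopf("concentrations must be >= 0")
    if (is.numeric(cell$e) && (cell$e < 0 || cell$e >= 1))
      stopf("constant e_true must lie in [0, 1)")
  }
  structure(
    list(shape = as.integer(shape), detector_max = detector_max,
         cells = cells, gains = gains,
         bt_donor = bt_donor, bt_acceptor = bt_acceptor,
         background = background, shading_amplitude = shading_amplitude,
         noise = noise, read_sd = read_sd, quantize = quantize,
         seed = as.integer(seed)),
    class = "fret_scene_spec"
  )
}

# Smooth multiplicative illumination field: radial falloff from the image
# center, 1 at the center, 1 - amplitude at the corners.
shading_field <- function(shape, amplitude) {
  if (amplitude == 0) return(matrix(1, shape[1], shape[2]))
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  ry <- outer(((seq_len(shape[1]) - cy) / (shape[1] / 2))^2,
              ((seq_len(shape[2]) - cx) / (shape[2] / 2))^2, `+`)
  1 - amplitude * ry / max(ry)
}

# Rasterize the cells into donor/acceptor concentration fields and the true
# efficiency field. Overlapping cells sum concentrations; the efficiency
# specification of the later cell wins on the overlap.
scene_fields <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  d <- matrix(0, h, w); a <- matrix(0, h, w); e <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (cell in spec$cells) {
    norm2 <- ((rows - cell$center[1]) / cell$radii[1])^2 +
      ((cols - cell$center[2]) / cell$radii[2])^2
    inside <- norm2 <= 1
    if (!any(inside)) next
    ramp_d <- cell$ramp_d %||% cell$ramp %||% c(1, 1)
    ramp_a <- cell$ramp_a %||% cell$ramp %||% c(1, 1)
    # linear ramps across the cell's horizontal extent
    x0 <- cell$center[2] - cell$radii[2]; x1 <- cell$center[2] + cell$radii[2]
    xfrac <- (cols - x0) / max(x1 - x0, 1)
    fd <- ramp_d[1] + (ramp_d[2] - ramp_d[1]) * xfrac
    fa <- ramp_a[1] + (ramp_a[2] - ramp_a[1]) * xfrac
    d[inside] <- d[inside] + cell$d * fd[inside]
    a[inside] <- a[inside] + cell$a * fa[inside]
    if (is.numeric(cell$e)) {
      e[inside] <- cell$e
    } else {
      rho0 <- (spec$gains$k_a * a[inside]) / pmax(spec$gains$k_d * d[inside], 1e-12)
      e[inside] <- ifelse(d[inside] > 0,
                          sigmoid_efficiency(rho0, cell$e$e_max, cell$e$k, cell$e$h),
                          0)
    }
  }
  list(d = d, a = a, e = e)
}

# Forward model: ideal channels -> shading -> background -> noise ->
# quantization. Returns the acquisition plus full ground truth.
forward_model <- function(spec, fields, label) {
  g <- spec$gains
  dd_i <- g$k_d * fields$d * (1 - fields$e)
  aa_i <- g$k_a * fields$a
  sens <- g$k_f * fields$d * fields$e
  da_i <- sens + spec$bt_donor * dd_i + spec$bt_acceptor * aa_i
  shade <- shading_field(spec$shape, spec$shading_amplitude)
  ideal <- list(dd = dd_i, da = da_i, aa = aa_i)
  observed <- list()
  n_clipped <- c(dd = 0L, da = 0L, aa = 0L)
  for (ch in names(ideal)) {
    x <- ideal[[ch]] * shade + spec$background[[ch]]
    if (spec$noise %in% c("poisson", "poisson_gaussian"))
      x <- matrix(stats::rpois(length(x), as.vector(x)), nrow(x), ncol(x))
    if (spec$noise == "poisson_gaussian" && spec$read_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, spec$read_sd), nrow(x), ncol(x))
    if (spec$quantize) {
      x <- round_half_up(x)
      n_clipped[[ch]] <- sum(x > spec$detector_max | x < 0)
      x <- pmin(pmax(x, 0), spec$detector_max)
    } else {
      n_clipped[[ch]] <- sum(x > spec$detector_max | x < 0)
      x <- pmax(x, 0)
    }
    observed[[ch]] <- x
  }
  acq <- fret_acquisition(
    dd = image2d(observed$dd, spec$detector_max,
                 allow_overrange = !spec$quantize),
    da = image2d(observed$da, spec$detector_max,
                 allow_overrange = !spec$quantize),
    aa = image2d(observed$aa, spec$detector_max,
                 allow_overrange = !spec$quantize),
    label = label
  )
  ratio_true <- matrix(NA_real_, spec$shape[1], spec$shape[2])
  pos <- fields$d > 0 & fields$e < 1
  ratio_true[pos] <- (g$k_a * fields$a[pos]) /
    (g$k_d * fields$d[pos] * (1 - fields$e[pos]))
  truth <- list(
    e_true = fields$e, ratio_true = ratio_true,
    d = fields$d, a = fields$a,
    dd_ideal = dd_i, da_ideal = da_i, aa_ideal = aa_i,
    bt_donor = spec$bt_donor, bt_acceptor = spec$bt_acceptor,
    background = spec$background, shading = shade,
    n_clipped = n_clipped
  )
  list(acquisition = acq, truth = truth)
}

#' Generate one synthetic FRET acquisition with ground truth
#'
#' Runs the forward model: ideal signals `DD* = k_d d (1 - e)`,
#' `AA* = k_a a`, sensitized emission `S = k_f d e`,
#' `DA* = S + bt_donor DD* + bt_acceptor AA*`; each channel is then
#' multiplied by the shading field, incremented by the background level,
#' noise-corrupted, rounded half up and clipped to the detector range.
#'
#' @param spec A [scene_spec()].
#' @param label Label for the acquisition.
#' @return List with `acquisition` (a [fret_acquisition()]) and `truth`
#'   (per-pixel `e_true`, `ratio_true`, ideal channels, true bleed-through,
#'   background, shading field, and per-channel clipped-pixel counts).
#' @export
generate_acquisition <- function(spec, label = "synthetic") {
  with_seed(spec$seed, forward_model(spec, scene_fields(spec), label))
}

#' Generate donor-only and acceptor-only control acquisitions
#'
#' The donor-only control zeroes every acceptor concentration and the true
#' efficiency; the acceptor-only control zeroes every donor concentration.
#' The forward model is otherwise identical to the main scene, so the
#' controls carry the same true bleed-through fractions. Each control uses
#' its own seed derived from the scene seed, as separately acquired control
#' cells would.
#'
#' @param spec A [scene_spec()].
#' @return List with `donor_only` and `acceptor_only`, each a
#'   [generate_acquisition()] result.
#' @export
generate_controls <- function(spec) {
  strip <- function(cells, what) lapply(cells, function(cell) {
    if (what == "acceptor") { cell$a <- 0; cell$e <- 0 } else cell$d <- 0
    cell
  })
  donor_spec <- spec
  donor_spec$cells <- strip(spec$cells, "acceptor")
  donor_spec$seed <- spec$seed + 1L
  acceptor_spec <- spec
  acceptor_spec$cells <- strip(spec$cells, "donor")
  acceptor_spec$seed <- spec$seed + 2L
  list(donor_only = generate_acquisition(donor_spec, "donor-only control"),
       acceptor_only = generate_acquisition(acceptor_spec, "acceptor-only control"))
}

#' Generate a random (non-specific) FRET scene
#'
#' Emulates cells expressing free donor and acceptor with no specific
#' interaction: a low ratio-dependent baseline efficiency everywhere inside
#' the cells, plus sparse high-efficiency outlier pixels concentrated at the
#' cell edges, where non-specific transfer is most prominent. This is the
#' scene whose raw mean efficiency is inflated by a few outliers while the
#' frequency-weighted curve stays at the baseline.
#'
#' @param spec A [scene_spec()]; its per-cell `e` is replaced by `baseline`.
#' @param baseline Baseline sigmoid `list(e_max=, k=, h=)` (default plateau
#'   0.05).
#' @param outlier_density Fraction of edge-ring pixels set to `outlier_e`.
#' @param outlier_e Efficiency of the outlier pixels. The default 0.5 is an
#'   order of magnitude above the baseline plateau yet leaves the quenched
#'   donor signal inside the evaluable exposure window, so the outliers
#'   actually reach the curve (as they do in real recordings).
#' @return As [generate_acquisition()], with `truth$outlier_mask` added.
#' @export
generate_random_fret_scene <- function(spec,
                                       baseline = list(e_max = 0.05, k = 1, h = 2),
                                       outlier_density = 0.01,
                                       outlier_e = 0.50) {
  spec$cells <- lapply(spec$cells, function(cell) { cell$e <- baseline; cell })
  with_seed(spec$seed, {
    fields <- scene_fields(spec)
    outliers <- matrix(FALSE, spec$shape[1], spec$shape[2])
    if (outlier_density > 0) {
      rows <- matrix(seq_len(spec$shape[1]), spec$shape[1], spec$shape[2])
      cols <- matrix(seq_len(spec$shape[2]), spec$shape[1], spec$shape[2],
                     byrow = TRUE)
      for (cell in spec$cells) {
        norm2 <- ((rows - cell$center[1]) / cell$radii[1])^2 +
          ((cols - cell$center[2]) / cell$radii[2])^2
        ring <- which(norm2 <= 1 & norm2 >= 0.81)
        if (!length(ring)) next
        n_out <- min(max(round(outlier_density * length(ring)), 1L), length(ring))
        outliers[sample(ring, n_out)] <- TRUE
      }
      fields$e[outliers] <- outlier_e
    }
    res <- forward_model(spec, fields, "random-FRET scene")
    res$truth$outlier_mask <- outliers
    res
  })
}

#' Generate a shading reference image
#'
#' The shading reference a microscope operator would acquire from a uniform
#' fluorescent target: the scene's illumination field scaled to
#' `level_frac * detector_max` counts, quantized.
#'
#' @param spec A [scene_spec()] (uses its shape, amplitude, detector range).
#' @param level_frac Mean illumination level as a fraction of full scale.
#' @return A [image2d()].
#' @export
generate_shading_reference <- function(spec, level_frac = 0.5) {
  field <- shading_field(spec$shape, spec$shading_amplitude)
  image2d(round_half_up(level_frac * spec$detector_max * field),
          spec$detector_max)
}
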