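---
title: "Quantifying sensitized-emission FRET with fretmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sensitized-emission FRET with fretmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretmap)
```

## The measurement

Förster resonance energy transfer (FRET) is non-radiative energy transfer
from an excited donor fluorophore to a nearby acceptor. Its efficiency falls
with the sixth power of the separation, which makes it a molecular-scale
ruler below roughly 10 nm and a practical reporter of protein–protein
interaction in living cells. `fretmap` implements the sensitized-emission
variant: three single-channel images are recorded per acquisition —

* **DD** — donor excitation, donor emission,
* **DA** — donor excitation, acceptor emission (the FRET channel),
* **AA** — acceptor excitation, acceptor emission,

and the acceptor fluorescence that was *sensitized* by transfer is isolated
from the DA channel by subtracting the two spectral crosstalk
contributions. Unlike acceptor photobleaching, nothing is destroyed, so the
same cells can be followed over time.

## Pipeline and models

The pipeline order is fixed and logged: shading correction → background
subtraction → dynamic-range masking → net FRET → efficiency → ratio curve.
Corrections are applied before any ratio or threshold is computed.

### Flat-field (shading) correction

Laser illumination across a scanned field is not uniform. Given a shading
reference image $Y$ (a uniform fluorescent target) with mean $M$, each
channel $B$ is corrected pixelwise as

$$B' = B \cdot \frac{M}{Y}.$$

Reference pixels below one count are floored to one count and their number
reported; the reference should never be that dark, but a division by zero
must not silently amplify noise. Corrected values may exceed the detector
full scale; they are returned unclipped with a warning count, because
clipping here would bias the bleed-through ratios estimated next. One
`shading_model` is accepted per channel — whether one reference is shared
across channels is left to the configuration, since acquisition practice
varies.

### Background

Thirty 15×15-pixel squares are placed uniformly at random (with
replacement) over all positions where the square fits inside the image; the
square with the lowest mean grey value defines the background level, which
is subtracted with a floor at zero. Ties on the minimum go to the
first-drawn square, and the seed of the draw is recorded in every estimate,
so a background level is always reproducible bit for bit. The candidate
squares themselves are returned, which lets a test re-derive the selection
by brute-force enumeration.

### Bleed-through calibration

Two crosstalk paths contaminate the DA channel: donor emission leaking into
the acceptor detection band (*donor bleed-through*) and direct acceptor
excitation by the donor laser (*acceptor bleed-through*). Each is calibrated
from cells expressing a single fluorophore:

$$\mathrm{BT}_{donor} = \frac{\sum \mathrm{DA}}{\sum \mathrm{DD}}
  \quad\text{(donor-only cells)},\qquad
  \mathrm{BT}_{acceptor} = \frac{\sum \mathrm{DA}}{\sum \mathrm{AA}}
  \quad\text{(acceptor-only cells)},$$

with the sums restricted to pixels whose reference channel lies between 10%
and 90% of the detector full scale (inclusive endpoints, configurable).
Below about 10% of the dynamic range crosstalk ratios become dominated by
noise; near saturation they grow non-linearly; between the two the ratios
are constant, which is what makes a single scalar per path sufficient. The
*ratio of sums* is used rather than the mean of per-pixel ratios: under
Poisson statistics it is the minimum-variance estimator of a shared
proportionality constant, and it does not blow up on dim pixels. An
optional per-channel autofluorescence floor can exclude intensities below a
measured cutoff (default off: autofluorescence of non-transfected cells is
typically far below fusion-protein signal).

### Masking

FRET can only be evaluated where both fluorophores are present and neither
channel is unreliable. A pixel is *underexposed* when DD or AA falls below
10% of full scale (or below the autofluorescence floor), *overexposed* when
either exceeds 90%, and *evaluable* otherwise. All thresholds are fractions
of the detector full scale (`detector_max`), never of the observed maximum;
`detector_max` is user-supplied because 12-bit data is routinely stored in
16-bit containers.

### Net FRET and efficiency

Per pixel,

$$nF = \mathrm{DA} - \mathrm{DD}\cdot \mathrm{BT}_{donor}
       - \mathrm{AA}\cdot \mathrm{BT}_{acceptor},$$

$$E = \frac{nF}{nF + \alpha\,\mathrm{DD}},$$

where $\alpha$ accounts for the ratio of quantum yields and detection
efficiencies of the two fluorophores and defaults to 1, appropriate when
plateau values have been cross-checked against an independent method (e.g.
acceptor bleaching). **The efficiency expression is a reconstruction**: it
is the standard sensitized-emission form implied by treating $nF$ as the
acceptor-detected count of transferred quanta and $\mathrm{DD}$ as the
count of untransferred ones under negligible non-radiative losses, and it
is the form the package fixes. With matched donor/FRET gains it recovers
the true efficiency exactly on the simulator's forward model, which is the
consistency condition the test suite enforces.

Pixels with $nF \le 0$ are reported as unevaluated (`NA`), not clamped to
zero — clamping would bias curve means downward wherever crosstalk noise
dominates. Their count is carried on the map object.

### The frequency-weighted ratio curve

Efficiency rises with the acceptor/donor abundance ratio (more acceptors
per donor means more transfer opportunities) and saturates at a plateau, so
mean efficiencies are reported *per acceptor/donor-ratio bin* rather than
as one number; the raw AA/DD fluorescence ratio serves as the abundance
proxy and the bins default to logarithmic spacing because expression levels
span orders of magnitude.

Within a ratio bin, a handful of extreme efficiency values — aggregates at
cell edges, residual crosstalk errors — can shift a plain mean
substantially, and simply cutting values below a threshold makes it worse
(the surviving high outliers then dominate). Instead, each bin's
efficiencies are histogrammed in bins of width 0.01 over $[0,1]$; histogram
bins with fewer than `min_freq_frac` (default 5%) of the modal bin's count
are discarded; the bin efficiency is the count-weighted mean of the
retained bin centers. The plain mean is kept alongside for diagnostics.
The weighting scheme itself (modal-relative frequency filtering) is this
package's concrete choice for "weight by frequency"; it is fully
parameterized, and `min_freq_frac = 0` reduces it to the plain mean up to
half a histogram bin.

### Sigmoid fit and Förster distance

The curve is summarized by a Hill-form sigmoid

$$E(\rho) = \frac{E_{max}}{1 + (k/\rho)^h},$$

fit by weighted (pixels-per-bin) Levenberg–Marquardt least squares from a
deterministic multi-start grid ($k$ over the quartiles of the bin centers,
$h \in \{0.5, 1, 2, 4\}$, $E_{max}$ from the maximum observed efficiency);
the best start by residual sum of squares wins. The Hill form is monotone,
bounded, and its plateau $E_{max}$ is the quantity the distance estimate
consumes. Flat curves (range $<10^{-8}$) return a degenerate fit with
unidentifiable $k$ and $h$ rather than an arbitrary answer.

Assuming transfer between exactly one donor and one acceptor, the plateau
efficiency inverts to a separation through the Förster relation

$$r = R_0 \left(\frac{1-E}{E}\right)^{1/6},$$

with $R_0 = 4.9$ nm by default (ECFP/EYFP). Every distance records the
$R_0$ it used: the separation is only meaningful *conditional on the
Förster radius*, and the default is configurable. The distance is computed
from the fitted plateau by default; a weighted mean over a user-selected
ratio range is available instead.

### Random-FRET baseline

Free donor and acceptor produce non-specific transfer by chance proximity
and aggregation; this sets the detection floor for any claimed interaction.
`compare_curves` differences a sample curve against such a baseline on
shared ratio bins and flags the sample as *specific* only when its plateau
exceeds the baseline's and the per-bin difference is positive in a majority
(configurable) of shared bins. No hypothesis test is attached — the
comparison is descriptive.

## The synthetic generator

No real acquisitions ship with the package, so a forward simulator defines
the study conditions every stage is validated under. Per pixel, from donor
concentration $d$, acceptor concentration $a$ and true efficiency $e$:

$$\mathrm{DD}^* = k_d\, d\,(1-e),\qquad
  \mathrm{AA}^* = k_a\, a,\qquad
  \mathrm{DA}^* = k_f\, d\, e + \mathrm{BT}_{d}\,\mathrm{DD}^*
                  + \mathrm{BT}_{a}\,\mathrm{AA}^*.$$

Donor quenching is modelled ($\mathrm{DD}^*$ scales with $1-e$) so that the
efficiency identity is exact when $k_f = k_d$. Channels are then multiplied
by a smooth radial shading field, offset by a constant background,
noise-corrupted (Poisson, optionally plus Gaussian read noise), rounded
half up and clipped to the detector range. Clipped pixels are counted.
Setting `quantize = FALSE` skips rounding/clipping for machine-precision
identity checks.

Default conditions, chosen once as typical of confocal CFP/YFP imaging and
not revisited: a 12-bit detector (`detector_max = 4095`); four elliptical
cells whose donor/acceptor levels and opposing linear concentration ramps
sweep the AA/DD ratio continuously from about 0.1 to 6 while keeping DD and
AA inside the 10–90% window; gains $k_d = k_a = k_f = 2$ counts per unit;
true crosstalk 0.30 (donor) and 0.12 (acceptor), magnitudes typical of
CFP emission tails and direct YFP excitation; background 20 counts per
channel; 15% radial shading; Poisson noise. The default interaction scene
uses a true sigmoid with $E_{max} = 0.30$, $k = 1$, $h = 2$; the random-FRET
scene uses a low baseline ($E_{max} = 0.05$) plus sparse outlier pixels of
$E = 0.5$ on the cell-edge ring (1% of ring pixels). The outlier efficiency
is 0.5 rather than something higher because donor quenching would otherwise
push those pixels below the 10% exposure floor and they would never reach
the curve.

What the simulator does *not* emulate: optical point-spread blur, channel
misregistration and chromatic aberration, photobleaching kinetics,
structured autofluorescence, detector pattern noise, 3-D geometry. Passing
tests therefore demonstrate correctness of the computational method on its
own model assumptions — they do not certify performance on data whose
dominant errors are optical.

## Numerical and interface choices

* Matrices are indexed the native R way, 1-based `(row, col)`; every module
  shares this convention, including the recorded background-square origins.
* Quantization rounds half up (`floor(x + 0.5)`), not half to even.
* Unevaluated pixels are `NA`; maps written to disk require an explicit
  mask before non-finite values are accepted, and write them as 0.
* Grayscale output maps are 16-bit TIFFs with bit-exact linear scaling of a
  stated value range; pseudocolor output uses one fixed jet-style colormap.
* TIFF round-trips are lossless for integer counts (8- or 16-bit
  containers).
* The valid-window endpoints are inclusive; all windows are fractions of
  `detector_max`.
* Background squares are drawn with replacement; first-drawn wins ties.
* Every CLI run writes a manifest (input checksums, full configuration,
  software version, seeds) sufficient to reproduce it, and outputs are
  written via temp-file-and-rename so failures leave no partial files.

## Problem sizes

The shipped tests and the acceptance script run on 128²–512² scenes with
roughly 10⁴–10⁵ cell pixels per scene — ample for the sub-1% calibration
and plateau-recovery checks performed, while keeping the whole suite in the
seconds range. Larger images change nothing structurally: every stage is
linear or near-linear in pixel count.

## Known limitations

* The efficiency formula is a reconstruction (flagged above); if a
  different $\alpha$ convention or efficiency form is required it must be
  substituted consciously.
* AA/DD is a fluorescence-ratio proxy for the molecular acceptor:donor
  ratio; no gain calibration is applied to the ratio axis.
* The distance estimate assumes one-to-one transfer without competition;
  oligomeric geometries need a different model.
* Bleed-through is treated as constant within the valid window; wavelength-
  or intensity-dependent crosstalk models are out of scope.
* Channel registration is assumed; nothing re-aligns the three images.
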