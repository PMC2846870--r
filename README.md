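# fretmap

Sensitized-emission FRET quantification for microscopists: from raw
three-channel acquisitions and single-fluorophore control images to
bleed-through-corrected per-pixel FRET efficiency maps, frequency-weighted
efficiency-vs-acceptor/donor-ratio curves, sigmoid fits, random-FRET
baselines and Förster-distance estimates.

Förster resonance energy transfer (FRET) reports molecular proximity below
~10 nm and is a standard readout for protein–protein interaction in living
cells. In the sensitized-emission variant, three images are recorded per
field: **DD** (donor excitation / donor emission), **DA** (donor excitation /
acceptor emission — the FRET channel) and **AA** (acceptor excitation /
acceptor emission). The DA signal is contaminated by two crosstalk paths,
calibrated from donor-only and acceptor-only control cells as ratios of
sums over the reliable 10–90% band of the detector dynamic range. Per pixel,
on shading-corrected, background-subtracted channels:

```
nF = DA − DD·BT_donor − AA·BT_acceptor        (net FRET)
E  = nF / (nF + α·DD),  α = 1 by default      (FRET efficiency)
r  = R0 · ((1 − E)/E)^(1/6)                   (Förster distance from plateau E)
```

Pixels outside the 10–90% exposure window in either DD or AA are masked.
Because efficiency rises sigmoidally with the acceptor/donor abundance
ratio (AA/DD), per-pixel efficiencies are binned by ratio, weighted by
frequency within each bin (rare outlier efficiencies are discarded relative
to the modal histogram bin instead of applying a threshold cut-off, which
merely shifts means toward the surviving extremes), and summarized by a
Hill sigmoid `E(ρ) = E_max/(1 + (k/ρ)^h)`. A random-FRET baseline —
cells expressing free donor and acceptor — defines the specificity floor any
sample curve is compared against.

A forward simulator generates ground-truth scenes (cells, concentration
gradients, true efficiency fields, crosstalk, shading, background, Poisson
noise, detector quantization) plus matching controls, so the whole pipeline
is testable without microscope data.

## Worked example

Simulate a study whose true interaction sigmoid has plateau `E_max = 0.30`,
calibrate bleed-through from its controls, and analyze it:

```r
library(fretmap)

spec  <- scene_spec(shape = c(256, 256), seed = 42)
study <- cmd_simulate(spec, "demo")

cfg <- run_config(shading_dd = study$shading, shading_da = study$shading,
                  shading_aa = study$shading)
cal <- cmd_calibrate(
  c(dd = study$donor_dd, da = study$donor_da, aa = study$donor_aa),
  c(dd = study$acceptor_dd, da = study$acceptor_da, aa = study$acceptor_aa),
  cfg, "demo/calibration.json")
#> calibration: bt_donor = 0.3002 (20996 px), bt_acceptor = 0.1203 (16815 px)

res <- cmd_analyze(study$dd, study$da, study$aa,
                   "demo/calibration.json", cfg, "demo/out")
#> analyze: 16805 evaluable px, e_max = 0.2991, r = 5.65 nm
print(res$fit)
#> <fret_sigmoid> e_max = 0.2991, k = 1.176, h = 1.73 (rss 0.033, 10 bins)
```

The calibration recovers the scene's true crosstalk fractions (0.30 / 0.12)
from noisy shaded controls, and the fitted plateau efficiency 0.2991 agrees
with the generating value 0.30 within 0.3%. The distance printed alongside
(`r = 5.65 nm`) is the Förster inversion of that plateau at the default
`R0 = 4.9 nm` (ECFP/EYFP) — meaningful only conditional on that radius.
Curve bins look like:

```r
head(as.data.frame(res$curve)[res$curve$n_pixels > 0,
     c("ratio_center", "weighted_mean_e", "raw_mean_e", "n_pixels")])
#>   ratio_center weighted_mean_e raw_mean_e n_pixels
#> 3    0.2610157      0.02389113 0.02426631      999
#> 4    0.3831187      0.03602466 0.03626433     1837
#> 5    0.5623413      0.06512638 0.06529904     1933
#> 6    0.8254042      0.10479631 0.10459529     2092
#> 7    1.2115277      0.15537869 0.15502306     1569
#> 8    1.7782794      0.20111574 0.20130039     2312
```

`cmd_analyze` also writes the net-FRET and efficiency maps (16-bit TIFF and
pseudocolor PNG), the blue/red/green exposure-mask overview, the curve CSV,
fit/distance JSONs and a reproducibility manifest. `cmd_compare` then
differences a sample curve against a random-FRET baseline and flags
specific interaction. The same four steps are available from a shell via
the installed `inst/scripts/fret` script
(`fret simulate|calibrate|analyze|compare --flag value ...`).

See `vignettes/fretmap-methods.Rmd` for the models, every tunable parameter
and the design rationale.

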