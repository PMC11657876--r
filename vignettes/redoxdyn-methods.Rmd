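---
title: "redoxdyn: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{redoxdyn: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Widefield autofluorescence microscopy with an emission splitter projects two
spectral bands of one field of view — centered at 451 nm (dominated by
NAD(P)H) and 560 nm (dominated by FAD and other flavins) — side by side onto
a single camera sensor, so every acquired frame is one image holding two
half-images. Because NAD(P)H is the reduced and FAD the oxidized coenzyme,
the normalized intensity ratio

$$\mathrm{ORR} = \frac{I_{451}}{I_{451} + I_{560}}$$

is an optical proxy for the cellular redox state: blocking the electron
transport chain (e.g., with cyanide) raises NAD(P)H fluorescence and with it
the ORR, while glucose re-feeding of starved cells produces a rapid,
per-cell heterogeneous intensity rise. At ~100 Hz frame rates these dynamics
are resolvable, but the photon budget per frame is small, so quantification
must contend with shot noise, camera read noise, photobleaching under
continuous illumination, and a camera offset comparable to the signal.

`redoxdyn` implements the full analysis chain — split-frame TIFF I/O,
channel registration, thresholding/segmentation, per-cell trace extraction,
ORR and photobleaching metrics, stimulus-response kinetics, and
normality-gated group statistics — together with a synthetic image simulator
that generates split-frame stacks with known ground truth, so every stage of
the chain is verifiable without access to raw microscope data.

## The synthetic imaging model

`simulate_timelapse()` draws a field of non-touching elliptical cell
phantoms, each with a bright cytoplasm, a nucleus dimmed by
`nucleus_factor` (default 0.6 — NAD(P)H and FAD are cytosolic/mitochondrial,
so nuclei appear dark in both channels), and `mito_density` punctate
mitochondria brightened by `mito_factor` (default 1.8). Both channels share
the same geometry and differ only in base intensity.

The camera model is

$$\text{counts} = \mathrm{Poisson}(\text{signal}) +
  \mathcal{N}(0, \sigma_\mathrm{read}) + \text{offset},$$

clipped to $[0, 65535]$ and quantized to 16 bits. The expected cytoplasm
signal scales linearly with illumination power × exposure relative to a
reference point (4.14 mW × 10 ms). Defaults: 32 counts/pixel/frame in the
451 channel and 14 in the 560 channel at the reference (an ORR of
32/46 ≈ 0.70, and deliberately dim — autofluorescence at 10-ms exposures is
photon-starved), read noise sd 2 counts, offset 100 counts (typical sCMOS
values). When every noise source is off, the generator returns exact
expected intensities without quantization, which is what makes the
"noiseless traces equal ground truth exactly" oracle testable.

Three experiment modes are generated:

* **Photobleaching** (the default `simulation_config()`): 12 cells, 3000
  frames at 99.4 Hz (30 s). Each channel decays monoexponentially,
  $I(t) = I_0 e^{-kt}$, with defaults $k_{451} = 0.0019\,\mathrm{s^{-1}}$
  and $k_{560} = 0.0011\,\mathrm{s^{-1}}$ at 4.14 mW — chosen so the 30-s
  loss is ≈5.6% and ≈3.3%, the magnitudes reported for that power. A
  per-cell lognormal rate multiplier (sdlog 0.3, mean 1) models the
  cell-to-cell bleaching spread visible in single-cell data; the pipeline's
  dose-proportional rate map ($k \propto$ power) makes bleaching increase
  with illumination.
* **Cyanide** (`cyanide_sim_config()`): a static perturbation multiplying
  the 451-nm cell signal by 1.6 and the 560-nm signal by 0.93 (the 560
  direction is inconsistent in practice; both factors are configurable),
  moving the ORR from ≈0.70 to ≈0.80. A per-image lognormal channel gain
  (sdlog 0.067 per channel) models dish-to-dish biological variation and
  yields a within-group image-level ORR sd of ≈0.02 at n = 15 images/group,
  the regime the group-statistics calibration prescribes.
* **Glucose bolus** (`glucose_sim_config()`): 5 cells, 3000 frames at
  99.6 Hz, stimulus at 8 s. Each cell's trace is flat (apart from bleaching
  and an optional pre-stimulus drift, default −4% across the pre-stimulus
  span) until `stimulus + delay`, with delays drawn Unif(1, 4) s; it then
  rises linearly at a rate drawn Unif(0.4, 1.6) a.u./s (451 nm; the 560-nm
  rate is a Unif(0.4, 0.8) fraction) until reaching 1.10× its pre-onset
  level, then stays flat. The piecewise-linear shape is a deliberate
  minimal model: the real response is known to be a rapid rise followed by
  sustained elevation, but no functional form is established, and a ramp
  makes "onset" and "rise rate" exactly defined quantities to recover.

Two ground-truth subtleties are worth stating. First, traces are defined as
ROI means of the noiseless image *including* the camera offset — that is
exactly what the measurement pipeline computes, so truth and measurement are
commensurable; rates in "a.u./s" are raw count units per second. Second,
with bleaching active, the noiseless post-onset slope is the drawn ramp rate
minus the concurrent bleach slope; the recorded `true_rate_au_per_s` is
therefore the least-squares slope of the noiseless trace over the default
2-s fit window (it equals the drawn rate when bleach rates are zero), which
keeps rate-recovery tests exact rather than approximate.

The simulator's pixel sampling is desk-scale: defaults use 0.65 µm/px
(photobleaching; think 4×-binned sCMOS) and 0.325 µm/px with larger phantoms
(glucose mode), rather than full-resolution 0.16 µm sampling, to keep a
3000-frame stack within single-CPU memory. Cell areas in the glucose preset
(~2500–4000 px) approach the pixel counts of real traced cells, which is
what makes rise-rate recovery at 10% feasible; shrinking cells further
inflates trace shot noise quadratically in relative terms.

What a green test does *not* establish: phantoms are non-touching ellipses
(no watershed separation is implemented or needed), ROIs are static (no cell
motion), illumination is spatially flat (no vignetting or flat-field error),
there is no spectral bleed-through between the halves, no focus drift, and
the background is structure-free. Real data violate all of these to some
degree; the package's claims are about the correctness of the estimators
under the stated model, not about robustness to un-modeled artifacts.

## Image handling

Frames are split at the vertical midline; which half is the 451-nm channel
is configuration (`layout`, default `left451`), because the assignment
depends on the splitter's dichroic orientation and is not derivable from the
data. Registration (`register_channels()`) maximizes normalized
cross-correlation over integer shifts within ±`max_shift` (default 10 px),
ties broken toward zero shift. Sub-pixel registration is deliberately
absent: the downstream quantities are ratios and window means of ROI
averages, and interpolation would resample intensities for no measurable
benefit. Timebase convention: frame $i$ (0-based) is stamped
$t = i/\text{frame rate}$.

TIFF support is a minimal built-in baseline codec (uncompressed grayscale
multi-page, 8/16-bit, both byte orders on read), with acquisition metadata
embedded as JSON in the ImageDescription tag; the test suite cross-validates
the codec against an independent implementation. RGB, tiled or compressed
files are rejected explicitly rather than half-supported.

## Thresholding and ROIs

The reference procedure sets a manual intensity threshold by eye and traces
cells by hand on the 451-nm channel (the brighter one), then applies the
same ROIs to the 560-nm channel and to all frames. `redoxdyn` replaces both
manual steps with reproducible equivalents, as flags:

* **Image-level metrics** use pixels above an automatic threshold
  (`otsu` by default; `fixed` and `percentile` available) on the
  time-averaged 451-nm image, with an optional second Otsu split inside the
  foreground that discards the dimmer (nucleus) class
  (`exclude_nucleus = TRUE` in the pipeline), mirroring the instruction to
  remove background and nucleus pixels while keeping cytoplasm.
* **Cell-level traces** use whole-cell ROIs: 8-connected components of the
  thresholded foreground, holes filled (so the dim nucleus belongs to its
  cell), components under `min_area` (default 100 px) dropped. ROIs are
  static across time and shared by both channels.

The Otsu implementation maximizes between-class variance over all candidate
splits of the observed values (no histogram binning), so it agrees exactly
with a brute-force search; a constant image yields an empty mask and a
warning instead of an error. Touching cells are not separated — a documented
limitation, acceptable because the phantoms are non-touching and the manual
procedure it replaces also traced isolated cells.

One measurement correction lives in the pipeline rather than the metric
ops: at 10-ms exposures the camera offset (≈100 counts) exceeds the cell
signal (≈15–55 counts), so a ratio of raw masked means is dominated by the
offset and compresses all contrast. The pipeline therefore subtracts each
channel's background mean (pixels below the first-stage threshold) from the
masked means before forming the image-level ORR. `orr_image()` itself
defaults to raw means (background arguments are opt-in), keeping the core
operation faithful to the simple ratio-of-means definition.

## Metrics

* `compute_orr()` implements the ratio with domain checks; image-level ORR
  is the ratio of masked means (means first, then the ratio — pixelwise
  ratio maps exist for visualization only, because single-pixel ratios of
  low counts are noise-amplifying).
* `percent_change()` supports both sign conventions in use:
  `eq2` = (initial − final)/initial × 100, positive when signal is lost,
  and `table` = its negative. Reports round to one decimal; tests compare
  unrounded values except where printed tables are being reproduced.
* `photobleach_report()` averages the first and last `n_window = 10` frames
  of each cell's 451-nm, 560-nm and per-frame-ORR series and reports both
  conventions.
* `compute_snr()` defaults to contrast SNR,
  (signal mean − background mean)/background sd, computed on time-averaged
  first/last window images by `snr_timepoints()`; the definition is recorded
  in the output because the quantity is conventionally reported without a
  formula, and a `ratio` variant is provided.

## Stimulus-response kinetics

All estimators run on a centered 25-frame moving average (no phase lag;
edges use truncated windows) and are invariant to intensity offsets and
equivariant under time shifts (up to one frame from window discretization).

* **Baseline drift**: percent change (table convention) between the first
  10 frames of the record and the last 10 frames before the stimulus.
* **Onset detection**: baseline level and sd come from a linear fit over
  the 2 s preceding the stimulus — the level is the fit value *at* the
  stimulus and the sd is the residual sd, so pre-stimulus drift biases
  neither. The response is declared where the smoothed trace exceeds
  level + 3·sd for 50 consecutive frames (~0.5 s). The raw crossing time is
  biased late by ≈ 3·sd/slope, so the estimate is refined by a two-line
  changepoint: a local baseline line fitted between stimulus and crossing
  (tracking slow post-stimulus decay such as continued photobleaching) is
  intersected with a line fitted to the rise. The rise fit skips one
  smoothing window after the crossing (where the smoothed kink is convexly
  blended) and stops at the running maximum (so step responses do not
  flatten the fit). With these choices, noiseless ramp onsets are recovered
  to within a frame, and at default noise to well within 0.2 s.
* **Why 50 frames and not fewer**: the sustained-crossing count must exceed
  the smoothing window, otherwise a single smoothed noise excursion (which
  is autocorrelated over the window) can satisfy the criterion; at 25
  frames the false-positive rate on stimulus-free runs was several percent
  per trace, at 50 it is negligible. A zero-sd (noiseless) baseline
  degrades the criterion to "any sustained increase" and sets a flag.
* **Rise rate**: least-squares slope of the *raw* trace over
  [onset, onset + 2 s] — at the observed rates the ramp lasts well beyond
  2 s, so the window sees pure rise.
* **Time-to-peak**: argmax of the smoothed post-onset trace, relative to
  the stimulus; monotone-to-end traces report the record end with an
  `unpeaked` flag.
* **ORR kinetics** use smooth-then-ratio (per-frame ratio of smoothed
  channel means), disablable via `smooth_ratio = FALSE`.

## Group statistics

`compare_groups()` reproduces the published decision rule: Shapiro–Wilk on
each group at α = 0.05; if **both** pass (the wording is read
conjunctively), an unpaired two-sided Student's t-test, otherwise a
two-sided Mann–Whitney U test, each at α = 0.05. "Standard t-test" is taken
as the equal-variance form, with Welch available as an option. Zero-variance
groups (Shapiro–Wilk undefined) are routed to Mann–Whitney with a warning.
Star annotations use the conventional strict thresholds
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001; `ns` otherwise).
No multiplicity correction is applied by default — conditions are reported
per-test, as in the source procedure — but Holm/Bonferroni adjustment is
available separately. The gate-then-test composite keeps its type-I error
at the nominal level under a normal null (verified by simulation in the
acceptance suite: 2000 null replicates at n = 15/group must reject at a
rate inside the 99% binomial band around 0.05).

## Numerical and degenerate-input conventions

Tie-breaks: Otsu takes the lowest maximizing threshold; registration
prefers the smallest shift; component labels are assigned in image scan
order. Degenerate inputs fail loudly and specifically: odd-width frames,
RGB pages, empty masks, zero-variance backgrounds, too-short traces (the
error names the required length), impossible phantom placements (the error
names `n_cells` and the field of view). Quantization is automatic only when
noise is on, so noiseless runs stay exact. Seeds are part of the
configuration; identical config + seed reproduces stacks bit for bit, and
pipeline runs stamp a config hash and package version into their YAML
manifest.

## Known limitations

* No watershed: touching cells become one ROI.
* Static ROIs: moving cells are not tracked.
* The glucose response model is piecewise-linear; estimators are exact for
  it and approximate for smoother real responses.
* The 560-nm channel at low rates carries little kinetic information; rate
  recovery guarantees are stated for the 451-nm channel.
* SNR absolute values, measured ORR distributions and per-power bleaching
  percentages of the reference study derive from its unreleased raw images
  and are not reproduced here; the synthetic recovery and property tests
  stand in for them.
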