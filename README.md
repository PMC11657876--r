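# redoxdyn

Analysis of dual-emission autofluorescence microscopy of cellular
metabolism, for imaging groups who quantify redox state from NAD(P)H and
FAD fluorescence at high frame rates.

A widefield microscope with an emission splitter projects the 451-nm
(NAD(P)H) and 560-nm (FAD) bands of one field of view side by side onto a
single camera, so each acquired frame is a split image holding both
channels. From such multi-page TIFF stacks, `redoxdyn` computes:

* the **optical redox ratio**, `ORR = I451 / (I451 + I560)`, at image level
  (ratio of thresholded, background-corrected channel means) and per cell
  per frame;
* **photobleaching**, as the percent change between the means of the first
  and last 10 frames of a continuous acquisition,
  `(I_initial10 − I_last10) / I_initial10 × 100`, per cell for the 451-nm,
  560-nm and ORR series (both sign conventions);
* **contrast SNR**, `(signal mean − background mean) / background sd`, at
  the start and end of a time lapse;
* **stimulus-response kinetics** per cell: pre-stimulus baseline drift,
  onset delay after a stimulus (sustained mean + 3·sd crossing with
  two-line changepoint refinement), initial rise rate (a.u./s), and
  time-to-peak;
* **group comparisons** with the field's decision rule: Shapiro–Wilk
  normality gate on both groups, then Student's t-test or Mann–Whitney U
  at α = 0.05, with `*`/`**`/`***`/`****` annotations.

Because raw data of the kind this pipeline targets is rarely deposited, the
package ships a first-class **synthetic imaging simulator**
(`simulate_timelapse()`): elliptical cell phantoms (dim nucleus, bright
cytoplasm, mitochondrial puncta), monoexponential per-cell photobleaching,
cyanide-type (static ORR shift) and glucose-bolus (delayed per-cell ramp)
perturbations, and a camera model of Poisson shot noise + Gaussian read
noise + offset, quantized to 16 bits — with full ground truth (masks,
noiseless traces, bleach rates, delays, rates) so every estimator is tested
against known answers. Split-frame TIFF reading/writing is built in
(uncompressed baseline TIFF, metadata embedded as JSON in the description
tag).

## Worked example

Simulate a 30-s photobleaching acquisition (4 cells, 2 Hz here for brevity;
the full-scale design is 12 cells at 99.4 Hz × 3000 frames), segment it,
and quantify per-cell bleaching:

```r
library(redoxdyn)

cfg <- simulation_config(n_cells = 4, fov_shape = c(90, 150),
                         cell_radius_px = c(10, 14),
                         n_frames = 60, frame_rate_hz = 2, seed = 42)
sim <- simulate_timelapse(cfg)
cs  <- sim_channel_stack(sim)                    # split into 451/560 stacks

avg <- rowMeans(cs$data_451, dims = 2)           # time-averaged 451 image
seg <- segment_cells(avg, threshold_background(avg))
#> label_mask: 4 cell(s) on a 90 x 150 image (otsu threshold on the 451 channel)

traces <- extract_traces(cs, seg)
pb <- photobleach_report(traces)
pb[pb$metric == "i451", c("cell_id", "initial_window_mean",
                          "final_window_mean", "percent_eq2")]
#>   cell_id initial_window_mean final_window_mean percent_eq2
#> 1       1               134.2             132.2       1.474
#> 2       2               133.6             131.6       1.491
#> 3       3               134.6             133.2       1.054
#> 4       4               136.3             133.9       1.814
```

Each cell lost 1–2% of its raw 451-nm intensity over 30 s at 4.14 mW
(initial/final values are raw camera counts including the 100-count
offset; the per-cell spread comes from the simulator's lognormal bleach-rate
heterogeneity).

A control-vs-cyanide group experiment at one illumination power, 15
simulated images per group, and the gated comparison:

```r
grp <- run_group_experiment(experiment_config(
  "illumination_sweep", conditions = 4.14, n_images = 15,
  sim = list(n_cells = 4, fov_shape = c(90, 150), cell_radius_px = c(10, 14)),
  seed = 7))
aggregate(orr ~ group, grp$table, function(x) round(c(mean = mean(x), sd = sd(x)), 3))
#>     group orr.mean orr.sd
#> 1 control    0.705  0.023
#> 2 cyanide    0.795  0.017
grp$comparisons
#>   condition test_used statistic  p_value significant stars
#> 1      4.14         t     -12.3 9.07e-13        TRUE  ****
```

The cyanide group's ORR is elevated by ≈0.09 (blocked electron transport
accumulates NAD(P)H); both groups pass the normality gate, so a Student's
t-test is used and the shift is significant at `****`.

A command-line interface mirrors the pipeline
(`simulate | split | segment | orr | bleach | dynamics | compare | run`):

```sh
Rscript -e 'redoxdyn::redoxdyn_cli()' simulate --preset glucose --out g.tif --seed 1
Rscript -e 'redoxdyn::redoxdyn_cli()' dynamics --in g.tif --stimulus 8 --out kinetics.csv
```

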