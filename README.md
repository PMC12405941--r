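# beeRF

Analysis pipeline for intracellular recordings from single photoreceptors
of the insect compound eye, centred on the polarization-sensitive dorsal
rim area (DRA) of honeybee (*Apis*) and bumblebee (*Bombus*) eyes.

Bees navigate by the sky's linear-polarization pattern, which they read
with UV-sensitive DRA photoreceptors that combine high polarization
sensitivity (PS) with unusually wide receptive fields (RFs). A striking
feature of DRA recordings is **photoreceptor coupling**: a single
impaled cell can show several disjoint regions of high spatial
sensitivity — its own RF plus the fields of neighbouring, electrically or
neurally coupled cells — separated by low-sensitivity gaps, with
millisecond response-delay offsets and small shifts in the preferred
e-vector angle between the lobes. `beeRF` implements the full analysis
required to quantify these phenomena, plus a ground-truth simulator so
that every stage is testable by parameter recovery without any raw data.

## What the package computes

Given three standard stimulus protocols per cell:

1. **V-log(I)** — intensity series; peak responses are fitted with a Hill
   (Naka–Rushton) function `V(I) = V_max · Iⁿ / (Iⁿ + Kⁿ)`
   (`fit_hill`). Its inverse, `s(r) = (r/(1−r))^{1/n}` with
   `r = V/V_max`, converts any voltage response into an
   equivalent-intensity *sensitivity* (`inverse_hill`).
2. **Grid scan** — a 0.9°×0.9° UV square flashed for 20 ms every 145 ms
   in 1° steps over a 20°×20° grid (21×21 positions, row-major). The
   per-epoch `max − min` responses form the raw spatial-sensitivity map
   (`extract_raw_map`), which is Gaussian-smoothed (σ = 1°,
   `smooth_map`), inverse-Hill transformed and normalized
   (`to_sensitivity`), and fitted with a weighted sum of up to three
   elliptical Gaussians plus a constant offset (`fit_rf`; component count
   by BIC). RF size is reported as the equal-area circular FWHM
   `sqrt(FWHM_major · FWHM_minor)`. Coupling is flagged when ≥ 2
   components exceed 50% of the map maximum and the sensitivity along the
   line between their centres drops below 25% (`detect_coupling`);
   per-component response delays come from matched-filter peak timing
   (`delay_difference`).
3. **Polarizer series** — responses versus e-vector angle; repeats are
   averaged per angle in mV (`average_repeats`), transformed to
   sensitivities, and summarized as `PS = max(s)/min(s)` with the
   preferred angle φ_max from a cos²-model least-squares fit
   (`compute_ps`). PS > 20 is flagged artefactual and excluded.

Cells are then classified into main retina / marginal DRA / DRA
(`classify_cell`: recording depth decides when known; PS, absolute
sensitivity and RF size vote otherwise) and the group statistics are run
(`two_way_anova` with Type-II sums of squares, `shapiro_wilk` residual
checks, `tukey_hsd` with a compact letter display, and the linear model
`fwhm_circ ~ ps + species + eye_region`, `fit_fwhm_ps_model`).

The `ground_truth_cell` / `simulate_*` family generates synthetic voltage
traces for all three protocols from known RF components (with coupling
weights and latency offsets), Hill parameters, cos² polarization tuning,
a ~340 nm A1 pigment template and additive Gaussian noise.

## Worked example

A simulated coupled DRA cell (main RF at (−2°, 1°), secondary at
(5°, 3°) with weight 0.7 and a 3 ms latency lag; true PS 9.7 at
φ_max = 30°; V_max 40 mV, K = 1, n = 1; noise sd 5% of V_max):

```r
library(beeRF)
cell <- ground_truth_cell(
  components = data.frame(
    az = c(-2, 5), el = c(1, 3),
    sigma_major = 1.5, sigma_minor = 1.5, orientation = 0,
    w = c(1, 0.7), latency_ms = c(0, 3)),
  v_max = 40, k_half = 1, n_hill = 1,
  ps_true = 9.7, phi_max_true = 30, noise_sd_mV = 2)

proto <- grid_scan_protocol()
hill  <- fit_hill_trace(simulate_vlogi(cell, 10^seq(-1.5, 1.5,
                                                    length.out = 9),
                                       seed = 1))
scan  <- simulate_grid_scan(cell, proto, seed = 2)
sens  <- to_sensitivity(smooth_map(extract_raw_map(scan, proto)), hill)
rf    <- fit_rf(sens)
```

This prints:

```
<hill_fit> v_max=39.226 mV, k_half=0.9795, n=1.043 (rss=1.3, 9 pts)
<rf_model> 2 component(s), offset=0.021, rss=0.033, quality=high
     role amplitude weight center_az center_el ... fwhm_circ
1    main    0.9412 1.0000    -1.975     1.017 ...     4.095
2 coupled    0.7099 0.7542     4.971     2.975 ...     4.012
```

The Hill parameters land within a few percent of truth; the two RF
components are recovered at their true centres with the secondary's
weight ≈ 0.75 (true 0.7). The circular FWHM (4.1°) slightly exceeds the
generating value (3.5°) because the σ = 1° map smoothing is not
deconvolved — the same convention the FWHM figures of real recordings
carry. Continuing:

```r
detect_coupling(rf, sens)$coupled        # TRUE
delay_difference(scan, proto, rf)        # delta_t main - secondary = -4 ms
                                         # (truth -3 ms; +/- 1 sample @ 1 kHz)
reps <- lapply(1:3, function(r) {
  ep <- epoch_amplitudes(simulate_pol_series(cell, seq(0, 165, 15),
                                             seed = 2 + r),
                         kinds = "polarizer")
  data.frame(angle_deg = ep$payload, response_mV = ep$amplitude_mV)
})
compute_ps(average_repeats(reps), hill)
#> <ps_measurement> PS=8.437, phi_max=30.4 deg
```

The cell is flagged coupled, the latency offset is recovered to the
sampling resolution, and PS/φ_max come back near truth (8.4 vs 9.7;
30.4° vs 30°).

The full demo (12 simulated cells across both species and all three eye
regions, through to the group statistics) is one call:

```r
run_pipeline(pipeline_config(sim = simulation_config(seed = 1)), "out/")
# out/cells.csv, out/report.json, out/cell_###.json
```

or from a shell: `Rscript inst/cli/beeRF.R run --out out/ --seed 1`.

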