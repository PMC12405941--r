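---
title: "Methods: receptive-field, polarization and coupling analysis of bee photoreceptor recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptive-field, polarization and coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(beeRF)
```

This vignette documents the models, numerical choices and open design
decisions behind `beeRF`. It states no empirical result that the test
suite does not itself compute.

## The measurement model

An intracellular electrode records the graded membrane potential of one
photoreceptor while three stimulus protocols run: a graded-intensity
flash series (V-log(I)), a polarizer-angle series, and a grid scan in
which a small UV square (0.9° × 0.9°) flashes for 20 ms every 145 ms at
each node of a 20° × 20°, 1°-step grid, scanning left-to-right then
top-to-bottom. Grid node *k* (1-based, row-major) therefore maps to row
`(k-1) %/% 21 + 1` and column `(k-1) %% 21 + 1`, with the top row at the
highest elevation. All angles tied to the polarizer are axial (e-vector
symmetry): they live on [0°, 180°) and offsets fold to [0°, 90°].

### Intensity–response nonlinearity

Peak responses follow a Hill (Naka–Rushton) curve
\(V(I) = V_\max I^n / (I^n + K^n)\), with \(V_\max\) (mV), the
half-maximum intensity \(K\) (relative intensity units, stored linear)
and the slope \(n\). `fit_hill` minimizes squared error in
log-parameter space (all three parameters are positive), multi-starting
the slope at {0.5, 1, 2} with \(K\) initialized at the intensity whose
response is nearest half-maximum. Requirements — at least 5 points
spanning 2 log₁₀ units — reflect what makes the three parameters jointly
identifiable.

The *inverse Hill transformation* maps a response fraction
\(r = V/V_\max\) to an equivalent intensity
\(s(r) = (r/(1-r))^{1/n}\), the cell's sensitivity in units of \(K\)
(\(s(0.5) = 1\)). \(V_\max\) always comes from the cell's own V-log(I)
fit, never from the grid-scan maximum, so the transformation is anchored
to the cell's full operating range. Because \(s \to \infty\) as
\(r \to 1\), responses are clipped at `r_cap = 0.99` before inversion
and the clipping is flagged; a map or series is afterwards rescaled by
its own maximum so final sensitivities lie in [0, 1].

### Spatial receptive fields

The raw map value at a grid node is the epoch's `max − min` voltage —
the stated extraction rule, which removes the per-epoch baseline. The
raw map is smoothed with a separable Gaussian (σ = 1°, reflect
boundary, kernel radius ⌊4σ + 0.5⌋ px, matching the common ndimage
discretization), then transformed to sensitivity and fitted with

\[ \hat S(x) \;=\; c \;+\; \sum_{k=1}^{K} A_k\,
   \exp\!\big(-q_k(x)/2\big), \qquad K \le 3, \]

where \(q_k\) is the rotated anisotropic quadratic form of component
*k* and \(c\) is a constant offset that absorbs wide low-sensitivity
"brim" regions. Fits use bounded L-BFGS-B (σ ∈ [0.3°, 15°], centres
within the grid ± 2°), initialized from the strongest local maxima after
non-maximum suppression (radius 2°); \(K\) is chosen by BIC with the
residual floored at 10⁻¹⁴ per point so noiseless fits prefer the
smaller model. The largest-amplitude component is the *main cell*
(weight 1, the cell the electrode punctured); others are potential
*coupled* secondaries with weight = amplitude ratio. Axis FWHMs are
\(2\sqrt{2\ln 2}\,\sigma\) and the equal-area circular FWHM is
\(\sqrt{\mathrm{FWHM}_{maj}\,\mathrm{FWHM}_{min}}\).

**Coupling rule.** A cell is coupled when at least two fitted components
each reach > 50% of the map maximum at their centres *and* the map along
the straight line between those centres dips below 25% of maximum
(operationalizing "usually < 20%" with margin; both thresholds are
configuration values). The along-line profile is returned for
diagnostics.

**Response delays.** For each component, the time of maximum response is
the median over its territory's five strongest epochs of the epoch peak
time relative to flash onset; differences are reported at trace
resolution (1 ms at 1 kHz). Per-epoch peak times are located by matched
filtering against a response template averaged from the main component's
strongest epochs, using a per-lag Pearson correlation. Two numerical
points matter here. First, a plain per-epoch argmax is hopeless in the
stated noise regime: the response kernel is flat near its peak, so
white noise at 5% of \(V_\max\) jitters the argmax by several
milliseconds — more than the 0–5 ms offsets being measured — whereas the
matched filter uses the whole waveform and recovers offsets to ± 1
sample. Second, the correlation must be computed as a *normalized*
(Pearson) statistic per lag: raw truncated-window cross-correlation of
mean-subtracted segments drifts systematically toward lag 0 as the
overlap window shrinks. The template is shared by all components, so any
template bias cancels in the main-minus-secondary difference.

### Polarization sensitivity

Repeated polarizer sweeps are averaged per angle in raw mV *before* any
transformation. The averaged series is normalized by the fitted
\(V_\max\), inverse-Hill transformed, and summarized as
\(PS = \max(s)/\min(s)\). The preferred angle φ_max is the maximum of a
least-squares cos² fit rather than the argmax of the sampled comb: the
model \(s(\phi) = A + B\cos 2(\phi - \phi_{max})\) is linear in
\((A, B\cos 2\phi_{max}, B\sin 2\phi_{max})\), so the fit is exact for
cos²-type tuning and resolves φ_max far finer than the 15° sampling
step — necessary because coupled-cell comparisons are made at 3°–5°
resolution. Mean PS above 20 is flagged "artefactual (PS > cap)" and
excluded (near-zero or hyperpolarizing minima make the ratio
meaningless); a non-positive minimum response excludes the measurement
with its own reason rather than erroring.

### Spectral sensitivity

Spectral responses, transformed to sensitivities, are fitted with the
standard A1 visual-pigment alpha-band template (the published
three-exponential closed form in \(x = \lambda_{max}/\lambda\)),
peak-normalized at λ_max and optimized over λ_max alone with the
multiplicative scale solved in closed form. The template's supported
range is [300, 700] nm; UV receptors peak near 340 nm. The band is flat
near its peak, so value-at-λ_max normalization can leave up to ~0.1%
excess at the template's true maximum — harmless for fitting, but worth
knowing when asserting bounds.

## Eye-region classification

Recording depth, when available, always decides the region label
(the topological criterion); numeric criteria then only raise
consistency warnings. Without depth, available criteria vote: PS below
`ps_high` (default 4) is main-retina-like; a Hill \(K\) below
`k_half_ref · sqrt(sensitivity_ratio)` (defaults 0.1 and 10, i.e. the
geometric midpoint of a ten-fold sensitivity gap) counts as "high
sensitivity" (main retina / marginal DRA); circular FWHM at or above 5°
is DRA-like. High PS together with high sensitivity labels the marginal
DRA. These thresholds are package defaults calibrated to typical group
contrasts — the underlying study classified topologically and gave no
numeric cut-offs, so they must not be read as measured constants.

## Group statistics

The two-way ANOVA on PS and FWHM uses `species + eye_region` without
interaction and Type-II sums of squares (each factor added last to the
additive model), appropriate for the unbalanced group counts of
single-cell datasets; interaction is available behind a flag and is then
tested against the full model. Residuals feed a Shapiro–Wilk check.
Tukey's HSD runs on the studentized range with a compact letter display
at α = 0.05 (insert-and-absorb over the non-significance graph). The
size–sensitivity model `fwhm_circ ~ ps + species + eye_region` uses
treatment coding with reference levels (Apis, main retina) so
coefficient signs read as marginal-DRA and DRA offsets relative to the
main retina; rank deficiency is detected by QR and reported with the
collinear columns. Only main-cell properties enter these tables;
PS-excluded cells are dropped from PS analyses but keep contributing
their FWHM (the source text does not settle this; the permissive default
is documented here).

## The synthetic world

`ground_truth_cell` fixes everything the estimators later recover: RF
components (centre, axes, orientation, weight, latency), Hill
parameters, true PS and φ_max, λ_max = 340 nm, and the noise level.
Choices the source protocol does not pin down:

* **Response kernel** — a shape-3 gamma, \(g(t) \propto t^2 e^{-t/\theta}\),
  peak-normalized with time-to-peak 30 ms (θ = 15 ms). Response kinetics
  are not described in the source; the kernel only needs to be smooth,
  unimodal and shared across components so latency offsets (0–5 ms)
  carry the delay signal.
* **Polarization tuning** — cos² (Malus-type) with floor \(1/PS\):
  \(f(\phi) = 1/PS + (1 - 1/PS)\cos^2(\phi - \phi_{max})\). Only the PS
  ratio is specified by the source; this standard microvillar model
  reproduces it exactly.
* **Noise** — additive white Gaussian, sd 5% of \(V_\max\). The simplest
  falsifiable choice; real membrane noise is low-pass, so white noise is
  *harsher* on peak-based estimators than reality (see below).
* **Flash intensity** — \(I_0 = 3K\): bright but sub-saturating
  (\(r = 0.75\) at the RF centre for \(n = 1\)).
* **Coupled cells** — drawn with separation 6–9° and component FWHM at
  most 0.45 × separation, so the two high-sensitivity regions are
  genuinely split by a valley below ~20% of maximum; secondary weights
  are 0.55–0.9 (clearly above the half-maximum coupling criterion — a
  secondary *below* half maximum is undetectable by that criterion by
  definition) and latencies lag 0–5 ms. Hyperpolarizing opponent
  components are representable (negative amplitude) but default off.
* **Population defaults** — main retina: FWHM 2–4°, PS 1.2–3,
  K 0.08–0.15, n 0.6–1.0; marginal DRA: FWHM 4–6.5°, PS 4–9, sensitive;
  DRA: FWHM 5–9°, PS 4–12, K ten-fold higher, n 0.9–1.2, coupling
  probability 0.25 (the observed fraction of coupled DRA recordings).

Identical seed and configuration give bit-identical traces and
pipeline outputs.

### What a green test establishes — and what it does not

The simulator emulates the *protocols* and the *parametric structure* of
the recordings: grid timing, Hill saturation, cos² tuning, multi-lobed
RFs, latency lags, stationary noise. It does not model phototransduction
dynamics, photon shot noise, membrane filtering, electrode drift,
adaptation, eye movements or optics (lens, pore canals, the 0.9°
stimulus footprint). Parameter recovery on this world therefore
validates the *estimators* — their algebra, their bias behaviour under
stationary noise, their determinism — not the biological accuracy of any
particular published group mean. Those group means are statistics of the
deposited raw recordings and are out of reach without them, which is why
acceptance for this artifact is property-based.

## Numerical choices worth knowing

* **Background pedestal.** The `max − min` epoch extraction adds the
  expected *range* of the noise (≈ 5 sd for white noise at 1 kHz over a
  145 ms epoch) uniformly to every grid node. Left in place, this
  pedestal is amplified by the convex inverse Hill transform and can
  push the map peak into the clipping region. `to_sensitivity` therefore
  subtracts the map minimum (quantile 0 — the quietest node defines zero
  response, echoing the per-epoch minimum-subtraction idea) before
  dividing by \(V_\max\). On a noiseless map the subtraction is zero and
  the sensitivity map reproduces the generating profile exactly.
* **Epoch amplitudes elsewhere.** For V-log(I) and polarizer epochs
  (where the extraction rule is not pinned), the default estimator is
  the lightly smoothed epoch peak minus the mean of the trailing quarter
  of the epoch: no extreme-value bias, and its small multiplicative
  attenuation cancels whenever the Hill fit and the transformed series
  come through the same estimator.
* **Smoothing bias.** σ = 1° map smoothing inflates fitted FWHMs
  (strongly for the narrowest fields); it is not deconvolved, matching
  the reporting convention for real recordings. Recovery tests bound the
  resulting relative error rather than pretending it away.
* **Degenerate inputs.** Flat maps, flat spectra, all-equal responses,
  < 2 factor levels, groups with < 2 observations and zero-variance
  residual vectors all raise typed errors (or flags, where the
  measurement should survive) rather than numeric surprises.
* **Ties and orientation.** σ_major < σ_minor after optimization is
  fixed by swapping axes and rotating 90°; orientations are reported
  mod 180°.

## Known limitations

* FWHM estimates carry the smoothing footprint (no deconvolution of
  either the σ = 1° filter or the 0.9° stimulus).
* The coupling rule is the stated threshold rule; secondaries below half
  maximum, or lobes so wide they merge, are by definition not flagged.
* `delay_difference` needs usable epochs in each component's territory;
  territories whose strongest epochs sit below the noise floor return
  `NA` for that component.
* Classification thresholds are conventions, not measurements; depth
  metadata always wins when present.
* The native format of acquisition software is out of scope: the
  CSV/JSON interchange contract (`time_s,voltage_mV` plus a marker
  sidecar) is the boundary a converter must meet.
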