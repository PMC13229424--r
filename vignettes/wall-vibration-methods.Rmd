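---
title: "Quantifying flow-induced vascular wall vibrations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flow-induced vascular wall vibrations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vesselvib` post-processes time-resolved vessel-wall fields — displacement
and wall traction on a triangulated surface, with a centerline — into the
vibration, spectral, and hemodynamic metrics used to characterize
arteriovenous fistula (AVF) remodeling, and compares patient groups with
mixed-effects models. This vignette records the model, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design decisions taken where the procedure was genuinely open.

Units are fixed package-wide: geometry in mm, time in s, traction in Pa,
frequencies in Hz. Vibration amplitudes are reported in μm.

## The measurement pipeline

**High-pass vibration amplitude.** The displacement field `u(x, t)` is
filtered per node and Cartesian component with a zero-phase high-pass
above `highpass_cutoff_hz` (default 25 Hz — above all cardiac harmonics,
below the 45–100 Hz vibration bands of interest). The realization is an
order-4 Butterworth applied forward and backward (`filtfilt`), on traces
padded by odd reflection over three cutoff periods to suppress edge
transients. The combined response `|H|²` attenuates content at half the
cutoff by ≈48 dB and stays within 0.4% of unit gain above twice the
cutoff; a brick-wall FFT filter serves as the independent oracle in the
tests (≤2% RMS disagreement on interior samples). The *vibration
amplitude* is the time average, over a whole number of cardiac cycles, of
the Euclidean magnitude of the filtered displacement — a time-averaged
magnitude, not an RMS or envelope. The *99th spatial percentile* of the
magnitude, per timestep, tracks the vibration through the cycle; its
maximum and time average give the peak and cycle-averaged amplitudes.
Percentiles interpolate linearly between order statistics at plotting
positions `k/(n+1)` (`quantile` type 6), under which 100 values 1…100
give 99.99 at q = 99; the convention is exposed and fixed for
reproducibility.

**High-pass strain.** Per surface triangle, the in-plane Green–Lagrange
tensor of the filtered displacement restricted to the element plane,
`E = ½(F'F − I)` in the triangle's reference frame; the scalar is the
largest absolute principal value, time-averaged over whole cycles and
mapped to nodes by area-weighted averaging. Filtering precedes
differentiation (filter-then-strain); for the linear part of the strain
the two operations commute, and this order keeps the contract simple.
The full (not linearized) tensor is used, so rigid rotations produce
exactly zero strain; uniform inflation of a tube by stretch λ produces
exactly `(λ² − 1)/2` on the polygonal cross-section. Whether a reported
scalar strain should be principal-value, von-Mises-like or a tensor norm
is not determined by the source material; the largest absolute principal
value was chosen as the most interpretable bound.

**Spectrograms and band detection.** The spectrogram input is the JAV
spatial mean of the *outward-normal component* of the high-pass
displacement. Two effects force this choice: magnitude-based statistics
of a zero-mean oscillation are rectified (their spectral content appears
at twice the physical frequency unless a dominant colinear carrier
linearizes them), and averaging over a vessel cross-section cancels all
non-axisymmetric spatial modes. The signed normal projection preserves
the band frequencies through the axisymmetric component. The STFT uses a
Hann window of `spectrogram_window_s` (default 0.2 s → 5 Hz resolution)
with 90% overlap, one-sided PSD in (unit)²/Hz, dB re 1 unit, floored at
−120 dB. The 0.2 s default follows from two constraints: the window must
span several cutoff periods (≥ 4/25 s = 0.16 s), and the Hann main lobe
(±2 bins) must not bridge the ~25 Hz valley between the stenosis band
pair, which a 0.1 s window does. Band detection runs on the time-averaged
PSD within `[cutoff, band_fmax_hz]` (default up to 200 Hz, the range in
which wall-displacement bands occur): supra-threshold runs are merged
when gaps are narrower than `band_min_gap_hz` (10 Hz), discarded when
narrower than `band_min_width_hz` (8 Hz), and centered at power-weighted
centroids. The default threshold is *relative*: the larger of
(median supra-cutoff PSD + 10 dB) and (peak − 15 dB). A band must rise
above the broadband floor *and* be within the prominence drop of the
strongest peak; a flat broadband plateau is its own median and is never
flagged. Absolute dB thresholds are available (`mode = "absolute"`) but
are not the default because the absolute reference of reported dB levels
is convention-dependent.

**Wall-shear indices.** From solver-exported wall traction vectors τ:
TAWSS `= (1/T)∫‖τ‖dt`; OSI `= ½(1 − ‖∫τ dt‖/∫‖τ‖dt)` (0 unidirectional,
0.5 full reversal, defined 0 for zero traction); SPI = fraction of the
mean-removed traction-magnitude power above the same 25 Hz cutoff,
computed from the periodogram — the cutoff is shared with the vibration
metrics deliberately, so "high-frequency" means the same thing across the
pipeline. The Q-criterion `½(‖Ω‖²_F − ‖S‖²_F)` consumes velocity-gradient
tensors directly; the pipeline does not attempt finite-element gradient
recovery from volumetric velocity, since solvers export these fields.

**Slicing.** Nodes are projected to the nearest point of the centerline
(segment-wise orthogonal projection) and binned half-open by arclength,
`[k·spacing, (k+1)·spacing)`, over the first `slice_extent_mm` = 25 mm of
the JAV with `slice_spacing_mm` = 1 mm — 25 slice means per patient per
metric, the unit of statistical analysis. The source material is
internally inconsistent on spacing (0.1 mm in one place, 1 mm and "25
values per patient" elsewhere); 1 mm is the default because 25 values is
the quantity the statistics actually use, and 0.1 mm remains available as
a configuration override. Projection-binning rather than exact
plane–mesh intersection is used for robustness on coarse meshes; on a
curved vessel with curvature radius ≥ 5× the lumen radius the two
assignments agree on ≥95% of nodes (tested against the plane-cut oracle).
Slice means are unweighted node means (area weighting available); slices
with fewer than three nodes are flagged and excluded from statistics.

**Group statistics.** Per metric, a random-intercept model
`value ~ group + (1 | patient)` is fitted by maximum likelihood (ML
rather than REML so likelihoods stay comparable across fixed-effect
structures). If the Shapiro–Wilk test on the Gaussian residuals rejects
at 0.05, the model is refitted as a Gamma GLMM with log link (Laplace
approximation) — the appropriate family for positive, right-skewed
amplitude data — and that family is reported. The two-group analysis
contrasts Patency against pooled Adverse remodeling at α = 0.05; the
three-group analysis contrasts stenosis and dilatation against patency
at the Bonferroni level α/3 = 0.0167. **Degrees of freedom:** group
contrasts compare patients, of which there are six; Wald statistics are
therefore referred to a t distribution with (patients − groups) degrees
of freedom for both families. With a plain normal reference the test
rejects ≈16% of null cohorts at the 5% level in simulation; with t(4) the
empirical size is ≈7% and the headline contrast still reaches p < 0.01 in
the majority of simulated cohorts at the observed effect sizes. A
patient-level permutation test is provided as a distribution-free
cross-check (note its two-sided resolution floor of 2/15 with 6
patients). The WSS–vibration correlation fits
`vibration ~ index + (1 | patient)` and reports the *conditional
correlation coefficient R*, defined here as the Pearson correlation
between observations and the conditional (fixed + random) fitted values —
one of several possible readings of "conditional R", chosen and
documented; slope p-values use residual-scale df since the covariate
varies within patient.

## The synthetic generator

The generator emulates what the analysis assumes about real AVF wall
motion: (a) quasi-static cardiac pulsation — a radial excursion of
0.05 mm composed of decaying harmonics at 1–3 Hz; (b) narrowband
vibration localized in the JAV — band-limited Gaussian processes
(frequency-domain synthesis, cosine-tapered inside the declared band
edges so the component's power stays within its bands) shaped by a
raised-cosine axial envelope floored at 0.45; and (c) a white noise floor
of 0.05 μm per node.

**Mode structure.** Vibration is a mixture of *bending* modes — rigid
lateral translations of each cross-section, axially correlated over a
coherence length L — and a small *breathing* (radial, axisymmetric)
fraction β = 0.1. This structure is forced by the calibration targets:
coherent wall-normal motion of a tube of radius R produces hoop strain
`w/R`, pinning strain/amplitude at ≈ 0.29/mm for a 3.5 mm vessel, five
times the observed clinical ratios (≈ 0.05/mm). Ring translations are
inextensional at leading order; their membrane strain comes from the
axial gradient of the displacement and scales as amplitude/L, making L
the strain calibration knob, while the breathing fraction (strain floor
`β·amplitude/R`) carries the axisymmetric spectral signature the JAV-mean
trace sees.

**Self-calibration.** The generator is calibrated per vessel, in order:
the overall vibration scale is set so the slice-mean time-averaged
amplitude of the band component matches the target (the bands lie in the
filter passband, so the unfiltered component is an accurate stand-in);
then L is adjusted by a log-space secant iteration (bounded to
1.5–80 mm) until the slice-mean Green–Lagrange strain of the *physically
scaled* field is within 3% of its target — the full tensor is mildly
nonlinear in amplitude, so calibrating on an unscaled field and rescaling
biases the result; if the strain target is below the breathing floor, β
is relaxed. After assembly the realized amplitude is verified on the
genuinely high-pass-filtered series and must fall within 5% of target.

**Group presets** encode the three observed regimes: patency — broadband
25–200 Hz content at 6.6 μm / 0.30×10⁻³; stenosis — two bands, 55 Hz
(stronger, 2:1 power) and 90 Hz, at 31.7 μm / 1.68×10⁻³; dilatation — a
single 50 Hz band at 15.9 μm / 1.00×10⁻³. The stenosis band centers sit
inside the clinically observed 45–100 Hz range (individual patients show
pairs such as 55–65 & ~100 Hz or 45–50 & 70–75 Hz); the lower band is
assigned the larger power because it dominates the observed spectra,
with the exact ratio a free parameter. Cohorts draw per-patient targets
through a single truncated-normal severity factor that shifts amplitude
and strain together (the two co-vary physically, and the coupling makes
per-patient targets jointly attainable). The reported ±SD values are
treated as slice-pooled totals and split into a between-patient part
(fraction 0.3 of the SD) and a within-patient across-slice part
(√(1−0.3²) ≈ 0.95) — the across-slice spread along the 25 mm of analyzed
vein is taken to dominate, consistent with wide per-patient boxplots.
The group targets are the three-group values; the pooled adverse mean of
a 2+2 cohort is therefore ≈ 23.8 μm, slightly above the separately
reported pooled value of 22.5 μm, which is an internal feature of the
source statistics, not a calibration error. For inference-scale
simulation (hundreds of cohorts) `simulate_slice_table()` draws slice
values directly — Gamma within patient around the drawn target — rather
than synthesizing displacement fields.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: no hemodynamics (no Navier–Stokes, no FSI
coupling, no Womersley profiles) — the traction generator produces
controlled index values, not flow physics; idealized straight tubes, not
patient-specific lumen geometry; stationary band processes, whereas real
vibration waxes and wanes within the cycle (systolic bursts); vibration
direction restricted to the m = 0/m = 1 shell modes; and no measurement
or segmentation error. Recovery of the printed group statistics by the
pipeline demonstrates the *pipeline's* correctness and the calibration's
fidelity, not clinical validity of the thresholds.

## Numerical choices and problem sizes

Defaults used throughout the workflow and tests, chosen as realistic
study conditions: cardiac period 1.0 s (configurable; used when a series
records none); sampling 2 kHz for 3 cycles (6000 steps — comfortably
above the 10-samples-per-period rule for the highest 200 Hz content, and
enough cycles for 5 Hz spectral resolution with time averaging); tube
radius 3.5 mm (cephalic-vein caliber), length 30 mm, tessellated 40 × 24
(960 nodes) for cohort work. Strain evaluation processes timesteps in
chunks of 400 to bound memory. The inference studies use 100 cohorts for
power and 400 for empirical size; the correlation recovery uses 50
replicates. Degenerate inputs: zero-variance group data short-circuit the
mixed model to the exact group difference with p = 0; constant signals
have SPI 0 by definition; zero traction has OSI 0; empty spectra yield an
empty band set rather than an error.

## Known limitations

Wald/t inference with six patients remains approximate — the permutation
cross-check is deliberately included, and its own resolution is limited.
The Gamma fallback keys on a single Shapiro–Wilk threshold (0.05), so
cohorts near the boundary may flip family between seeds; contrast signs
agree between families on well-separated data (tested). Band detection
reports centroid frequencies robustly but band *widths* inflate with
spectral leakage at 5 Hz resolution. The on-disk field container stores
15 significant digits, which is below double precision round-trip
fidelity. Centerlines must be supplied (or come from the generator);
no automatic centerline extraction is provided.
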