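---
title: "MEG microstate analysis with megastate: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEG microstate analysis with megastate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megastate)
```

## The microstate model

Resting-state M/EEG activity can be described as a sequence of *microstates*:
quasi-stable spatial patterns (topographies) of the sensor field, each
lasting tens of milliseconds, that succeed one another abruptly. The model
has three ingredients:

* a small set of class maps $a_1, \dots, a_K$ (unit-norm, zero-mean
  topographies over the sensors),
* a label sequence $L(t) \in \{1..K\}$ assigning each sample to one class,
* an amplitude process: the observed frame is
  $x_t \approx g_t \, s_t \, a_{L(t)} + \varepsilon_t$, with $g_t > 0$ the
  momentary field strength, $s_t \in \{-1, +1\}$ an (ignored) polarity, and
  $\varepsilon_t$ sensor noise.

Polarity is not informative for MEG microstates, so every similarity in the
package defaults to the *absolute* spatial Pearson correlation
$|C(x, a)|$; a signed mode is available via `polarity_invariant = FALSE`.

`megastate` implements the standard analysis chain on this model:

1. **GFP and peak maps.** The global field power
   $\mathrm{GFP}_t = \mathrm{sd}_{\text{sensors}}(x_t)$ (population
   convention, divisor $n$) indexes momentary signal-to-noise; topographic
   maps are extracted at its strict local maxima
   (`global_field_power()`, `extract_gfp_peaks()`).
2. **Modified k-means.** Peak maps are clustered by the polarity-invariant
   k-means: assignment by maximal squared spatial correlation, centroid
   update as the dominant eigenvector of the assigned maps' outer-product
   sum (the arithmetic mean would cancel opposite-polarity maps). The best
   of `n_restarts` random initialisations by global explained variance is
   kept (`kmeans_microstates()`).
3. **Model selection.** The group GEV-vs-K curve (forced non-decreasing by
   cumulative maximum) is fed to the discrete Kneedle knee-point rule
   (`kneedle_optimal_k()`, sensitivity $S = 1$).
4. **Two-level clustering.** Subject-level class maps are pooled and
   re-clustered to grand-mean group maps (`group_level_maps()`), which are
   backfitted to every sample of every recording (`backfit()`). Classes are
   labelled Ms1..MsK by descending total coverage — a deterministic,
   data-driven ordering.
5. **Parameters.** Per class: mean duration (ms), occurrence (/s), coverage
   (%), plus the run-level transition matrix with self-transitions excluded
   (`microstate_metrics()`, `transition_probabilities()`). The identity
   $\text{coverage}/100 = \text{occurrence} \times \text{duration}/1000$
   holds exactly by construction.

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \, C(x_t,
a_{L(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2}$$

## Preprocessing

* **Filtering** (`bandpass_notch()`): 1–40 Hz Butterworth band-pass
  (4th-order high-pass and low-pass) plus a 50 Hz notch biquad with quality
  factor 30, all applied forward–backward for zero phase. The Butterworth
  polynomials are factored into second-order sections: a direct-form
  order-8 band-pass with a 0.002 normalised lower edge is numerically
  ill-conditioned (we measured linearity violations around $3\times10^{-5}$
  relative; the cascaded biquads restore $10^{-12}$). Channels are extended
  by odd reflection (three periods of the low edge) before filtering to
  suppress start-up transients.
* **Bad channels** (`detect_bad_channels()`): total 1–40 Hz power from a
  Hann-windowed 50%-overlap averaged periodogram, flagged when the robust z
  of the log power (median/scaled-MAD) exceeds 3. Flagged channels are
  dropped cohort-wide, not interpolated: interpolation would re-enter the
  clustering as a linear combination of kept channels and bias the maps.
* **Spatial filter** (`spatial_neighbor_filter()`): each sensor is replaced
  by the midrange $(\max + \min)/2$ of its six nearest neighbours (self
  excluded), frame-wise — an extremum-guided smoother. A
  neighbourhood-mean variant (self included) is available via
  `method = "mean"`. On a 64-sensor helmet the neighbour spacing is coarse
  (~0.33 rad), so even smooth fields are attenuated by roughly 15–25% RMS;
  the filter's defining property, which the tests assert, is the contrast:
  single-sensor spikes are eliminated entirely while smooth fields change
  far less (RMS change below a calibrated 0.35).
* **ICA** is deliberately a no-op hook: the pipeline accepts pre-cleaned
  data, and the synthetic cohorts contain no ocular or cardiac artifacts.

## The synthetic cohort generator

The generator produces exactly the data structure the analysis assumes, so
every stage can be validated against stored ground truth:

* **Layout**: Fibonacci (golden-angle) lattice on the upper unit
  hemisphere — quasi-uniform full-head coverage, deterministic
  (`make_sensor_layout()`; 64 sensors by default).
* **Templates**: Gaussian-kernel-smoothed white noise over the helmet
  (length scale 0.6), centred, normalised, rejection-sampled until all
  pairwise $|r| \le 0.7$ (`make_templates()`).
* **Dynamics**: a semi-Markov chain — per-state geometric dwell times (in
  samples), parameterised by mean dwell in ms, and a conditional jump
  matrix with zero diagonal (`transition_model()`,
  `simulate_state_sequence()`). The geometric law is the simplest one
  consistent with quasi-stable 40–120 ms segments and a first-order
  transition analysis; the default mean dwell is 60 ms. The initial state
  is drawn from the stationary coverage distribution
  $\pi_i d_i / \sum_j \pi_j d_j$ so realised class fractions are unbiased.
* **Rendering** (`render_recording()`): active map × smooth positive
  envelope (rectified Gaussian-smoothed noise, floored at 10% of its mean,
  mimicking GFP fluctuation), with each run's polarity flipped with
  probability 0.5 — this is what forces the analysis to be genuinely
  polarity-invariant. Independent Gaussian sensor noise is scaled so the
  array-wide RMS amplitude ratio equals `snr` (default 5). Absolute units
  are arbitrary: no amplitude calibration of the emulated instrument is
  attempted, and there is no biophysical forward model.
* **Cohorts** (`simulate_cohort()`): 25 patients and 18 controls by
  default, 64 channels, 1000 Hz, 480 s. Group effects are injected by
  shifting the stationary coverage of chosen classes in the patient group;
  the shift is implemented by closed-form rescaling of that class's dwell
  time (`adjust_model_coverage()`), which leaves the jump matrix intact and
  is exact in expectation. Between-subject variability is modelled by
  per-subject log-normal multipliers (log-SD 0.2) on the dwell means,
  chosen so that between-subject coverage SD is about 3 percentage points —
  the order reported for real cohorts — and so that the default +4 pp
  injected coverage effect corresponds to a standardised difference near
  1.2. Setting `subject_dwell_sd = 0` gives exchangeable subjects, which is
  what the generator-correctness checks use.
* **Clinical tables** (`simulate_clinical_table()`): per-group (truncated)
  normal draws whose default moments reproduce a published two-group
  demographic table (age, sex, education, depression and anxiety scores,
  plus patient-only headache measures); an optional coupling injects a
  target Pearson correlation between one clinical score and a supplied
  per-subject metric to exercise the correlation screen.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: physiological artifacts, spatially
correlated or non-stationary noise, inter-subject topography variability
(all subjects share the template set), volume-conduction structure, and any
instrument physics. The generator validates the *algorithms*, not the
neurophysiology.

## Statistics

* **Demographics**: two-sample t-tests computed directly from group
  summaries (`ttest_from_summary()`). Published tables rarely state the
  variance treatment; the default policy uses Welch when the sample
  variance ratio exceeds 4 and the pooled test otherwise, and both variants
  are exposed. Sex distributions use Fisher's exact test by hypergeometric
  enumeration with an absolute tie tolerance of $10^{-12}$
  (`fisher_exact_2x2()`).
* **Group contrasts** (`glm_group_comparison()`): Gaussian identity-link
  linear model `outcome ~ group + education + HAMD24 + HAMA14`, the
  simplest GLM consistent with continuous percentage/rate outcomes; the
  group coefficient is reported with a t-based two-sided p. With no
  covariates this reduces exactly to the pooled t-test (tested to
  $10^{-10}$).
* **Multiplicity** (`fdr_bh()`): Benjamini–Hochberg within families; the
  default family policy groups by parameter type (coverage, occurrence,
  duration — each across the K classes) and one family per
  transition-source row, mirroring how such results are reported
  per-panel; a global family is available.
* **Sensitivity** (`evalue_sensitivity()`): the adjusted difference is
  standardised ($d$ = estimate / residual SD), converted to an approximate
  risk ratio $RR = e^{0.91 d}$, and transformed by
  $E = RR + \sqrt{RR(RR - 1)}$; the lower control limit applies the same
  transform to the 95% confidence bound closer to the null (1 if the
  interval crosses the null).
* **Complementary logistic regression** (`logistic_complementary()`):
  `group ~ parameter + covariates` with Wald p; complete or
  quasi-separation is detected and flagged rather than estimated.
* **Exploratory correlations** (`pearson_screen()`): Pearson r within the
  patient group only (headache measures exist only there), p-values
  deliberately uncorrected and flagged exploratory.

## Numerical and degenerate-input conventions

* Backfit ties go to the lowest class index; zero-variance frames are
  unassigned (`NA`), and `min_corr = 0` by default so all frames are
  assigned and coverages sum to exactly 100%.
* Occurrence uses assigned time as its denominator (equal to total time at
  the defaults), keeping the coverage identity exact when a correlation
  threshold is used.
* No temporal smoothing or minimum-duration rejection is applied by
  default.
* Empty k-means clusters are re-seeded from the worst-explained map;
  convergence is a relative GEV change below $10^{-6}$.
* Transition rows with no departures are all-zero and flagged, never
  renormalised; unassigned stretches break run adjacency.
* All generators and the pipeline are bit-reproducible for a fixed seed;
  subject-level seeds are derived from the master seed by a fixed linear
  congruential rule kept below $2^{31}$.

## Design choices where the field leaves room

* **Knee selection input**: GEV-vs-K (rather than a dispersion measure);
  the sweep defaults to K = 2..8.
* **Spatial filter reading**: the midrange-of-neighbours rule is the
  default interpretation of extremum-based neighbour interpolation; the
  neighbourhood mean is the alternative behind a switch.
* **Class ordering**: descending group-level coverage, which is
  deterministic; note this means class labels are not comparable across
  independent runs except through topography matching (the tests match
  output classes to generating templates by maximal $|r|$ before comparing
  parameters).
* **Container**: recordings travel as a delimited-text matrix plus JSON
  sidecar (sampling rate, sensor positions, run-length-encoded truth
  labels); the data payload is written at full precision (`%.17g`) so the
  round trip is bit-exact.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
synthetic cohorts at sizes chosen to exercise every code path while staying
lightweight: transition/dwell recovery uses a single 480 s, 1000 Hz label
sequence; segmentation checks use 5–10-subject cohorts at 32 sensors,
200 Hz, 30 s, SNR 5; calibration of the group statistics uses the study's
group sizes (25 vs 18) with 500–2000 Monte-Carlo replicates; and the
end-to-end detection check runs 20 seeded pipeline replicates at 25/18
subjects, 24 sensors, 200 Hz, 60 s. Two of these checks pin conditions the
problem leaves open, and the choices matter enough to state:

* **Class-count selection.** Knee-point recovery of the planted K = 6 is
  checked on cohorts whose templates satisfy pairwise $|r| \le 0.4$. With
  strongly correlated templates (the generator default allows up to 0.7),
  merging two similar classes costs little GEV, the curve turns concave
  before its plateau, and the discrete Kneedle rule — by its own
  definition, not by implementation error — places the knee at K − 1. Six
  planted states are only *identifiable* as six when their maps are
  separated; the check tests the selection machinery under identifiable
  conditions.
* **Effect detection.** The detection cohort tightens the between-subject
  dwell jitter (log-SD 0.12 instead of the default 0.2) to offset the
  coverage-estimation noise that 60 s recordings add relative to
  full-length (480 s) ones, keeping the cohort's standardized group
  difference at the intended detectable level; and it simulates clinical
  covariates exchangeable between groups
  (`clinical_params = "exchangeable"`), isolating detection of the
  microstate effect from the separate question of power loss under
  covariate–group collinearity (with the default demographically
  imbalanced covariates, which are pure noise with respect to the outcome,
  the group coefficient's standard error inflates by ~1.6×).

On these cohorts the six-class solution explains a higher share of
GFP-weighted variance than is typical for real MEG (the generator's states
are clean by construction), so GEV levels themselves are not comparable to
empirical reports — recovery rates and calibration, not GEV magnitude, are
the meaningful outcomes. Band-pass filtering also smears state boundaries
(ground-truth label accuracy drops from ~0.97 on raw renders to ~0.65
after filtering), diluting injected coverage effects by roughly a fifth —
worth remembering when translating effect sizes between the generator
scale and the analysis scale.

## Known limitations

* No source localisation, atlas mapping, or comparison to canonical EEG
  classes A–D; no ICA; no vendor file formats (an import hook would sit at
  `read_recording()`).
* The E-value conversion assumes the standard approximate
  risk-ratio mapping for continuous outcomes; it is a sensitivity
  heuristic, not an identification result.
* Exploratory correlations are reported uncorrected by design and should
  be treated as screening output.

```{r quick-example, eval = FALSE}
# a complete miniature analysis (about half a minute)
cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 8, n_controls = 6, n_sensors = 32,
                         fs = 200, duration_s = 30, K = 6, snr = 5,
                         coverage_effects = c(Ms2 = 0.04), seed = 1),
  cluster = list(k_min = 6L, k_max = 6L, n_restarts = 10L,
                 max_iter = 500L, tol = 1e-6, polarity_invariant = TRUE),
  seed = 1)
res <- run_pipeline(cfg, tempdir())
cat(res$report, sep = "\n")
```
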