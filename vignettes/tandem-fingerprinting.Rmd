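---
title: "Untargeted fingerprinting of tandem-ionization GCxGC-TOF MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted fingerprinting of tandem-ionization GCxGC-TOF MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemgc)
```

## The analytical problem

Comprehensive two-dimensional gas chromatography with time-of-flight mass
spectrometry (GCxGC-TOF MS) separates complex metabolome extracts on two
coupled columns: a modulator re-injects the first-column effluent every
few seconds onto a short second column, so every analyte is located by a
first-dimension retention time (minutes) and a second-dimension retention
time (seconds) and appears as a 2D peak on the total-ion-current (TIC)
image. Tandem (variable-energy) ionization acquires two interleaved data
streams in a single run: a hard 70 eV channel with classical, fragment-rich
spectra suitable for library identification, and a soft low-energy channel
(12 eV) with roughly an order of magnitude lower absolute response but
spectra re-weighted toward high-m/z, structure-diagnostic fragments. A
third, *fused* stream is the point-wise sum of the two.

`tandemgc` implements the full untargeted fingerprinting workflow for such
data -- background subtraction, 2D peak detection, spectral-similarity-
constrained template alignment across runs, reliable-peak selection,
composite chromatograms, peak-region quantification, class-discriminant
statistics, retention-index identification and fuzzy-ratio class
comparison -- together with a synthetic dual-energy generator that
provides ground truth for every stage. No public raw data exist for the
acquisition design the package emulates, so the generator is first-class,
tested code: all end-to-end claims in this package are claims about
recovery of known, injected truth.

## The synthetic-data generator

`simulate_run()` renders each library compound as a 2D Gaussian blob
(default sigma of 1 modulation in the first dimension and 0.05 s in the
second; the underlying instruments' peak shape is not published, and a
separable Gaussian is the conventional idealization). Its first-dimension
position comes from the compound's linear retention index through a
configured n-alkane ladder (C7-C30, eluting at `0.8 + 0.45 (n - 7)` min by
default): temperature-programmed elution makes retention essentially
linear in carbon number, which the ladder encodes without modelling
thermodynamics. Key default parameters of `synth_config()`:

* **Acquisition**: 5 s modulation period, 50 Hz per channel (250 samples
  per modulation), unit-spaced nominal masses 45-500 Da. The m/z window is
  a mass filter: fragments outside it are dropped and the spectrum
  renormalized, so deposited TIC volume does not depend on the window.
* **Retention jitter**: multiplicative Gaussian, 0.20% RSD in the first
  dimension and 1.90% in the second -- the repeatability level of the
  emulated acquisition -- shared between channels of a run, since both
  channels observe the same elution.
* **Background**: column-bleed baseline carried by the classical siloxane
  masses (73, 147, 207, 281, 355), with a monotone first-dimension ramp
  (40% peak-to-peak) and Gaussian noise whose TIC-pixel standard deviation
  is 5,000 counts at 70 eV and 50 counts at 12 eV -- the levels implied by
  mapping a signal-to-noise gate of 100 onto the 500,000 / 5,000 count
  thresholds of the two channels. Poisson shot noise applies to the
  deposited signal. Counts are rounded to integers (detector counts),
  which also makes the text run container exact.
* **Responses**: per-compound 70 eV response factors are lognormal around
  4e6 counts; 12 eV responses are lower by a lognormal factor centred on
  10 (one order of magnitude). A configurable fraction of compounds can be
  made effectively invisible at 12 eV to study fusion benefits.
* **Study design**: 4 QC + 3 MHO + 5 MUO subjects x 2 process x 2
  analytical replicates = 48 runs. Abundances follow a lognormal
  hierarchy: subject CV 15%, process CV 8%, analytical CV 8% (together
  ~11-12% technical RSD, matching the QC repeatability of the emulated
  study; the subject level is a moderate biological-variability choice --
  the class effects are defined on class means, and larger values are
  configurable).
* **Class effects**: MUO runs scale each compound's abundance by a
  MUO:MHO ratio; the named reference entries default to the percent
  differences of the emulated study's discriminant-metabolite table under
  the `(MUO - MHO)/MHO x 100` convention (+325.2% becomes a ratio of
  4.252). That convention is a package decision: the source table does not
  print its formula, and its text and table disagree slightly for one
  analyte, so the table's values are taken as printed.

Sixteen library entries are fixed and named (`reference_compounds()`),
mirroring discriminant metabolites with their printed retention indices
and second-dimension times; their dual-energy spectra are synthetic but
follow TMS-derivative logic (silyl fragments 73/129/147 dominating at
70 eV, high-mass fragments such as 202/319/333 for
N-acetyl-D-glucosamine enhanced at 12 eV). Randomly generated entries are
spaced at least 40 retention-index units apart or forced at least 0.4 s
apart in the second dimension, because two compounds closer than the peak
width in both dimensions are physically unresolvable and would only
measure the generator, not the pipeline.

What the generator deliberately does **not** emulate: detector
saturation, mass-spectral skewing across a peak, non-Gaussian tailing,
wrap-around of late second-dimension eluters (blobs near the modulation
boundary may split; no wrap correction is applied), derivatization
chemistry, and real biological covariance between metabolites. Passing
end-to-end tests therefore demonstrates correctness of the algorithms
under idealized peak shapes and independent lognormal abundances, not
performance on real chromatograms.

## Processing model and numerical choices

**Folding.** The raw detector stream (scans x m/z) folds into a cube
indexed modulation x intra-modulation sample x m/z; modulation `k` covers
scans `[(k-1)P+1, kP]` with `P` = period x rate. First-dimension time of
a column is `(k-1) x period` (no injection-delay offset), second-dimension
time of a row is `(j-1)/rate`; both conventions are round-trippable and
absolute agreement with any particular instrument's clock is not
attempted.

**Background.** The rolling-ball background is the greyscale opening of
the TIC image with a flat square structuring element (half-width 15 px by
default, about five times the second-dimension peak width). The opening
runs as separable min/max filters written in the package -- the installed
image library's morphology is binary-only -- with replicate padding. On
noisy images an opening rides about two noise SDs below the baseline, so
the median of the residual is added back (pedestal correction) before
clipping at zero; the unclipped residual is kept for noise estimation,
whose robust scale is the MAD x 1.4826 of background pixels. The
outermost `ball_radius` pixels retain a boundary bias on monotone ramps;
the generator keeps analytes away from the run edges for this reason.

**Peak detection.** Local-maxima-seeded watershed (EBImage) with an
h-maxima-style merge tolerance of 3x the noise level to absorb shoulder
maxima; apex ties break toward lower first- then second-dimension index.
A peak's footprint is the connected region above 2x noise around its apex
within its catchment; its volume is the TIC sum over the footprint. The
conventional "S/N 100" gate enters as the corresponding absolute count
threshold per channel (500,000 at 70 eV, 5,000 at 12 eV, 100,000 fused,
via `snr_threshold_to_counts()`); a secondary apex-to-noise gate
(default 5) discards pixels-thin artefacts. With footprints truncated at
2x noise, volumes of near-gate peaks are under-estimated by design; all
downstream statistics are rank-based or scale-free, so this truncation is
monotone-harmless.

**Spectral similarity.** Match factors are pure weighted cosines with the
Stein-Scott identity weighting (intensity^0.6 x mz^3) on nominal-mass
bins, scaled to 0-999; the reverse variant restricts the comparison to
reference masses. The composite search score used by some
commercial tools (with its ratio-of-adjacent-peaks term) is intentionally not implemented; all gate
thresholds (750 match, 900/950 identification) operate on this package's
score. Apex spectra are taken from the raw cube -- not the
background-subtracted image -- so bleed masses contribute to observed
spectra exactly as they would in practice.

**Alignment.** The template seeds from the run with the highest total TIC,
matches every run inside a +-1.5-modulation / +-0.15 s window (about three
sigma of the default jitter) with DMF and RMF >= 750, fits per-dimension
affine retention transforms by least squares, and re-matches once.
Unmatched peaks then grow the template (mapped back through the inverse
transform, deduplicated by window + spectral similarity), and a final pass
counts matches per entry; entries matched in more than half of the runs
(`floor(n/2) + 1`, i.e. 25 of 48) become reliable peaks. Greedy one-to-one
assignment runs in descending DMF order with nearest-retention
tie-breaking. Non-rigid warps are out of scope: the generator's jitter is
affine to first order, and higher-order warp families are not
identifiable from affine jitter.

**Regions and quantification.** The sum composite is built by bilinear
resampling of every (background-subtracted) run image into template
space. Peak regions are the watershed footprints of composite peaks above
`n_runs` x the per-run count gate (responses add across runs, so the gate
scales with the number of runs; composite noise is estimated from the
composite itself). Each region maps into every run through that run's
transform and integrates by bilinear sampling at the transformed pixel
centres -- the affine scale is within a fraction of a percent of 1, so no
Jacobian correction is applied.

**Statistics.** Percent response (each run row scaled to sum 100) feeds
PCA over all 48 runs, QCs included. The MUO-vs-MHO contrast excludes QCs
and, by default, (a) averages the four technical replicates of each
subject before testing -- replicates of one subject are not independent
evidence about the class, and treating them as such inflates the
false-selection rate several-fold -- and (b) uses raw aligned volumes
rather than percent responses: with only ~30 features, strong effect
compounds shift every run's total, and the induced compositional closure
turns null features into apparent discriminators. Both choices are
configurable (`contrast_unit = "run"`, `contrast_scale = "percent"`); on
panels of hundreds of regions the closure term is negligible and percent
responses behave well. Selection is Kruskal-Wallis at alpha 0.05 with
Dunn's z post hoc and Bonferroni correction over group pairs when more
than two groups are compared (for two groups Dunn's test degenerates and
the KW p gates directly; an optional Bonferroni across features is off by
default, the package's reading of the usual practice). PLS-DA is NIPALS with a
centred one-hot response on autoscaled features, two components by
default (the dimensionality of the visualizations the workflow produces);
VIP scores satisfy mean(VIP^2) = 1 by construction and gate at VIP >= 1.

**Identification.** Linear retention indices follow van den Dool-Kratz
interpolation on the alkane ladder (first-dimension time only, as usual
for temperature-programmed indices); candidates pass when DMF >= 900,
RMF >= 950 and |RI difference| <= 10, all boundaries inclusive.

**Class comparison.** Class composites (sum or mean) are compared by a
fuzzy ratio: both images are normalized by their own totals, replaced by
their windowed maxima (3x3 by default) to absorb residual misalignment,
and the per-pixel log2 ratio is reported with pixels below an intensity
floor (3x the reference noise by default) masked. Taking the windowed
maximum of *both* images keeps the operator exactly antisymmetric under
swapping analyzed and reference; the "fuzzy" operator family has no
single published definition, so this one is chosen for its exact symmetry.

## Problem sizes and the validation experiments

The package validates itself at a desk scale chosen once: 48-run studies
of 30 compounds on a 144-modulation x 250-sample grid with 200 m/z bins
(45-244 Da; all diagnostic fragments of the reference subset that fall in
this window carry the spectra, and the mass filter renormalizes the
rest), five replicate studies per experiment.

* `run_recovery_experiment()`: eight compounds carry MUO:MHO effects of
  at least 50% (the largest printed percent differences of the reference
  table); the fused-stream pipeline must flag effect compounds
  (KW-selected and VIP >= 1), pass few nulls, and select most compounds
  as reliable peaks at the 750/750 gates.
* `run_null_calibration()`: 1,000 features with zero injected effects
  over exchangeable runs (one run per subject, so the test's own
  calibration is measured, not the pseudo-replication of a clustered
  design); the selection rate at alpha 0.05 must sit inside the binomial
  95% band.
* `run_fusion_benefit()`: with 30% of compounds invisible at 12 eV, the
  reliable-peak counts must order fused >= 70 eV >= 12 eV.

`scripts/acceptance.R` reruns all of these from scratch at a given seed.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 7, channels = "fused", n_compounds = 8,
  include_reference = FALSE,
  library_args = list(ri_range = c(900, 1450)),
  design_args = list(n_qc = 2, n_mho = 2, n_muo = 2,
                     process_reps = 1, analytical_reps = 2),
  synth = synth_config(n_modulations = 60, acquisition_rate = 25,
                       mz_range = c(45, 180), noise_sd_70 = 1000,
                       noise_sd_12 = 10, baseline_level_70 = 4600,
                       baseline_level_12 = 368),
  min_counts = c("70eV" = 1e5, "12eV" = 1e3, "fused" = 2e4),
  ball_radius = 12)
res <- run_pipeline(cfg)
res
```

## Known limitations

* The run container is a plain-text format (JSON header + TSV count
  matrix); vendor raw formats and binary scientific containers are not
  read or written.
* Apex-pixel spectra only: co-eluting analytes are not deconvolved, and a
  merged pair of peaks yields a single feature.
* Affine retention correction only; no wrap-around handling at the
  modulation boundary.
* The spectral-similarity score is the pure weighted cosine; thresholds
  tuned for composite search scores may not transfer exactly.
* All end-to-end performance statements are about synthetic data with
  the idealizations listed above.
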