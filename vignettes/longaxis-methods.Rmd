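---
title: "Methods: long-axis connectivity parcellation and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-axis connectivity parcellation and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longaxis)
```

## What the package computes

`longaxis` implements a resting-state functional-connectivity analysis of an
elongated region of interest (ROI) — the motivating case is the hippocampus,
whose anterior and posterior segments connect differently to the default mode
network (DMN). The pipeline has four analysis stages plus a synthetic-data
stage that makes all of them testable without patient data:

1. **Temporal cleaning** of each subject's BOLD run: band-pass filtering to
   0.008–0.09 Hz, principal-component nuisance regression from a noise
   compartment (the CompCor idea: white matter and CSF carry physiological
   noise but no neural signal), one-hot spike regressors for artifact
   volumes, and mask-normalized Gaussian smoothing.
2. **Connectivity-based parcellation**: each ROI voxel's fingerprint is its
   correlation with every gray-matter voxel outside the ROI; per subject the
   fingerprints' similarity forms a second-order correlation matrix; the
   matrices are averaged across subjects in a fixed canonical voxel order
   and clustered with k-means (k = 2, k-means++ seeding, squared Euclidean
   distance, 25 replicates, 100 Lloyd iterations), giving an anterior and a
   posterior parcel along the ROI's long axis.
3. **Seed-based group inference**: each parcel's mean time course is
   correlated with every gray-matter voxel, Fisher z transformed, and the
   per-voxel group difference (patients vs. controls, education as covariate
   of no interest) is tested by permutation cluster-extent inference at a
   cluster-defining threshold of p < 0.005 with Benjamini–Hochberg FDR at
   q < 0.05 across clusters; small-volume correction reruns the whole
   procedure inside an a-priori mask. A randomization t test compares
   subgroups (e.g. with/without mesial temporal sclerosis) on peak
   connectivity values.
4. **Brain–behavior analysis**: parcel-to-DMN-hub connectivity (8-mm sphere
   seeds at the posterior cingulate and medial prefrontal hubs in real use;
   planted hub masks in phantoms) is correlated with neuropsychological
   factor scores obtained by projecting oriented, z-scored raw test scores
   on externally supplied factor loadings. The module also provides the
   demographic tests used for cohort tables: Pearson chi-square without
   continuity correction, Fisher's exact test, one-way ANOVA, and the
   pooled-variance t test.

## The phantom generator

`generate_phantom()` builds multi-subject studies with known ground truth.
Its design mirrors the statistical assumptions of the analysis, not MRI
physics:

* **Geometry.** Two elongated ellipsoid ROIs lie along the grid's y (long)
  axis; four 3×3×3 hub blocks carry the network signals ("mPFC-like" and
  "anterior-network" carry the anterior signal, "PCC-like" and
  "posterior-network" the posterior signal); a separate block is the noise
  compartment. Everything else is gray matter. The default grid is
  18×14×12 voxels of 3 mm.
* **Latent signals.** Per subject, the anterior signal A, posterior signal P
  and a physiological signal are sums of six cosines with random phases at
  frequencies drawn among the run's Fourier bins inside 0.008–0.09 Hz.
  Drawing on Fourier bins (rather than continuous frequencies) makes the
  band limit exact over the acquisition window and, because the three
  signals use disjoint bins, makes them exactly uncorrelated over the run —
  so tests of band-power and of nuisance removal have sharp expectations.
* **Coupling gradient.** An ROI voxel at normalized long-axis position y
  mixes `c_ant * w(y) * A + c_post * (1 - w(y)) * P`, where `w` is a sigmoid
  with slope `gradient_sharpness`; truth labels are `w > 0.5`. Group
  coupling values `c_ant`, `c_post` are jittered per subject
  (`coupling_sd`, default 0.12, truncated to [0, 1]); without this
  between-subject variance a brain–behavior correlation would be degenerate
  by construction.
* **Nuisance structure.** A slow cosine drift (0.001–0.004 Hz, below the
  pass band), the shared physiological signal (amplitude 1.5 in the noise
  compartment, 25 % of that in gray matter), white noise (`noise_sd`, the
  unit of all amplitudes), and whole-volume spikes at `spike_rate` of
  volumes (offset 8 noise SDs) with synthetic motion traces that step
  > 1 mm at exactly the spike volumes, so spike detection can be tested
  against planted truth.
* **Behavior.** `score = behavior_slope * c_ant(subject) + N(0,
  behavior_noise_sd)` — linear with Gaussian noise, because the downstream
  analysis is a Pearson correlation, making this the matched test bed.
* **Defaults.** T = 180 volumes at TR = 2 s (a standard ~6-minute resting
  acquisition); coupling 0.8 with SD 0.12; `gradient_sharpness` 8 (a clear
  but not step-like gradient); `noise_sd` 1; `spike_rate` 0.03. These are
  the generator's study conditions; the recovery benchmarks below state
  where they deliberately differ.

What the phantom does **not** emulate: hemodynamic response shapes, spatial
autocorrelation of scanner noise, inter-subject anatomical variability,
registration error, and realistic DMN topography. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not performance on real data.

## Numerical choices

* **Filter realization.** The band-pass applies the squared-magnitude
  response |H(ω)|² of an order-4 Butterworth band-pass spectrally, on an
  even (mirror) extension of each series. This is the transfer function of
  an ideal transient-free forward–backward (filtfilt) pass: exactly zero
  phase, exactly equivariant under time reversal, with no edge transients —
  at T = 180 samples a literal forward–backward recursion leaves visible
  transients because the poles at the 0.008 Hz edge decay slowly. The
  implementation is also vectorizable across all voxels at once via the
  FFT. `bandpass_response()` exposes the exact gain for verification.
* **Cleaning order.** Spike volumes are flagged on the raw run (global
  signal z > 3, volume-to-volume translation > 1 mm or rotation > 0.05 rad
  per axis). The data are band-pass filtered first; every regressor —
  noise-compartment components *and* spike one-hots — is then passed
  through the same filter before the joint regression. Filtering the spike
  columns is essential: a whole-volume offset becomes a ringing pattern
  after filtering, and only the identically filtered regressor removes that
  ringing exactly. Residuals are thus in-band and orthogonal to the design.
* **Smoothing.** Separable Gaussian convolution with σ = FWHM/(2√(2 ln 2))
  per axis (mm converted to voxels through the grid affine), kernels
  truncated at 4σ and renormalized; mask-normalized by dividing by the
  smoothed mask indicator, which preserves constants exactly and in-mask
  mass to well under 0.1 % on contiguous masks. The ROI voxel series are
  never smoothed on the parcellation path — only the gray-matter target
  series (4 mm) and the group-comparison maps (8 mm by default) — so
  spatial adjacency inside the ROI cannot manufacture cluster contiguity.
* **k-means.** Features are the rows of the group-averaged second-order
  matrix. Replicate r of 25 is seeded deterministically with
  `rng_seed + r`; each replicate draws k-means++ centroids and runs Lloyd
  iterations; an emptied centroid is re-seeded at the point farthest from
  its assigned centroid; the minimum-inertia replicate wins. On instances
  of up to 8 voxels the result is verified against exhaustive enumeration
  of all 2-partitions.
* **Canonical order and naming.** Voxels are always ordered by the R array
  linear order (x fastest, then y, then z), which fixes the "identical
  voxel sorting" required before averaging across subjects. After
  clustering, the cluster with the larger mean y in mm is named *anterior*
  (RAS+ orientation); an exact tie is broken toward the smaller cluster
  index and recorded.
* **Pruning.** The published workflow removed isolated misclassified border
  voxels by visual inspection; `prune_isolated()` automates this with
  connected components (26-connectivity by default): components smaller
  than 5 % of the largest component of either cluster are removed and
  listed. Pruning that would empty a cluster is an error.
* **Permutation cluster inference.** The observed t map (linear model with
  intercept, group, covariates; permutations relabel group membership only,
  covariates stay bound to subjects; all distinct relabelings are
  enumerated when fewer than requested) is thresholded at the two-sided t
  for the cluster-defining p. Positive and negative suprathreshold sets are
  clustered separately. Clusters are ordered by extent with suprathreshold
  excess mass (Σ|t| − t_crit) as a continuous tie-break; the null records
  each permutation's maximal cluster under that order, and the uncorrected
  p of an observed cluster is `(1 + #{permutation maxima ≥ cluster}) /
  (1 + n_permutations)`. The mass tie-break matters at desk scale: null
  cluster extents are small tied integers, and the continuous secondary
  ordering gives null p-values that are exactly (discretely) uniform, which
  the calibration suite verifies with a Kolmogorov–Smirnov test. A pooled
  null over all permutation cluster sizes is available as
  `null_type = "pooled"`. FDR is Benjamini–Hochberg across observed
  clusters at q = 0.05; an option exists because voxel-level FDR was also a
  defensible reading, but cluster-level matches the reported tables.
* **Fisher boundary handling.** Correlations with |r| = 1 (a voxel equal to
  the seed) or undefined (constant series) are masked out and recorded
  rather than transformed.
* **Chi-square without continuity correction.** The cohort's printed 2×2
  statistics (8.7, 0.37, 1.1) reproduce exactly only without the Yates
  correction, so that is the implemented convention.
* **Correlation sidedness.** Brain–behavior p-values are two-sided by
  default with a `alternative` switch, since the provenance of reported
  one-tailed-looking p-values is ambiguous; the choice is recorded in the
  output row. A Bonferroni option over a declared family of connections
  implements the corrected threshold (p < 0.0125 for four connections).
* **Factor scores.** The loadings, standardization constants and test
  orientations are *inputs* (`factor_model()`): the normative PCA behind
  them is published elsewhere and not re-estimated here. The phantom's
  behavior score plays the role of a factor score in tests.

## Benchmark problem sizes

The test and acceptance suites run at desk scale, chosen so the whole suite
completes on one CPU in minutes while each check retains sharp expectations:

* *Parcellation recovery*: 10 generator seeds × 20 subjects on the default
  18×14×12 grid, T = 180, `gradient_sharpness = 20` (the abrupt-gradient
  regime in which truth labels are well defined), noise SD 1; adjusted Rand
  index ≥ 0.9 required in ≥ 9 of 10 seeds.
* *Null calibration*: 50 repetitions of a no-group-difference phantom
  (12×10×8 grid, 10 subjects per group) with 200 permutations each; the
  family-wise rate of any FDR-significant cluster must stay ≤ 0.10 and the
  map-level cluster p (`p_map`, defined for every map including
  cluster-free ones) must pass a KS uniformity test at α = 0.01. At 200
  repetitions this p is uniform to within Monte-Carlo error (mean 0.4997,
  KS p 0.98 in the development runs); the α = 0.01 check itself retains the
  nominal 1 % false-alarm rate.
  Maps are computed directly on the generated runs here: calibration is a
  property of the inference stage and holds under any exchangeable
  per-subject map distribution.
* *Effect recovery*: 12 vs 12 subjects, anterior coupling 0.85 vs 0.25,
  cleaning plus 4-mm map smoothing, 300 permutations; the union of
  significant control-greater clusters must overlap the anterior-network
  hub masks with Dice > 0.5. The map-smoothing kernel is scaled with the
  phantom (an 8-mm kernel spans a third of the 54-mm grid and smears source
  signal over most of the search space; real brains are an order of
  magnitude larger relative to the kernel).
* *Brain–behavior recovery*: 100 generator seeds at n = 20 on a 14×12×8
  grid; the planted positive slope's sign must be recovered in ≥ 95 seeds.

## Known limitations

* Group-level parcellation only; per-subject parcellation is out of scope.
* k is fixed by the user (default 2); no model selection for k.
* Anatomical labeling of clusters, atlas management, and the spatial
  preprocessing chain (realignment, normalization) are out of scope —
  inputs are assumed to share one standard-space grid.
* The permutation scheme keeps covariates bound to subjects under
  relabeling (no Freedman–Lane residualization); with strongly
  group-imbalanced covariates this is a known approximation.
* At phantom scale the smoothing halo around signal sources is large
  relative to the grid, so voxel-precise localization statements (e.g.
  Dice against unsmoothed truth masks) are necessarily approximate.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  rng_seed = 1,
  phantom = phantom_config(
    n_per_group = c(control = 10, patient = 10),
    anterior_coupling = c(control = 0.9, patient = 0.4),
    posterior_coupling = c(control = 0.9, patient = 0.9)),
  inference = inference_config(n_permutations = 500))
res <- run_pipeline(cfg)
glance(res$labelings$left)
tidy(res$contrasts$left_anterior_patient)
res$behavior
```
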