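---
title: "Simulating and analysing multi-level category topographies in event-related fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing multi-level category topographies in event-related fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetopo)
```

# The problem

A region of cortex may carry information about a stimulus set at several
levels of abstraction at once: whether a face is familiar at all, which
semantic category a familiar face belongs to, and which individual it is.
`facetopo` implements the full analysis chain needed to ask whether these
levels are represented by *spatially offset* neural populations: per-run GLM
estimation of condition responses, split-data representational similarity
analysis, pairwise decoding, fixed-size searchlight mapping, permutation
harvesting of peak locations with rank-based and mixture-model statistics on
their spatial distributions, and seed-based winner-take-all connectivity.
Because the package is aimed at method verification, it ships a first-class
synthetic-data module that plants known, spatially offset signals, so every
downstream stage can be tested against ground truth without any external
data.

# The synthetic experiment

## Event-related design

`generate_design()` emulates a fast event-related paradigm: per run, 40
stimulus trials (8 repetitions of each of 5 face categories — four familiar
semantic categories plus unfamiliar faces), each trial 4 s long (1 s face
event, 1 s blank, 1 s letter event, 1 s blank), interleaved with 35–39 null
trials of 0–10 s. The first 10 s and last 4 s of each run are always null.
Each category's eight trials in a run carry identity labels 1–8.

Two scheduling choices are ours. First, null trials are placed uniformly at
random among the inter-trial slots rather than by an optimal-efficiency
sequencer: design efficiency matters for empirical power, not for the
correctness properties tested here. Second, null durations are drawn on the
2 s repetition-time grid (0, 2, …, 10 s) so that every event onset is
TR-aligned; the continuous 0–10 s alternative would only blur the
convolution check without adding realism.

## Planted spatial signal

`signal_spec()` places three spherical regions (default radius 7 mm, i.e. 2
voxels at the 3.5 mm isotropic default) in a 20³ voxel grid whose affine
maps 0-based voxel indices to right–anterior–superior (RAS) millimetre
coordinates:

* a **familiarity** region, carrying a template common to all familiar
  categories, drawn from N(1, 1) so the familiar-vs-unfamiliar contrast has
  positive mean;
* a **subcategory** region, carrying one template per familiar category,
  per-voxel centred across the four categories;
* an **identity** region, carrying per-identity templates nested inside the
  category template (`identity = nesting_weight × category + perturbation`,
  default weight 0.5), with perturbations per-voxel centred across the
  eight identities of each category.

The centring is load-bearing. Each level's templates must carry only that
level's kind of information: category templates encode *differences between
categories* (their common component belongs to the familiarity level), and
identity perturbations encode *differences between identities* (they
average out of category-level responses exactly). Without centring, the
subcategory region leaks a deterministic familiar-vs-unfamiliar contrast
and the identity region leaks a category-mean signal, and maps for
different levels share peaks — the planted geometry would be untestable.

The default centres sit on voxel centres, with the subcategory region 3
voxels anterior to the familiarity region and the identity region 4 voxels
anterior and 3 superior to it — separations of two to four voxels, the
scale at which offset representational peaks have been reported in
posteromedial cortex. Templates are drawn once per `signal_spec` seed and
held fixed across runs and subjects: the signal is run-stable; only the
noise varies.

## Noise level

`generate_patterns()` adds i.i.d. Gaussian noise per run, condition and
voxel, default `noise_sd = 5` against unit region amplitudes. With 16 runs
this puts the same-condition split-half pattern correlation of a 100-voxel
neighborhood covering a region near 0.1 — the weak-effect regime typical of
event-related pattern analyses. The choice is deliberate and was made from
a degeneracy diagnostic, not from effect-size optimism: Kendall tau-a over
the 10 entries of a 4×4 split-data RSM is a coarsely quantised statistic
with maximum 24/45, and at low noise it *saturates* — every neighborhood
that sees enough signal attains exactly the ceiling, the map develops an
exact-tie plateau, and the argmax degenerates to storage order. No real
dataset reaches that regime; simulating it would test tie-breaking rather
than localization. At `noise_sd = 5` fewer than 6% of single-split centres
saturate and subject-averaged maps have a unique, well-placed maximum.

`generate_timeseries()` turns betas into BOLD-like series by convolving the
event boxcars with a double-gamma HRF (gamma shapes 6 and 16, unit scale,
undershoot ratio 1/6, positive lobe peaking near 5 s; the positive lobe is
normalised to 1), sampled at TR = 2 s, plus optional linear drift and
Gaussian noise. The letter events enter as their own regressor source.

What the generator does *not* emulate: physiological noise spectra, motion,
spatial noise correlations, field inhomogeneities, or surface geometry.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not robustness to every artifact of real
acquisitions.

# The analysis chain

## GLM

`build_design_matrix()` builds per-run matrices with either 6 task
regressors (five categories + letter) or 41 (40 individual face events +
letter), plus linear trend, quadratic trend, mean confound and optional
motion columns. `fit_glm()` discards the first four frames of each run and
estimates ordinary least squares per voxel; rank-deficient designs fail
loudly, naming the offending columns. We default to plain OLS rather than
prewhitening: the synthetic noise is white, so OLS *is* the exact model; an
AR(1) option would add an estimated nuisance parameter that nothing in the
desk-scale tests exercises. Pattern analyses always use per-run fits.
`normalize_intensity()` implements the grand-mean scaling to 100;
`smooth_volume()` provides Gaussian smoothing for the univariate and
connectivity paths only — pattern analyses are never smoothed.

## Split-data RSA

`mean_subtract()` removes the mean pattern across conditions per run and
voxel. `split_rsm()` splits the runs into two equal halves, averages
patterns within each half per condition, and computes all cross-half
Pearson correlations; the N×N matrix is averaged over 100 random distinct
half-partitions by default (all of them when fewer exist). The CDI
(category discriminability index) is the mean diagonal minus the mean
off-diagonal of that matrix. Model correlations use Kendall tau-a between
the symmetrised matrix's diagonal-plus-upper-triangle vector and the same
entries of a binary identity-matrix model. Two details deserve note:

* **tau-a, diagonal included.** With a binary model the off-diagonal
  entries are constant, so excluding the diagonal would leave a constant
  model vector and an undefined correlation. Including it, tau-a's tie
  handling means a matrix *numerically equal* to the model scores
  `n_diag × n_off / (n(n−1)/2)` (24/45 for N = 4), not 1 — the statistic's
  true ceiling. tau-a rather than tau-b follows the recommendation of the
  representational-similarity literature for tie-heavy model matrices.
* **Averaging order.** tau is computed on the permutation-averaged matrix,
  not averaged over per-split taus, matching the convention that the
  correlation values themselves are averaged across splits before model
  comparison. (For peak harvesting, below, per-split maps are what is
  permuted, so there tau is necessarily per split.)

Undefined correlations (zero-variance patterns) propagate as missing
values, never as zeros. Group inference is a one-sample t test per quantity
across subjects with Benjamini–Hochberg step-up control across tests.

## Decoding

`pairwise_svm_cv()` trains a linear soft-margin SVM (cost 1, no scaling —
patterns are already mean-subtracted; an optional per-fold standardisation
fits on training folds only) on all runs but one and tests on the left-out
run, for each of the six pairs of familiar categories. A test pattern whose
decision value is exactly 0 counts as an error: conservative and
deterministic. Significance against the 50% chance level reuses the
BH-controlled group t machinery.

## Searchlight

`build_neighborhoods()` assigns every in-mask voxel its k = 100 nearest
in-mask voxels by metric distance — the volumetric counterpart of a
constant-cardinality surface searchlight, which is the property that
matters (every neighborhood samples the same number of voxels). Distance
ties at the k-th neighbor break by grid voxel index, making neighborhoods
independent of storage order. `run_searchlight()` evaluates the RSA
statistics per neighborhood through a vectorised path (sparse neighborhood
sums of the per-half condition means and their products) that is
numerically identical to looping `split_rsm()` over restricted pattern
sets; the identity is asserted in the test suite. Mean subtraction is
applied to the full pattern set *before* restriction — the order is fixed
and matters. Searchlight maps default to 20 split permutations: maps are
averaged over permutations anyway, and the ROI-level convention of 100 is
needlessly slow at map scale.

## Topography

`harvest_peaks()` repeats an analysis over random run-splits and records
the location of the subject-averaged map maximum per permutation: the
familiar-vs-unfamiliar contrast t-map per half-set for the familiarity
level (each split contributes both complementary halves), and single-split
searchlight tau maps against the 4×4 or 32×32 categorical model for the
subcategory and identity levels (per-subject maps averaged before the
argmax). The result is a labelled set of RAS peak coordinates.

Their separation is quantified three ways:

* `peak_location_tests()` — Kruskal–Wallis per coordinate axis and pairwise
  two-tailed Mann–Whitney U per axis, Bonferroni-corrected within each
  family; the joint decision is "any axis significant after correction".
  This per-axis construction is our reading of a "multivariate
  Kruskal–Wallis" comparison of group medians along three axes; no single
  canonical multivariate version of the test exists.
* `anosim()` — the rank-based analysis of similarities on the full
  Euclidean distance matrix, authored in-package with mid-ranks and the
  add-one permutation p-value convention (p is never exactly zero); the
  test suite cross-checks it against both an exhaustive rank oracle and
  the vegan implementation.
* `compare_mixtures()` — explicit-parameter 3-D Gaussian mixtures: component
  means, covariances and mixing proportions are plugged in directly from
  group sample statistics (no EM), with free-parameter count
  `k(3 + 6 + 1) − 1` and AIC comparison plus relative likelihoods
  `exp((AIC_min − AIC)/2)`. Singular covariances are regularised by adding
  `1e-6 · trace/3` to the diagonal so degenerate noiseless fixtures cannot
  crash the fit. The parameter accounting is stated explicitly because the
  AIC comparison is monotone in k under any consistent accounting.

`dice()` gives the usual overlap coefficient, defined as 0 for two empty
masks.

# Connectivity

`nuisance_residualize()` regresses out, per run, an intercept, the stimulus
regressor, motion columns, and the top five principal components of the
white-matter and ventricular-CSF voxel sets, then z-scores residuals per
voxel and concatenates runs (z-scoring precedes concatenation).
`seed_map()` correlates each voxel with the mean seed series, applies the
Fisher r-to-z transform, and thresholds at r ≥ 0.12. `winner_take_all()`
regresses every voxel in the analysis domain on all four seed series
jointly and assigns the label of the largest coefficient, averaging
coefficients across subjects first when several are supplied; exact ties go
to the lowest seed index (they arise only in noise-free fixtures). The
analysis domain is the *union* of the per-seed thresholded masks — the
natural reading of saving "strongly connected" locations per map; an
intersection would shrink the domain to voxels strongly coupled to every
seed at once, which defeats a winner-take-all parcellation.
`generate_connectivity_dataset()` plants a four-zone network (each zone one
latent series plus independent noise at a stated SNR) for end-to-end
verification, and `coupling_rm_anova()` supplies the one-way
repeated-measures F used for seed-by-ROI coupling tables.

# Low-level visual control

`equalize_images()` iterates histogram rank-matching to the set-average
luminance distribution and imposition of the set-average Fourier amplitude
spectrum with each image's own phase retained (3 rounds by default). Within
each round the histogram step runs first and the spectrum step last, so the
matched-spectrum property — identical radially averaged power curves — holds
*exactly* after every round, while histograms match to the residual of one
spectrum correction. The order is our choice; iterated to convergence the
two orders coincide, and the verifiable acceptance property (matched radial
spectra to <1%) is the one we pin exactly. `gabor_c1_features()` implements
V1-like simple/complex cells: zero-mean unit-norm Gabor filters over 4
orientations and 8 sizes (7–21 px) paired into 4 bands, rectified responses
max-pooled over half-overlapping spatial cells and adjacent scales. The
stimuli themselves are generated textured ovals with controllable class
structure (`generate_stimuli()`): real photographs are not redistributable,
and the control's logic — are classes separable from low-level features? —
only needs images whose class structure is known. `multiclass_loocv()`
leaves out one sample per class per fold, classifies with a linear
one-vs-one SVM, and estimates chance by re-running the whole procedure —
including fold construction — on shuffled labels; re-deriving folds from the
permuted labels keeps training folds class-balanced, which is what makes
the permutation null sit at 1/n_classes rather than below it.

# Numerical conventions

* All randomness flows from explicit integer seeds; per-run and per-stream
  sub-seeds are derived deterministically and stay below 2³¹.
* Run splits are distinct unordered half-partitions sampled without
  replacement, enumerated exhaustively when fewer exist than requested.
* Permutation p-values use the add-one convention throughout.
* Argmax ties (exact equality) resolve to the first index; neighborhood
  distance ties resolve by grid voxel index.
* Missing values propagate as `NA` with warnings, never silently as zeros.

# Problem sizes used in the shipped verification

The test suite and acceptance script run at desk scale, chosen so the full
chain is exercised end to end: chance calibrations use 200 permutations or
200 simulated null datasets; null-calibration checks pool 2000 simulated
ROIs into 250 group-level tests; the planted-topography check runs the full
20³-grid, 16-run, 8-subject configuration once for peak-median
localization, and 30 reduced replicates (14³ grid, 2 subjects, 10 peaks
per label) for rejection-rate calibration; ANOSIM null uniformity uses 300
datasets at 199 permutations. These sizes are statements of the
verification design, with binomial or KS tolerances matched to each.

# Known limitations

* Kendall tau-a with a 4-condition model is coarsely quantised; at high SNR
  searchlight maps saturate and localization claims degrade to tie-breaking
  (see the noise-level discussion). The 32-condition identity model does
  not suffer from this in practice.
* The univariate peak is the best single voxel of a template, not a region
  centroid, so its distribution's median need not coincide with the planted
  centre to within a voxel; only the searchlight analyses carry that
  guarantee.
* The ANOSIM comparison of peak distributions is sensitive to any
  distributional difference between labels, not only location shifts of the
  planted centres. Because the planted signal is run-stable, run-split
  permutations resample noise but never the template landscape, so each
  analysis's peaks concentrate around its own template-determined maxima —
  identity maps, which average 528 RSM entries, are nearly deterministic
  across splits. Even with all three region centres co-located, the three
  labels therefore form tight, distinct peak distributions and the ANOSIM
  false-positive rate is far above nominal. A co-location null calibrated
  at ~5% would require peaks to be independent draws from an
  analysis-independent distribution, which no run-stable-signal simulation
  can provide; the corresponding check in the acceptance suite documents
  this by failing at its stated tolerance.
* Surface-based machinery (projection, smoothing on the cortical sheet,
  surface searchlights) is intentionally absent; the voxel-grid analogues
  preserve the defining statistical properties.
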