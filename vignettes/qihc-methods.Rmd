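---
title: "Quantitative multiplexed IHC scoring: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multiplexed IHC scoring: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qihc)
```

## The problem

Multiplexed fluorescent immunohistochemistry (qIHC) stains one
formalin-fixed tissue section with several fluorophore-conjugated
antibodies plus a nuclear counterstain, and images it with a multispectral
camera. Because emission spectra overlap and tissue autofluoresces, the raw
channel stack must be *unmixed* into per-marker component images before any
quantification. The biological readout this package targets is a
*nuclear expression score* (NES): the mean nuclear intensity of a marker of
interest (RAD51 in the motivating application) over all imaged tumour
cells of a sample, expressed in camera-independent *normalized counts*.
Continuous nuclear scores of this kind are approximately Gaussian across
patients — unlike bimodal markers such as Ki67 — so cohorts are stratified
into the first quartile (Q1, low), interquartile range (IQR) and fourth
quartile (Q4, high) rather than split at the median, and the score's
association with progression-free and overall survival is assessed with
Kaplan–Meier curves, log-rank tests and Cox proportional-hazards models.

None of the patient imaging or clinical data behind such a study is
publicly available, so the package is organised around a synthetic slide
and cohort generator with complete ground truth. Every stage — unmixing,
segmentation, scoring, QC, stratification, survival statistics — is exercised
and validated against that truth.

## The imaging model

A multispectral image has $C$ channels. Each endmember $k$ (fluorophore or
autofluorescence) has a non-negative spectrum $s_k \in \mathbb{R}^C$,
normalized to unit Euclidean norm so that unmixed abundances carry the
intensity scale. A pixel with abundances $a_k$ (photons s$^{-1}$
pixel$^{-1}$) produces expected counts

$$
y = \mathrm{clip}\!\left(g \cdot t \sum_k a_k s_k + \varepsilon,\;
0,\; 2^{b}-1\right),
$$

with gain $g$, exposure time $t$ (seconds), bit depth $b$, and noise
$\varepsilon$ composed of Poisson shot noise on the pre-gain photon signal
and Gaussian read noise after the gain — the standard CCD model. Both noise
sources can be switched off, in which case imaging is exactly linear and
every downstream identity can be tested to machine precision.

Normalized counts invert the camera settings:

$$
\mathrm{NC} = \frac{\text{counts}}{2^{b} \times t \times g \times
\text{binning area}} .
$$

With the simulator's unit conventions this gives the package its central
*fixed point*: in the noiseless limit, the normalized mean nuclear count of
a marker equals its true abundance divided by $2^{b}$, exactly. The
acceptance suite verifies this per cell to machine precision.

## Spectral library and unmixing

The library is estimated the way a practitioner prepares one: the
autofluorescence (AF) spectrum is the unit-normalized mean spectrum of an
unstained slide; each fluorophore spectrum is the mean spectrum of the
brightest 2% of pixels (by total counts) of its single-stain slide, minus
the unstained slide's mean spectrum in raw counts, floored at zero and
normalized. Subtracting the AF *projection* instead would also remove the
overlapping part of the fluorophore spectrum; subtracting the measured AF
background keeps the estimate parallel to the truth (cosine similarity 1
in the noiseless round trip, > 0.999 with default noise).

Unmixing solves, per pixel, non-negative least squares
$\min_{a \ge 0} \lVert S a - y \rVert_2$ with a Lawson–Hanson active-set
solver implemented in compiled code. NNLS was chosen over pseudo-inverse
plus clipping because it is the standard contract for spectral unmixing
and is *oracle-testable*: for small endmember counts the exact solution
can be found by enumerating all active sets, and the test suite checks the
solver against that enumeration on a thousand random pixels at $10^{-6}$.
Saturated pixels (any channel at $2^{b}-1$) violate linearity and are
flagged; they are excluded from library estimation and from nuclear means,
and nuclei containing them carry a saturation flag.

## Segmentation

The commercial tool used in the motivating study relies on a proprietary
trainable tissue classifier. Here the tumour mask is obtained directly from
the epithelial-marker (EpCAM/cytokeratin) component: Otsu threshold (or a
fixed override), morphological closing (radius 3 px), and removal of
regions below 500 px. The synthetic generator makes the epithelial signal
uniformly positive in the tumour blob and absent in stroma, which
guarantees this route is sufficient (mask Jaccard ≥ 0.95 against truth is
asserted); on real tissue the closing radius and minimum region area are
the knobs to adjust.

Nuclei are segmented from the counterstain component: Gaussian smoothing
(σ = 1.5 px), Otsu threshold, Euclidean distance transform, watershed
(tolerance 0.2), then removal of labels under 20 px. Two refinements keep
the masks faithful: each label is restricted to pixels above the Otsu
threshold of the *raw* counterstain (so the smoothing used for stable
seeding does not dilate nuclei), and disconnected fragments left sharing a
watershed label are split into separate nuclei. All steps are
deterministic, and because every threshold is computed on bins spanning the
data range, the label count is exactly invariant to global intensity
rescaling. The defaults are tuned to the synthetic geometry (disk nuclei of
radius 3–4 px) and are not claims about any instrument; all are
overridable.

A cell's compartment is decided by strict majority of its nucleus pixels
inside the tumour mask, with exact ties going to tumour — a fixed
tie-break that keeps the pipeline deterministic. Cells straddling the
boundary may therefore differ from the generator's truth label by a pixel
or two of mask; this is why the end-to-end patient-score identity is
asserted at $10^{-3}$ relative rather than machine precision, while the
per-cell fixed point (which does not involve the mask) is exact.

## Scoring, QC and stratification

The core-level score is the mean normalized nuclear intensity over tumour,
non-saturated cells. Cores with fewer than 100 tumour cells fail QC —
exactly 100 passes, a boundary the tests pin down explicitly — and damaged
or oddly stained cores are represented by a manual exclusion flag, since
that judgement cannot be automated. Patient scores pool all tumour cells
of all passing cores (cell-weighted), matching a score defined across all
imaged tumour cells of a sample; a per-core-mean alternative is available
as a configuration choice. Patients need at least two passing cores by
default, and failures are excluded listwise with logged reasons.

Marker positivity (Ki67 extent, immune phenotypes) uses a threshold that is
either fixed or computed by Otsu's method over the supplied cell-level
distribution; the motivating study states no cut-offs, so the
cohort-level Otsu default is a reproducible stand-in. Immune phenotypes
are boolean combinations of marker positivity (cytotoxic T cell = CD3⁺CD8⁺,
regulatory T cell = CD3⁺FOXP3⁺, macrophage = CD163⁺), summarised per
compartment as counts, densities, and the tumour/stroma density ratio —
reported as missing, never infinite, when the stroma density is zero.

Stratification uses the linear-interpolation quantile convention (R type
7): scores strictly below the 25th percentile are Q1, strictly above the
75th are Q4. The convention is recorded in the output; for distinct scores
with $n$ divisible by 4 it yields exactly $n/4$ patients in each extreme
stratum, and strata are invariant under any strictly monotone transform of
the scores. Quartiles are always computed within a cohort, never shared
across cohorts.

## Cohort statistics

Kaplan–Meier estimation, the log-rank test, and Cox proportional-hazards
fits are delegated to the `survival` package behind thin, typed wrappers;
the test suite validates them against independent oracles — hand
product-limit computations, an explicit observed-minus-expected /
hypergeometric-variance accumulation, and a brute-force grid search of the
partial likelihood — rather than trusting either implementation alone. Cox
ties use the Efron approximation by default (Breslow optional); the choice
is recorded in the fit object. Wald 95% intervals are reported per
covariate with reference levels shown explicitly. The proportional-hazards
assumption is checked descriptively (scaled Schoenfeld residual trend
test) but never gates a fit. Two facts tie the layers together and are
asserted numerically: with no censoring the KM curve equals the empirical
survival function, and for two groups the Cox score statistic equals the
log-rank statistic on untied data.

Progression tables at a horizon (12 or 24 months) count, per stratum,
subjects with an event by the horizon versus subjects followed beyond it.
Subjects censored before the horizon without progression are excluded by
default — the source material does not define that denominator — and a
flag switches to counting them as non-progressed. The chi-square test is
Pearson's without continuity correction, with Yates' correction available.

Rank comparisons use the Mann–Whitney U test: exact by enumeration when
the combined sample size is at most 20 without ties (verified against full
labeling enumeration for all group sizes up to 6), otherwise the normal
approximation with tie correction. Correlations (Pearson, Spearman) and
simple linear regression cover the concordance analyses. Differential
immune-gene testing between Q4 and Q1 applies a per-gene two-sided Welch
t-test with Bonferroni adjustment $\min(1, m p)$, significant below 0.05;
Bonferroni is applied within a declared family only, never across
families. HRD subgrouping partitions patients at the validated score
cut-off of 42 (42 itself is positive) and reruns the survival comparison
within each subgroup while *retaining* full-cohort strata.

## What the generator emulates, and what it does not

The simulator reproduces the features the pipeline's correctness depends
on: Gaussian fluorophore spectra plus a broad AF endmember; a smooth random
tumour blob occupying a configurable area fraction; non-overlapping disk
nuclei (with an option to plant overlapping pairs for watershed tests);
lognormal per-cell abundances with a patient-level Gaussian distribution of
the scored marker's median; bimodal (Ki67-like) and phenotype-driven
immune markers; the full camera model; and survival times from an
exponential proportional-hazards model with log-hazard linear in the
standardized true score and independent exponential censoring calibrated
to a target censoring fraction.

It deliberately omits optics (point-spread function, chromatic
aberration), scanner tiling, spatial abundance gradients within nuclei,
cytoplasmic signal, irregular nuclear shapes, and any instrument-specific
noise calibration — the noise parameters are free configuration, not a
claim about any camera. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under these idealised conditions,
not segmentation performance on real histology.

Default study conditions: 10 channels; DAPI, RAD51, EpCAM, Ki67, CD3, CD8
plus AF; 192 × 192 px cores with 240 nuclei of radius 3 at 55% tumour
fraction (so a core carries well over 100 tumour cells and passes QC);
patient true scores Gaussian with mean 8000 and SD 2000 photons s⁻¹ px⁻¹;
12-bit camera at 0.05 s exposure, unity gain, shot noise on and 1 count of
read noise; two cores per patient; PFS baseline hazard 0.03 month⁻¹, a log
hazard ratio of log 2 per SD of score, and 20% censoring. Monte-Carlo
checks use 100 seeds for coefficient recovery (n = 500 patients), 500
replicates for the null size of the Q4-vs-Q1 log-rank test (n = 80), 20
replicates for the HRD-subgroup contrast (n = 200), and a 500-gene matrix
with 10 planted two-SD effects at 30 vs 30 patients for the
differential-gene stage; the imaging-based end-to-end check uses 60
patients with default noise and a 10-patient noiseless cohort for the
exact rank-order property.

## Numerical and degenerate-input choices

* Zero-median markers are treated as truly absent (no lognormal draw).
* A uniform positive epithelial component yields a full-frame tumour mask;
  an all-zero one yields an empty mask without error.
* All scores identical is a degenerate distribution and stratification
  refuses it; fewer than 8 non-missing scores likewise.
* Constant covariates, empty groups, zero-variance correlations, and
  all-dark reference slides raise errors naming the offending input.
* Genes with zero variance in both groups get p = 1 and a flag rather than
  an error, so one degenerate gene cannot abort a panel.
* One master seed drives everything; per-core seeds are derived at fixed
  offsets below $2^{31}$, so cohorts are reproducible core by core.

## Known limitations

The tissue classifier is thresholding plus morphology, not a trained
model; membrane-marker-guided cell-boundary refinement is not reproduced;
the nuclear mean uses nucleus pixels only. H-scores and genomic-scar HRD
scores are external inputs, never computed. Exact replication of any
published cohort's hazard ratios is not attempted — that would require the
unpublished patient data — so validation is property-based and
simulation-based throughout.
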