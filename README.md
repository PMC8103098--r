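# qihc

Quantitative multiplexed immunohistochemistry (qIHC) scoring and cohort
analysis for tissue-microarray studies — from multispectral image stacks to
survival statistics — plus a synthetic slide/cohort simulator with full
ground truth so every stage can be validated without patient data.

## What it does

Multiplexed fluorescent IHC measures several protein markers on one tissue
section; a multispectral camera records overlapping emission spectra that
must be unmixed before quantification. `qihc` implements the full analysis
chain:

1. **Spectral library** — fluorophore spectra estimated from single-stain
   reference slides, autofluorescence (AF) from an unstained slide.
2. **Unmixing** — per-pixel non-negative least squares (Lawson–Hanson
   active set, compiled) over the library, with an AF component, per-pixel
   residuals and saturation flags.
3. **Segmentation** — tumour mask from the epithelial-marker component
   (Otsu + morphology); nuclei from the counterstain (smoothing, Otsu,
   distance transform, watershed).
4. **Scoring** — per-cell mean nuclear intensities converted to
   camera-independent *normalized counts*,

   ```
   Normalized Counts = counts / (2^bit_depth × exposure[s] × gain × binning area)
   ```

   pooled into a nuclear expression score (NES) per core and per patient,
   with core QC (< 100 tumour cells fails), marker positivity (Ki67
   extent, immune phenotypes), tumour/stroma density ratios, and Q1 / IQR /
   Q4 quartile stratification.
5. **Cohort statistics** — Kaplan–Meier, log-rank, Cox proportional
   hazards (Efron/Breslow ties) with reference-level reporting,
   progression tables at 12/24 months with chi-square tests, Mann–Whitney
   rank tests (exact for small samples), Pearson/Spearman/regression
   associations, Bonferroni-corrected per-gene Welch t-tests between score
   strata, and HRD-score subgroup analysis (positive at ≥ 42).

The synthetic module (`sim_config`, `simulate_core`,
`simulate_reference_slides`, `simulate_cohort`, `simulate_expression`)
generates multispectral cores with disk nuclei, lognormal marker
abundances, a realistic camera model (shot noise, read noise, bit-depth
clipping — all switchable off for exact tests), and patient cohorts whose
survival times follow a proportional-hazards model in the true score.

## Worked example

```r
library(qihc)

cfg <- sim_config(seed = 42)          # 10 channels, 6 markers + AF, 240 nuclei
lib <- generate_library(cfg)
sim <- simulate_core(cfg, lib)        # image + ground-truth cell table
proc <- process_core(sim$image, lib)  # unmix -> masks -> cells

res <- score_core(proc$cells, "RAD51", core_id = "demo_core")
#> core NES = 2.0968, QC pass = TRUE (129 tumour cells)
#> true mean abundance / 2^12 = 2.0845     # truth, recovered within ~0.6%

marker_positivity(proc$cells[proc$cells$compartment == "tumour", ], "Ki67")$extent
#> 27.1                                    # % Ki67-positive tumour cells

immune_metrics(proc$cells, proc$mask$tumour_area, proc$mask$stroma_area,
               phenotypes = list(T_cyt = c("CD3", "CD8")))
#>   phenotype n_tumour n_stroma density_tumour density_stroma  ts_ratio
#> 1     T_cyt        7       12   0.0003448446    0.000724419 0.4760292

# a 60-patient cohort, imaged and scored end to end
co  <- simulate_cohort(60, seed = 7)
run <- run_synthetic_cohort(co, sim_config(seed = 1))
pat <- run$patients
cor(pat$nes, pat$true_abundance, method = "spearman")
#> 0.9999
table(pat$stratum)
#>  Q1 IQR  Q4
#>  15  30  15

d <- pat[pat$stratum %in% c("Q1", "Q4"), ]
logrank_test(d$pfs_time, d$pfs_event, droplevels(d$stratum))
#> log-rank: statistic = 20.39, p = 6.299e-06 (n = 15/15)

pat$z <- scale(pat$nes)[, 1]
cox_fit(pat, "pfs_time", "pfs_event", c("z", "age_group", "stage"))
#> Cox PH fit (efron ties), n = 60 used, 0 missing
#>       term level         HR (95% CI)        p
#>          z       3.168 (2.133-4.704) 1.10e-08
#>  age_group   <65                Ref.       NA
#>  age_group  >=65 1.076 (0.579-1.999) 8.17e-01
#>  ...
```

The simulated effect (hazard ratio 2 per SD of *true* score) is recovered
through the entire imaging chain: the per-SD hazard ratio on the *measured*
score is significant while the independently drawn clinical covariates are
not.

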