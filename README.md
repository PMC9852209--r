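# survoxel

Explainable survival-profile prediction from brain FDG-PET volumes.

## The problem

In amyotrophic lateral sclerosis (ALS), survival from diagnosis ranges
from months to more than a decade, and reliable prognostic tools are
scarce. Brain 2-[¹⁸F]FDG-PET measures regional glucose metabolism and is
acquired at diagnosis in many centres; the question is whether the scan
alone can predict a patient's survival-time range, and — just as
important for clinicians — *which brain regions* carry that prediction.

`survoxel` implements a voxel-based, explainability-oriented pipeline
for this problem, aimed at neuroimaging researchers who want a tested,
reproducible reference implementation that runs end-to-end on synthetic
cohorts (no patient data required):

1. **Survival discretization.** Continuous survival times *t₁ … tₙ* are
   partitioned by one-dimensional k-means into *k* profiles. Quality is
   summarized by the variance explained,
   *VE = SSB / SST*, where *SSB = Σ_c n_c (t̄_c − t̄)²* and
   *SST = Σ_i (t_i − t̄)²*. The number of profiles is chosen
   data-driven (mean silhouette width by default; the
   Calinski–Harabasz ratio *[SSB/(k−1)] / [SSW/(n−k)]* is available).
2. **Preprocessing.** Registered volumes are smoothed (Gaussian,
   FWHM in mm), intensity-normalized to the whole-brain mean, masked,
   and flattened into a subjects × voxels feature matrix — every voxel
   is a candidate feature.
3. **Class-aware voxel selection.** Within each profile's subjects, a
   k-nearest-neighbour similarity graph with heat-kernel weights
   *w_ij = exp(−‖x_i − x_j‖²/t)* is built, and every voxel *f* is
   ranked by its Laplacian score
   *L_r = (f̃ᵀ L f̃) / (f̃ᵀ D f̃)*, with *f̃ = f − (fᵀD1/1ᵀD1)1*,
   *D* the degree matrix and *L = D − W*. Low scores mark voxels that
   respect the local geometry of the profile's subjects; the top-*m*
   voxels (default 400) are retained per profile.
4. **One-against-all classification.** One SVM per profile (that
   profile positive, the rest negative) on the profile's own voxel
   set; kernel, cost and kernel parameters are tuned to maximize the
   cross-validated informedness *J = sensitivity + specificity − 1*,
   and evaluated on a stratified 10% holdout (error rate, *J*, and the
   c-statistic, i.e. AUROC of the decision values).
5. **Cluster mapping.** Each profile's selected voxels are reduced to
   contiguous 3-D clusters (26-connectivity, extent strictly greater
   than 100 voxels), localized in voxel and affine (mm) coordinates,
   and labelled relatively *hypo-* or *hypermetabolic* against the
   whole-brain mean.
6. **Cohort statistics.** One-way ANOVA of survival by group and
   King's-stage × profile odds ratios with Woolf confidence intervals,
   *exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d))*.

A synthetic-cohort module generates survival times (two calibrated
presets), clinical covariates (sex, onset, age, King's stage) and
phantom volumes with planted, severity-modulated metabolic lesions, so
that every stage of the pipeline is validated against known ground
truth.

## Worked example

```r
library(survoxel)

## survival discretization on a synthetic 418-subject cohort
d <- generate_survival_times(418, survival_preset("clustered"), seed = 1)
sel <- select_k(d$survival_years, k_range = 2:6, seed = 1)
print(sel$partition)
#> survival_partition: k = 3, VE = 93.6%, boundaries (years): 2.24, 4.52

## odds ratio of King's stage 1 against the short-survival profile
orr <- odds_ratio(88, 82, 167, 81)
sprintf("OR %.2f (95%% CI %.2f-%.2f)", orr$or, orr$ci_low, orr$ci_high)
#> "OR 0.52 (95% CI 0.35-0.78)"

## end-to-end pipeline on a reduced phantom cohort
cfg <- pipeline_config(output_dir = tempfile("run"), n_subjects = 120,
                       m = 150, budget = 5, folds = 3, n_neighbors = 4,
                       min_extent = 50, k_range = 2:4, seed = 1)
run_simulate(cfg)
fit <- run_fit(cfg)
run_report(cfg$paths$output_dir)
#> Survival discretization: k = 3 profiles, VE = 92.8%
#>   boundaries (years): 1.98, 4.65
#> Holdout performance (one-against-all):
#>   class 1: error 0.00%, informedness 1.000, c-statistic 1.000
#>   class 2: error 0.00%, informedness 1.000, c-statistic 1.000
#>   class 3: error 0.00%, informedness 1.000, c-statistic 1.000
#> Discriminant clusters (extent > threshold): 4
#>   class 1 cluster 1: 128 voxels, hypo, peak (8, 9, 14)
#>   class 2 cluster 1: 76 voxels, hyper, peak (21, 13, 18)
#>   class 2 cluster 2: 74 voxels, hyper, peak (10, 24, 12)
#>   class 3 cluster 1: 90 voxels, hyper, peak (15, 18, 22)
```

Three survival profiles emerge at roughly 2 and 5 years, the partition
explains ~93% of the survival variance, the phantom's planted lesions
are recovered as contiguous clusters with the correct metabolic
direction (the short-survival profile's deep lesion is hypometabolic,
the rest hypermetabolic), and the holdout classification is perfect —
expected here, because the phantom's class signatures are fully
separable by construction. A command-line wrapper with `simulate`,
`fit` and `report` verbs is provided in `inst/cli/survoxel.R`.

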