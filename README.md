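# gaitResponder

Predicting who will respond to a hip-strengthening exercise intervention
in mild-to-moderate knee osteoarthritis (OA), from data available before
treatment: walking-gait kinematics and the Knee injury and Osteoarthritis
Outcome Score (KOOS). The package is aimed at biomechanics and
rehabilitation researchers who want the full analysis pipeline — from raw
joint-angle stride recordings to a cross-validated classification model
and a projection of new cohorts into its subspace — as tested, reusable,
seed-reproducible code.

## The method

Each subject's six joint-angle channels (hip, knee, ankle × sagittal,
frontal) are low-pass filtered (10 Hz, 2nd-order zero-phase Butterworth),
segmented at gait events, time-normalized to stance (60 points) and swing
(40 points), averaged over 10 consecutive strides and concatenated into a
600-point gait signature. The cohort matrix **X** (98 × 600 in the study
design) is standardized column-wise and reduced by PCA, giving
min(n − 1, 600) = 97 gait principal components; PC scores plus the four
baseline KOOS subscales (pain, symptoms, ADL, QoL) form 101 candidate
predictors.

Intervention patients are labeled by the per-patient effect size of KOOS
change, d = (post − pre)/SD, averaged over the four subscales:
Non-Responders (d < 0.2), Low-Responders (0.2 ≤ d < 0.8), High-Responders
(d ≥ 0.8). Predictors are chosen by sequential forward selection wrapped
around an equal-prior linear discriminant under 10×10-fold cross-validated
error, run 10 times with different fold systems; features are ranked by
selection frequency and capped at one less than the smallest subgroup.
Cumulative entry of the capped features selects the prefix with the best
10×10-fold accuracy; the final canonical LDA (eigenvectors of W⁻¹B,
scores scaled to unit pooled within-group variance) is reported with
Wilks' Λ = Π 1/(1 + λᵢ), Bartlett's χ² = −(n − 1 − (p + k)/2) ln Λ,
Box's M, a Monte-Carlo Lilliefors normality screen, and the structure
matrix. Post-intervention, follow-up and pain-free-control data
(controls get perfect KOOS scores) are projected into the (DF1, DF2)
plane with the stored baseline standardization, and centroid stability is
assessed against the Voronoi regions of the baseline subgroup centroids.

A synthetic cohort generator reproduces the study's structure — group
sizes 59 + 39 (14/14/11) + 43 controls, 120 Hz strides with timing
jitter and smooth noise, a High-Responder hip-adduction ramp in the
loading response, a Non-Responder plantarflexion deficit at toe-off, and
lower baseline ADL for High-Responders — so the whole pipeline is
testable without patient data.

## Worked example

```r
library(gaitResponder)

cohort <- simulateCohort(cohortConfig(), seed = 1)
cohort
#> GaitCohort with 141 subjects ( control=43, intervention=39, reduction=59 )

res <- runPipeline(cohort, seed = 1)

table(res$subgroups$label)      # responder subgrouping from KOOS change
#>  Non  Low High
#>   14   14   11

head(res$ranking$ranking, 5)    # selection-frequency ranking (capped at 10)
#>   feature frequency meanPosition rank
#> 1    PC31       1.0     1.000000    1
#> 2    PC45       1.0     2.000000    2
#> 3     adl       1.0     3.000000    3
#> 4    PC36       0.7     4.000000    4
#> 5    PC77       0.6     5.333333    5

res$search$fit                  # best cumulative-entry discriminant model
#> DiscriminantFit: 7 predictors, 3 groups, 2 discriminant functions
#>   Wilks' Lambda = 0.1093, chi2(14) = 73.05, p = 5.39e-10

round(res$report$cvAccuracy, 3) # 10x10-fold cross-validated accuracy
#> [1] 0.856
```

The model keeps 7 of the 101 candidates — the baseline ADL subscale is
selected in every iteration together with PC31, whose loadings
concentrate in the hip-frontal loading-response block — and classifies
85.6% of intervention patients correctly under repeated cross-validation.
Λ = 0.109 with χ²(14) = 73.05 says the two discriminant functions
separate the subgroups far beyond chance. `res$projection` holds the
subspace points, the baseline subgroup centroids and the pain-free
control centroid (which lands in the Low/Non half of the plane, away
from the High-Responders).

Cohorts round-trip through plain CSV directories
(`writeCohortDir()` / `readCohortDir()` / `validateCohortDir()`), and
`inst/scripts/gait-pipeline.R` wraps `simulate`, `validate` and
`run-all` for shell use.

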