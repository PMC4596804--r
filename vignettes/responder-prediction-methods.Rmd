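---
title: "Predicting exercise-intervention response from gait waveforms and KOOS: methods"
author: "gaitResponder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting exercise-intervention response from gait waveforms and KOOS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Muscle-strengthening exercise improves pain and function in many patients
with mild-to-moderate knee osteoarthritis (OA), but individual responses
vary widely. If responders could be identified from data available *before*
treatment, clinicians could direct each patient to the therapy most likely
to help. `gaitResponder` implements a complete, reusable pipeline for one
such prediction problem: classifying patients as Non-, Low- or
High-Responders to a six-week hip-strengthening program from (a) their
baseline walking kinematics and (b) their baseline Knee injury and
Osteoarthritis Outcome Score (KOOS) subscales, and then examining how
post-intervention and long-term follow-up data sit in the fitted
classification subspace.

The pipeline has five stages, each an exported module:

1. **Waveform preprocessing** — six joint-angle channels (hip, knee, ankle
   in the sagittal and frontal planes) are low-pass filtered, segmented at
   gait events, time-normalized and averaged into one 600-point gait
   signature per subject.
2. **Data reduction** — the cohort signature matrix is standardized and
   decomposed by PCA; subjects are represented by their component scores.
3. **Responder subgrouping** — per-patient effect sizes of KOOS change
   define the class labels.
4. **Feature selection and classification** — sequential forward selection
   under repeated cross-validated linear-discriminant error, a frequency
   ranking with a subgroup-size cap, and a cumulative-entry search for the
   best discriminant model, with the standard diagnostics (Wilks' Lambda
   with Bartlett's chi-squared, Box's M, a Lilliefors normality screen,
   the structure matrix).
5. **Projection** — new cohorts (post-intervention, follow-up, pain-free
   controls) are projected into the discriminant plane and centroid
   stability is assessed.

A synthetic cohort generator with the same statistical structure makes
every stage testable without patient data.

## Waveform processing

Each recording is a `StrideSeries`: six angle channels sampled at 120 Hz
with foot-strike and toe-off events. Channels are filtered with a
2nd-order low-pass Butterworth at 10 Hz applied forward and backward.
Zero-phase dual-pass filtering is the gait-laboratory standard because it
leaves event timing intact; the squared magnitude response attenuates a
30 Hz component (3x the cutoff) to about 1% while passing 1 Hz
essentially unchanged. The series is extended by odd reflection at both
ends before filtering (about six cutoff periods) and cropped afterwards,
so start-up transients never reach the data.

Strides are segmented foot-strike to foot-strike with the interleaved
toe-off splitting stance from swing. Each stride is resampled by linear
interpolation to 100 points: 60 stance points including both the
foot-strike and toe-off endpoints, and 40 swing points excluding the
shared toe-off sample and ending at the next foot-strike. Whether the
original grids shared the boundary sample is not decidable from published
descriptions; this convention is fixed here and documented rather than
asserted as anyone else's. The first 10 valid consecutive strides are
averaged pointwise, and the six mean cycles are concatenated in the fixed
order hip-sagittal, hip-frontal, knee-sagittal, knee-frontal,
ankle-sagittal, ankle-frontal into a named 600-vector. Linear
interpolation is the least-assumption choice and makes the resampling
exactly testable (a linear ramp resamples to itself).

## Data reduction

The cohort matrix (98 subjects x 600 coordinates in the study design) is
standardized column-wise to mean 0, SD 1 using the sample-SD (n - 1)
convention, matching common statistical packages; the means and SDs are
stored so any later subject can be projected against the *baseline*
statistics. PCA is computed by singular value decomposition of the
standardized matrix (numerically stabler than an eigendecomposition of
the 600 x 600 correlation matrix), retaining min(n - 1, 600) components —
97 for a 98-subject cohort. Component signs are arbitrary in principle;
here the largest-magnitude loading of each component is forced positive
so results are bit-reproducible. The 97 gait PC scores plus the four
baseline KOOS subscales give 101 candidate predictors.

## Responder subgrouping

KOOS subscales (pain, symptoms, ADL, QoL) are scored 0-100 with 100 = no
symptoms; item scoring is `100 - mean(items) x 100 / 4` with mean
imputation of up to half-missing items. For each intervention patient the
change in each subscale is standardized to a per-patient Cohen's d and
the four d values are averaged; labels are Non (< 0.2), Low (0.2-0.8) and
High (>= 0.8), boundaries inclusive on the upper bin.

No published convention defines the denominator of a *per-patient* d.
The package's default is the per-subscale SD of the intervention cohort's
baseline scores: it is deterministic, recomputable from the data at hand,
and standardizes change against between-patient baseline spread. The SD
of change scores is available behind `denominator = "change"`; with a
degenerate baseline SD the error message points at that fallback. The
synthetic generator targets its effect sizes under the same convention,
so generation and analysis are self-consistent.

## Feature selection and the discriminant model

The selection wrapper uses the same classifier as the final model: an
equal-prior linear discriminant. The error measure is 10-fold
cross-validation repeated 10 times (stratified folds, so every fold
contains every class even with 11 High-Responders; unstratified folds can
produce empty-class training sets at n = 39). Selection starts from the
empty set, whose error is that of the majority-class rule, and greedily
adds the feature with the greatest error reduction, stopping as soon as
no addition strictly reduces the error. Ten selection runs use ten
derived seeds, hence ten different fold systems; features are ranked by
the fraction of runs selecting them, with ties broken by mean selection
position and then by name, and the list is capped at one less than the
smallest subgroup (10 for groups of 14/14/11). Error comparisons use
integer misclassification counts, so ties are exact and resolve to the
smallest column index; the whole procedure is bit-reproducible for a
given master seed. The inner CV loop is implemented in C++
(RcppArmadillo) with per-fold sufficient statistics precomputed over all
features, because the wrapper evaluates on the order of 10^5 small
discriminant fits per run.

The canonical discriminant solution maximizes between- over within-group
scatter: with within-scatter W and between-scatter B, the coefficient
vectors are the leading eigenvectors of W^-1 B (computed through a
Cholesky-symmetrized eigenproblem), scaled so discriminant scores have
pooled within-group variance 1, giving min(p, k - 1) functions — two for
three groups. Wilks' Lambda is computed from the eigenvalues as
prod(1/(1 + lambda_i)) (identically det(W)/det(T), which the tests verify
directly) with Bartlett's approximation chi2 = -(n - 1 - (p + k)/2) ln
Lambda on (p - q + 1)(k - q) degrees of freedom. Box's M uses the
standard chi-squared scaling. The Lilliefors screen simulates its null
distribution (10,000 seeded draws at the observed n) instead of relying
on asymptotic tables, which are inaccurate at n = 39. Assumption screens
are *reported* and logged as warnings; they never silently gate the fit.

Model search enters the capped features cumulatively in ranking order,
computes each prefix's repeated-CV accuracy, and keeps the smallest
prefix attaining the maximum, refit on the full data. Cross-validation
refits the entire discriminant (scatter matrices included) inside each
fold, so held-out subjects never leak into the training statistics.
Classification of a new subject minimizes the squared Euclidean distance
to the class centroids in discriminant space adjusted by -2 ln(prior) —
equivalent to the equal-covariance Gaussian posterior rule, which the
tests confirm by brute force. Priors are equal across the three
subgroups by default (group sizes are nearly balanced, and equal priors
match the default of the software family this analysis style comes
from); they are configurable.

## Projection and centroid stability

A new subject is projected by standardizing their 600-vector with the
*stored* baseline means and SDs, scoring only the PCs entered in the
fitted model, appending the entered KOOS subscales, and applying the
discriminant coefficients. Pain-free controls are projected with every
subscale set to the perfect score of 100. The whole map is affine, which
the tests exploit.

"Remaining in the initial third of the subspace" needs a geometric
definition that published text does not supply. The default
operationalization is the Voronoi partition of the three baseline
subgroup centroids in the (DF1, DF2) plane — each point belongs to its
nearest baseline centroid, with exact ties resolved Non < Low < High. A
DF1-only tertile alternative (boundaries at midpoints between adjacent
baseline centroid DF1 coordinates) is available behind
`regionMethod = "df1Tertile"`. Both conventions keep every subgroup
centroid in its own region when unchanged data are re-projected; neither
is verifiably the convention of any particular prior analysis.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with the study's design constants as defaults: 59 reduction-only OA
subjects, 39 intervention subjects whose true labels split 14/14/11, 43
pain-free controls, 120 Hz sampling, 12 recorded strides of which 10 are
used, stance 60% of a 1.1 s stride.

Waveforms are built from smooth low-order Fourier templates per channel
(qualitative caricatures of normal walking, not digitized from any
figure — figure digitization is unreliable, and only the qualitative
group contrasts matter). Subject individuality enters through constant
channel offsets (SD 2 deg), smooth per-subject shape harmonics (SD
2 deg), per-stride harmonic noise (SD 1.5 deg) and stride-timing jitter
(3% duration, 1.5% stance fraction). Two localized movement patterns
carry the group structure, both smooth C1 lobes so the 10 Hz filter
passes them almost unchanged: a hip-adduction ramp over the loading
response (first 15% of stance, decaying over the next 15% — standard
gait-phase conventions; the window boundaries are this package's choice)
and a dorsiflexion-direction bump centred on toe-off (last 10% of
stance). Every subject expresses a random amount of each pattern (SDs
1.75 and 1.5 deg), and group membership shifts only the means:
High-Responders +4 deg on the ramp, Non-Responders -3 deg on the ramp
(they reduce hip adduction during loading where High-Responders increase
it) and +2.5 deg on the toe-off bump (reduced plantarflexion). Because
the published source reports no quantitative effect magnitudes, these
are free parameters of the generator, not estimates of any study's
values; they were fixed so that the planted structure is reliably
recoverable by the pipeline at study size — strong enough that the
capped feature list usually contains both baseline ADL and a
loading-response hip-frontal PC, weak enough that cross-validated
accuracy sits in the high-80s rather than at ceiling. Subgroup score
distributions overlap, as in real cohorts.

KOOS baselines are normal around subscale means (pain 65, symptoms 70,
ADL 70, QoL 60; SD 10), with High-Responders centred at ADL 52 —
patients who respond best report the worst daily-living function at
baseline. Post-minus-pre changes equal the label's target mean effect
size (0 / 0.5 / 1.2 for Non / Low / High) times the baseline SD, plus
N(0, 2) noise, clipped to [0, 100]; under the subgrouping module's
baseline-SD denominator this lands >= 90% of subjects in their intended
bin. An optional shared-severity correlation between subscales exists
(`koosSubscaleCor`) but defaults to 0 so each subscale's predictive
value is unambiguous.

What the generator does *not* emulate: marker trajectories or ground
reaction forces; missing data and outliers; real inter-channel coupling
of gait deviations; KOOS floor/ceiling effects beyond clipping; any
post-intervention change in gait (stability analyses re-project
unchanged baseline data, which is exactly the null case the stability
claim needs). Passing tests therefore demonstrate that the pipeline
recovers structure it was designed to detect under its own assumptions —
not that those assumptions hold in any clinic.

## Numerical choices and degenerate inputs

* Constant waveform columns abort standardization with the column index;
  unstandardized input aborts the PCA.
* A singular pooled covariance aborts the discriminant fit with a hint
  to reduce the feature set; the CV kernel falls back to a pseudoinverse
  only inside folds, where transient near-singularity is expected.
* Component and discriminant-function signs are fixed by
  largest-loading-positive.
* All stage seeds derive deterministically from one master seed; seeded
  helpers save and restore the caller's RNG state.
* Tests exercise the study-sized design (98 x 600, 39 intervention
  subjects) where the structural counts matter, and 20-seed sweeps of
  the full pipeline for the recovery properties; unit tests use smaller
  cohorts (~20 subjects) chosen to keep the default suite quick while
  preserving every code path.

## Known limitations

* The per-patient Cohen's d denominator is a documented convention, not
  a reproduction of any particular prior computation; Fig-level summary
  magnitudes cannot distinguish the candidates.
* With 39 subjects the wrapper selection is noisy by nature: single
  spurious features (including KOOS subscales with no planted signal)
  enter the capped list at low frequencies, and occasionally displace
  the projected control centroid. The frequency ranking over ten runs is
  the mitigation, not a cure.
* The 10 Hz filter attenuates the ~5 Hz loading-response lobe by a few
  percent (~0.15 deg at a 4 deg effect). This is filter physics; the
  noise-free round-trip test asserts interpolation accuracy on the
  unfiltered path and documents the filtered deviation explicitly.
* Joint angles are taken as given; computing them from markers, event
  detection from force data, and gap-filling are out of scope.
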