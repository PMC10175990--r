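---
title: "Normative tangent-space connectivity and agile TMS target selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative tangent-space connectivity and agile TMS target selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agiletms)
```

## The model

The package treats individualized TMS targeting as a normative outlier
detection problem on functional connectivity edges. Each subject
contributes a parcel-by-parcel connectivity matrix; a healthy reference
cohort defines, for every unique parcel pair, what "normal" looks like;
and a patient's edges are scored against that reference. The chain is:

1. **Connectivity.** Parcel-averaged BOLD series (time × parcel) are
   summarized as Pearson correlation matrices. Because a session may have
   fewer time points than parcels (128 volumes against 377 areas at full
   scale), the sample matrix can be rank deficient; we therefore shrink it
   toward the identity, `C = (1 - λ) R + λ I`, which is symmetric positive
   definite (SPD) for any `λ > 0`. `λ = "auto"` uses an analytic
   Ledoit–Wolf-style estimate. One subtlety matters greatly in practice: a
   *single common λ* (the cohort mean of the per-subject estimates) must
   be used for reference subjects and patients alike. A strongly anomalous
   patient yields a much smaller individual `λ` than healthy subjects, and
   shrinking them differently shifts *every* edge of the patient relative
   to the normative distribution. `embed_cohort()` / `embed_patient()`
   enforce this.

2. **Tangent embedding.** SPD matrices live on a curved manifold where
   entrywise differences are a poor notion of deviation. We compute the
   affine-invariant geometric mean `G` of the reference matrices
   (fixed-point iteration on
   `G ← G^{1/2} exp(step · mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}`)
   and map every subject to the tangent space at `G`:
   `T = log(G^{-1/2} C G^{-1/2})`. At the base point the embedding is the
   zero matrix, and tangent edge values are approximately Gaussian and
   comparable across subjects. The embedding acts on shrunk *correlation*
   matrices (unit diagonal), matching the convention of a "tangent-space
   functional correlation matrix".

3. **Normative model.** `fit_normative()` estimates the per-edge mean and
   SD (denominator n − 1) across the reference tangent matrices and
   excludes the `round(E/3)` edges with the largest reference variance
   (`E = P(P−1)/2` unique pairs). Highly variable edges carry little
   diagnostic information; removing them a priori lowers the false
   discovery rate of the outlier step. A patient edge with
   `|z| = |(T_e − m_e)/s_e| > 3` is an anomaly: *hyper*connected above the
   threshold, *hypo*connected below. Under a Gaussian null the two-sided
   3-sigma rule flags `2Φ(−3) ≈ 0.27%` of included edges, the calibration
   the tests verify on simulated null patients.

4. **Agile target selection.** The anomaly matrix is restricted to the
   default-mode and central-executive networks (salience optionally; every
   published target is a DMN/CEN parcel). For each parcel we count its
   anomalous in-network edges; parcels with at least `min_anomalies = 2`
   ("multiple anomalies") qualify, are ranked by count with a slight
   multiplicative DLPFC priority (`dlpfc_bias = 1.2`), and the top 2–3 are
   prescribed. A column dominated by hyperconnectivity receives cTBS, by
   hypoconnectivity iTBS; an exact tie falls to cTBS, which dominates the
   observed prescriptions (20 of 24 left-8Av prescriptions in the bundled
   cohort).

5. **Dose planning.** iTBS: 3-pulse 50 Hz bursts every 200 ms, 40 trains
   of 10 bursts with 6.3 s intertrain gaps — 1200 pulses in 325.7 s. cTBS:
   one continuous 600-burst train — 1800 pulses in 120 s. Both at 80%
   resting motor threshold. The accelerated course delivers 5 sessions per
   day (hourly by default) for 5 days; all targets are stimulated
   consecutively in each of the 25 sessions, so one cTBS target
   accumulates 45,000 pulses over a course. Target masks can be exported
   as binary NIfTI volumes on the parcellation grid together with their
   world-space centroids (the coil-centering point).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigma_threshold` | 3 | outlier threshold, normative SD units |
| `exclusion_fraction` | 1/3 | fraction of highest-variance edges excluded |
| `networks` | DMN, CEN | search space for target columns |
| `min_anomalies` | 2 | in-network anomaly count needed to qualify |
| `k_min`, `k_max` | 2, 3 | targets per prescription |
| `dlpfc_bias` | 1.2 | multiplicative DLPFC ranking priority |
| `shrinkage` | `"auto"` | common shrinkage intensity in [0, 1] |

The threshold and exclusion fraction are the method's two published
calibration knobs and default to their published values. The DLPFC
priority is described only as "slight"; 1.2 lets a DLPFC parcel overtake
an equal-count competitor without overriding a genuinely stronger column
(a 20% margin). The bundled 377-parcel atlas assigns networks only where
the literature is explicit — lateralized DMN(left)/CEN(right) for 8Av,
PGs, 44 and 55b, bilateral labels for the remaining published target
parcels — and leaves everything else `"other"`; it is a plain TSV meant to
be edited as a site's own network table.

## What the synthetic cohort emulates — and what it does not

`generate_reference_cohort()` draws each subject's series as white-in-time
multivariate normal data from a subject-specific covariance: a shared
block-diagonal base correlation structure (blocks of 4 parcels at r = 0.4)
perturbed per subject by a symmetric Gaussian matrix with SD
`subject_sd = 0.1` in the tangent space at the base. This matches the
per-edge Gaussian normative model the scoring assumes: between-subject
spread (0.1) is comparable to the `1/sqrt(128) ≈ 0.09` finite-series
sampling noise. BOLD autocorrelation, head motion, physiological noise
and site effects are *not* modeled — the normative statistics depend only
on the cross-parcel correlation structure, so passing tests demonstrate
the statistical machinery, not robustness to scanner artifacts. Desk-scale
dimensions (64 parcels, 60–200 reference subjects) are used throughout the
tests and examples; the full 377-parcel scale is available through the
same configuration object.

### Anomaly injection is a calibration problem, not an addition

A finding that shaped the generator: one cannot simply add a large offset
to every edge incident to a parcel. A correlation row is Gram-constrained
(a variable cannot be strongly correlated with dozens of mutually
uncorrelated variables), and the matrix logarithm compresses coherent
dominant modes, so the achievable mean tangent offset of a *full* incident
fan saturates near two normative SDs — we measured the realized mean z of
a full-row injection peaking around 1.4 and then *decreasing* with
injection strength. Consequently:

* injected anomalies are **sparse** by default
  (`affected_edge_fraction = 0.25`, optionally restricted to in-network
  neighbors), the regime where multi-sigma offsets are representable and
  which matches the sparse anomaly patterns the method reads off its
  matrices; and
* `magnitude_sigma` is honored by **calibration**: given the study's
  cohort embedding and fitted normative model, the generator solves a
  damped fixed point for the generating structure whose image under the
  *scoring transform* (shrunk correlation, log at the cohort mean) places
  the injected edges exactly `magnitude_sigma` fitted SDs from the fitted
  mean, conditional on the patient's own subject-level perturbation.
  Without a fitted model the same solve runs against the idealized
  noiseless transform with the nominal scale
  `sqrt(subject_sd² + 1/n_volumes)`, and magnitudes are approximate.

Finite-series sampling noise also passes through the concave log, biasing
the *measured* offsets downward by roughly half a sigma; a short inner
Monte Carlo (24 simulated sessions) estimates this bias and the solver
re-targets once, so `magnitude_sigma` is honored on the expected measured
z-score.

## Numerical choices

* Matrix log/exp/sqrt via symmetric eigendecomposition, eigenvalues
  floored at 1e-12 before logs — near-singular shrunk matrices stay
  finite.
* Geometric mean: step 1.0 with halving on residual increase, tolerance
  1e-7 on the Frobenius norm of the mean tangent residual, 50 iterations;
  on non-convergence the log-Euclidean mean `exp(mean log C_i)` is
  returned with `converged = FALSE` and a warning.
* Edges are the unique unordered pairs (upper triangle, row-major),
  `E = P(P−1)/2`. The often-quoted full-matrix count (377² = 142,129)
  double-counts symmetric entries and the diagonal; unique pairs carry all
  the information.
* Variance-exclusion ties at the cutoff are broken by edge index, making
  the fit deterministic.
* Degenerate inputs fail loudly with classed conditions: constant parcels
  by name, identical reference cohorts, zero-variance paired differences,
  fully missing time points. Identical paired samples are reported as a
  degenerate-statistics error (the statistic is 0/0), not as t = 0.
* Injection calibration: damped fixed point with backtracking (accept a
  step only if the worst injected-edge residual decreases), relative
  tolerance 1e-3, 200 iterations.

## Outcome statistics

All tests are two-sided. Missing GAD-7 scores are replaced by the
time-point mean at full precision — imputation never changes a time
point's mean, and rounding the imputed value first would visibly move the
paired t statistics. Complete-case variants drop incomplete subjects
instead. The repeated-measures ANOVA uses the classical univariate
decomposition with subjects as blocks, `F = MS_time / MS_error` on
`(k−1, (k−1)(n−1))` degrees of freedom, without sphericity correction;
with two time points it equals the squared paired t, which the tests
verify. The bundled outcome and prescription tables are verbatim
transcriptions of the published subject-level data, including their
missingness pattern and the small internal inconsistencies of the source
(the 1-month summaries imply one more observed value than the table
prints; the published F statistics are inconsistent with the printed
sample sizes). The package computes whatever the table supports and does
not "fix" the table.

## Limitations

* The reference cohort is synthetic unless you supply real parcel series;
  the package starts *after* volumetric preprocessing and parcellation.
* Normative calibration assumes approximately Gaussian tangent edges;
  heavy-tailed acquisition artifacts would inflate the false-positive
  rate.
* Whether the clinic scored anomalies on tangent values or back-projected
  correlations is not documented; we score in tangent space, where the
  normative spread is defined.
* The hyper→cTBS / hypo→iTBS mapping inherits the (untested) assumption
  that TBS-induced excitability changes translate into connectivity
  changes of the same sign.
* Electric-field modeling, coil geometry, neuronavigation and
  motor-threshold estimation are out of scope; the exported centroid is a
  geometric, not biophysical, target point.
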