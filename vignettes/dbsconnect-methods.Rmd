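---
title: "EEG connectivity analysis of STN-DBS response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG connectivity analysis of STN-DBS response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsconnect)
```

# The scientific problem

Subthalamic deep brain stimulation (STN-DBS) improves motor symptoms in
Parkinson's disease, but the degree of improvement varies widely between
patients, and no electrophysiological marker is established for predicting
who will respond well. `dbsconnect` implements an analysis chain that asks
three questions of source-space EEG recorded during a three-stimulus visual
oddball task, with stimulation ON and OFF:

1. Does DBS change synchronization inside the basal-ganglia-thalamo-cortical
   **motor subnetwork**, and does the OFF-state expression of that
   subnetwork's dominant pattern track the motor benefit a patient obtains
   (MDS-UPDRS III, ON minus OFF)?
2. Which **whole-brain connectivity patterns** of the ON state relate to
   cognitive performance (neuropsychological T-scores)?
3. Can a patient's **DBS OFF connectivity profile** predict whether they are
   an *optimal responder* (UPDRS_diff below a response threshold)?

Because the underlying patient data are not openly deposited, the package is
organized around a synthetic-cohort generator that reproduces the statistical
structure these analyses assume, with known planted effects, so every stage
is testable end to end.

# Connectivity estimation

Source-space ROI time series (90 AAL regions, 1 kHz) are reduced to
functional connectivity with the **phase-lag index (PLI)**: for ROIs $i, j$
with instantaneous phases $\varphi_i(t)$,

$$\mathrm{PLI}_{ij} \;=\; \Bigl|\,\bigl\langle \operatorname{sign}\!\bigl(
\operatorname{wrap}(\varphi_i(t)-\varphi_j(t))\bigr)\bigr\rangle_t \Bigr|
\in [0,1],$$

with the wrap into $(-\pi,\pi]$ and $\operatorname{sign}(0)=0$, so exactly
zero-lag (volume-conduction-like) coupling contributes nothing. The chain
(`roi_timeseries_to_fc()`) is: optional FFT line filtering of continuous data
(zeroing bins within ±0.5 Hz of DBS-artifact lines, identically in both
conditions), epoching into 3 s trials (−1 to +2 s around target stimuli),
order-2 zero-phase Butterworth filtering into six bands (delta 0.1–4, theta
4–8, alpha 8–12, beta 12–30, low gamma 30–50, high gamma 50–100 Hz),
analytic-signal phases, cropping to the 200–600 ms post-stimulus window, PLI
per trial, and averaging the per-trial matrices per subject, band and
condition.

Numerical conventions worth stating once:

* **Sample indexing** is 0-based with half-open windows: at 1 kHz the
  200–600 ms window of a 3 s trial with onset at sample 1000 is samples
  1200..1599. (The proportionality rule is what matters: at 500 Hz the same
  window is 200 samples.)
* **Analytic signal before cropping.** Phases are computed on the full 3 s
  filtered trial and then cropped, so Hilbert edge artifacts fall outside
  the analysis window.
* **Filter form.** `signal::butter(2, ...)` band designs are checked for
  stability at construction (worst case, delta at 1 kHz: largest pole
  modulus 0.9996).
* **PLI bias.** For *independent* narrowband sources the phase difference is
  autocorrelated over roughly the reciprocal bandwidth, so a 400 ms window
  holds few effective samples and PLI has a positive bias that grows as
  bands narrow (empirically ≈0.15 in high gamma up to ≈0.55 in delta under
  pure noise). The i.i.d.-phase floor $\sqrt{2/(\pi n)}\approx 0.04$ at
  $n=400$ applies only to broadband phases. Consequently absolute PLI levels
  are not comparable across bands, and all inference here is paired
  (ON vs OFF within subject) or between-subject within band, never on
  absolute levels.

# Motor subnetwork model

The subnetwork is the fixed 14-ROI set (bilateral Precentral, SMA,
Postcentral, Caudate, Putamen, Pallidum, Thalamus). Its 91 within-subnetwork
edges per subject and condition form a (2n × 91) matrix per band; after
column centering, the **first eigenvariate** (first right singular vector)
gives one score per subject-condition plus a loading pattern and the
fraction of variance it explains. ON and OFF rows are pooled deliberately so
both conditions share one loading basis and their scores are comparable; a
per-condition basis would make paired differences partly reflect basis
rotation. Columns are centered but not variance-standardized, since PLI
edges share a scale. The loading sign is fixed by mean(loading) ≥ 0.

Band-wise ON vs OFF differences use the Wilcoxon signed-rank test with
Benjamini–Hochberg FDR over the six bands. Covariates (age, gender; gender
coded 0/1) enter a nonparametric paired test the only way they coherently
can: the ON−OFF difference vector is adjusted by removing the least-squares
contribution of the *centered* covariates — the location, which is the
quantity under test, is preserved — and the signed-rank test is applied to
the adjusted differences. Removing a full intercept-bearing projection would
annihilate exactly the mean shift being tested. This adjustment is an
approximation: it breaks exact sign-flip exchangeability, and in null
simulations it is measurably (mildly) anti-conservative — empirical size
≈0.052–0.06 at the nominal 0.05 — while the unadjusted test is exactly
calibrated. Both facts are asserted in the test suite.

Signed-rank conventions: zero differences are dropped before ranking (n is
reported after dropping), ties get mid-ranks, p-values are exact (via the
signed-rank distribution) when the retained sample has no ties and n ≤ 25,
else a normal approximation with tie and continuity corrections. An
all-zero difference vector yields a flagged degenerate result (p = 1)
rather than an error, so edge-wise sweeps keep running.

Post-hoc, in bands surviving FDR, each region's **seed connectivity** (mean
of its 13 within-subnetwork edges) is tested ON vs OFF with FDR over the 14
regions. The OFF-state eigenvariate scores are correlated with UPDRS_diff by
**Spearman partial correlation** (rank-transform, residualize both ranked
variables on age and gender plus intercept, Pearson on residuals, t-based p
with n − 2 − k df). A negative rho means patients who improve more under
DBS already express the motor pattern more strongly with stimulation off.

# Whole-brain patterns

Edge-wise ON vs OFF testing applies the same signed-rank machinery to all
4005 connections with FDR within band — a deliberately severe correction
that, as in weak-diffuse-effect regimes generally, typically yields no
survivors unless single edges carry large shifts.

ON-state PCA (`pca_patterns()`) is a column-centered SVD of the subjects ×
4005 edge matrix; components are ordered by descending eigenvalue. The
number of retained components per band comes from a randomized **elbow
estimate**: 1-D k-means over the scree values (k up to 10, random
initialization), k chosen as the smallest capturing 95% of the achievable
within-cluster variance reduction, and the reported count is the size of
the cluster containing the largest variance fraction — i.e., how many
leading components stand apart from the bulk. The procedure is repeated 100
times and the modal count used, ties broken toward fewer components.
Pattern scores are then related to the five T-scores by Spearman partial
correlations with FDR across the whole component × test grid (the most
conservative of the defensible correction scopes); subjects missing a
T-score are dropped pairwise, never imputed.

# Responder classification

The classifier asks whether DBS OFF connectivity predicts optimal response.
Labels derive from a response threshold t: optimal means UPDRS_diff < t.
Because t itself is unknown, it is tuned in a **nested leave-one-out**
design:

* **Outer loop** over subjects: one test subject held out entirely.
* **Inner loop** over the remaining subjects: for every candidate threshold
  (each distinct observed UPDRS_diff in the inner-training set — the
  natural grid, since only observed levels change any subset), the
  possibly-optimal subjects define a **connectivity profile**: per band,
  the subset-mean ON−OFF difference of every edge; edges deviating at least
  4 population SDs from the band's mean difference are retained with their
  sign. A linear SVM (C = 1, features standardized by training-fold
  statistics, class weights balanced against small-n imbalance) is trained
  on DBS OFF values of the profile's edges and scored on the inner held-out
  subject. The threshold maximizing the mean of the defined
  PPV/NPV/sensitivity/specificity wins; exact ties are broken uniformly at
  random (seeded, keyed to subject identity rather than ordering, so
  results are invariant to manifest order). The arithmetic mean was chosen
  over harmonic-mean or Youden-style criteria as the most symmetric
  reading of "best ratio between" the four metrics; `n_sd` and the
  criterion are arguments, not constants, so sensitivity analyses are one
  call away.
* The outer fold rebuilds profile and SVM on all non-test subjects at the
  selected threshold and classifies the test subject against the label that
  threshold induces. Folds whose profile comes out empty (possible under
  weak effects) are recorded unclassifiable and excluded from counts.
* The whole procedure is repeated (100 times under reference conditions;
  the only cross-repetition stochasticity is the seeded tie-breaking).
  Metrics are averaged over folds and repetitions with undefined
  (zero-denominator) metrics excluded, the modal threshold across folds and
  repetitions is reported, and the final profile is extracted from the full
  cohort at that threshold.

Leakage control is structural — the training path is a function of the
training rows only — and verified by a poisoning probe in the test suite:
perturbing the held-out subject's data leaves its fold's threshold, profile
and SVM weights bit-identical.

A scientific note on where the discriminative signal lives: profile edges
whose ON−OFF shift is the *same* in every responder carry no OFF-state
label information by themselves; OFF-state prediction works when the
DBS-affected edges (here, the motor subnetwork's) also differ between
responders and non-responders in the OFF state. The generator plants
exactly this structure, mirroring the claim that optimal responders express
the motor pattern more prominently even with stimulation off. The 4-SD rule
is scale-aware: the 91 motor edges are selectable outliers among 4005
whole-brain edges, but in heavily reduced networks they form too large a
fraction of a band to deviate 4 SDs from its mean — classifier analyses
therefore always run on the full 90-ROI network.

# The synthetic cohort generator

`cohort_spec()` defaults *are* the reference study conditions: 43 subjects,
90 AAL ROIs, six bands, ON/OFF pairs; UPDRS_diff uniform integers on
[−41, −9] (responder threshold −18, giving ≈70% optimal prevalence); ages
N(61, 7²); 14/43 female; UPDRS OFF uniform integers in [30, 70]; five
T-scores N(50, 10²), one channel (Stroop interference) designated to carry
the cognition effect, the rest pure noise — emulating a single genuine
cognition finding.

Per subject, band and condition, edges are built as a shared Beta(2, 5)
baseline (right-skewed, mode ≈ 0.2, mimicking sparse phase coupling; the
analysis assumes no particular null edge law) plus independent N(0, 0.02²)
condition noise, then three planted effects, then clipping to [0, 1] (the
clipped fraction is tracked and warned about above 20%):

* **Motor pattern** (high gamma): the OFF and ON states gain the fixed
  two-module loading (cortico-cortical edges weighted 0.15 against 1
  elsewhere, unit-normalized) scaled by `motor_effect_size` (default 3)
  times the subject's normalized improvement; the ON state additionally a
  uniform `motor_on_increase` (default 0.6) along the loading. Defaults were
  sized analytically: the OFF gradient places the planted direction well
  above the noise top singular value at n = 43, and the ON increment is
  ≈25 noise SDs per subject after projection, so band-specific detection
  and the negative OFF-UPDRS correlation are near-certain while single
  edges stay within [0, 1] (clipping ≈ 0.4%).
* **Responder profile**: two edges per band except delta (the reported
  profile spans all bands but delta), one increasing and one decreasing,
  shifted by ±0.15 in optimal responders' ON state only.
* **Cognition pattern** (high gamma, ON only): a unit-norm random pattern
  supported off the motor-subnetwork edges (so each planted effect stays
  attributable to its analysis stage), scaled by `cognition_effect_size`
  (default 4) times the standardized Stroop T-score — sized so the pattern
  is the leading ON-state principal component at n = 43.

Sub-seeds per subject are expanded from the master seed by multiplicative
mixing, so cohorts generated under nearby master seeds share no streams —
a property the 500-cohort null-calibration suite actually depends on.
Identical spec and seed reproduce a cohort bit for bit.

What the generator does **not** emulate: volume conduction and field
spread, genuine narrowband oscillatory dynamics behind the FC matrices
(matrices are sampled directly at the edge level except in the dedicated
coupled-oscillator fixtures), inter-band dependence, non-uniform responder
prevalence, or realistic effect sizes — the defaults are chosen for
testability, since no usable effect-size estimates exist for calibration.
Passing tests therefore demonstrate that the machinery recovers what it is
pointed at under known conditions, not that real cohorts carry effects of
this size.

# Problem sizes used by the test and acceptance suites

Monte-Carlo checks whose criteria do not depend on whole-brain size
(band-specific motor detection, OFF-UPDRS correlation power, profile
Jaccard recovery, null calibration) run on 20-ROI networks containing the
full motor subnetwork, with 100 cohorts (500 for null calibration) of 43
subjects. Classifier checks run on the full 90-ROI network (see the 4-SD
scale note above) with 1–2 repetitions — sufficient because repetitions
differ only through tie-breaking. The "high SNR" classifier condition is
`motor_effect_size = 8`, `noise_sd = 0.01`, `profile_effect_size = 0.3`.
The analysis drivers under `analysis/` default to 3 classifier repetitions;
`nested_loocv(..., repetitions = 100)` reproduces the reference conditions
unchanged.

# Known limitations

* The covariate adjustment for paired nonparametric tests is a documented
  approximation (mild anti-conservatism quantified above); an exact
  alternative would re-randomize covariate adjustment inside a sign-flip
  permutation scheme at substantially higher cost.
* The elbow rule's mapping from a k-means solution to "number of
  components" (size of the top cluster) is one reasonable reading of an
  under-specified procedure; alternatives (k − 1, largest gap) can differ
  on screes without a clean break.
* PLI's narrowband short-window bias (quantified above) is inherent to the
  estimator, not corrected; all analyses are designed around it.
* With all planted effects at zero the 4-SD profile is usually empty, so
  most outer folds are unclassifiable; chance-level behavior is asserted on
  the folds that do classify.
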