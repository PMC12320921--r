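---
title: "Signed network metrics and PLS for longitudinal connectomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed network metrics and PLS for longitudinal connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfcpls)
```

## Scope and data model

`scfcpls` analyzes paired two-timepoint cohorts of brain connectivity
matrices.  Each scan contributes two square symmetric region-by-region
matrices: structural connectivity (SC), with non-negative streamline
proportions from probabilistic tractography, and functional connectivity
(FC), with Fisher z-transformed BOLD correlations in which negative weights
are retained.  Diagonals (self-connections) are structurally zero.  Regional
network metrics computed per scan are stacked into a scans x regions panel
— all timepoint-1 rows, then all timepoint-2 rows, same subject order in
both blocks — which is the `X` matrix of the PLS analyses.

The package assumes the matrices have already been built by an MRI
pipeline; it starts from delimited-text matrices and takes over
normalization, network analysis, statistics, and quality control.

## Matrix preparation

* **SC normalization.** Raw streamline counts are converted to proportions
  by dividing each row by its own row sum (the streamlines sent from the
  seed region), then symmetrized by averaging the two directions, since
  tractography carries no directionality.  Seeds with no streamlines at all
  are kept as zero rows with a warning rather than rejected: disconnected
  nodes are meaningful to the downstream metrics, and dropping scans for a
  single empty seed would be too aggressive.
* **FC transform.** `fisher_z_transform()` applies `atanh` off-diagonal and
  rejects |r| >= 1 by naming the offending entry.
* **Consensus thresholding.** SC edges "present" (strictly positive) in
  fewer than a fraction (default 0.75) of the scans are zeroed in every
  scan, suppressing tractography false positives.  Presence is strict
  positivity because proportions are non-negative and zeros encode absence.
  The mask is monotone in the fraction, and per-scan zeroed-edge counts are
  reported so cohort-level summaries can be quoted.
* **Region exclusion** drops named rows/columns (e.g. regions outside the
  imaging field of view) while preserving label order; all matrices are
  label-indexed so no 0/1-based index convention is ever exposed.

## Graph metrics on signed weighted networks

**Modularity.** `modularity_signed()` maximizes the asymmetric signed
objective Q* = Q+ − v−/(v+ + v−) · Q−, where Q± is the Newman modularity of
the positive/negative sub-network and v± its total weight.  Positive
weights therefore dominate, which is the standard choice for FC networks
where negative edges are informative but weaker evidence of shared
community membership.  For non-negative SC input the objective reduces to
ordinary weighted modularity.  The optimizer is Louvain-style: greedy
random-order local moves on the modularity matrix followed by aggregation,
repeated to a fixed point; the best of `n_restarts` (default 100) runs is
kept and the result is deterministic given the mandatory seed.  The
resolution parameter defaults to gamma = 1 and is exposed.  On all small
graphs we have enumerated (n <= 8, including signed ones), the returned Q
never exceeds and almost always attains the exhaustive-search optimum; two
equal disconnected cliques give Q = 0.5 exactly.

**Local clustering.** For SC, the weighted coefficient
C_i = sum_jh (w_ij w_ih w_jh)^(1/3) / (k_i (k_i − 1)) with weights scaled
by the network maximum and binary degree k_i; C_i = 0 when k_i < 2.  For
FC, the signed generalization
C_i = sum_{j≠h} w_ij w_ih w_jh / sum_{j≠h} |w_ij w_ih|, which rewards
balanced triangles and penalizes frustrated ones; a vanishing denominator
(isolated region) gives C_i = 0, matching reference-implementation
behavior.  Both match brute-force triangle enumeration to 1e-12 in the test
suite.

**Weighted degree** is the off-diagonal row mean, d_i = sum_j w_ij/(N−1):
"average connection strength" with self-connections structurally zero.

## Null models

`generate_signed_null()` randomizes each sign class's binary topology by
degree-preserving double-edge swaps (default 10 attempts per edge), with
proposals rejected if they would collide with an existing edge of either
sign, so the two classes stay disjoint.  The class's weight multiset is
then reassigned to the rewired edges by greedy rank-matching: edges are
scored by the product of the endpoints' residual target strengths, and the
sorted weights are assigned in batches with re-ranking after every batch.
Every null therefore preserves the per-sign degree sequence and weight
multiset exactly and approximates the strength sequence.  The re-ranking
batch is 5% of the edges by default: with 10% batches the strength
correlation on heterogeneous modular networks fell marginally short of the
0.9 the approximation is expected to deliver, while 5% achieves ~0.95 at
negligible cost.  Dense signed networks admit few legal swaps (almost every
slot is occupied), in which case the null ensemble degenerates gracefully
toward weight-reshuffling on the fixed topology — the preservation
contract still holds exactly.

Empirical p-values are p = #(null >= observed)/n (ties count as extreme,
the conservative choice), with the denominator n rather than n + 1,
matching the proportion definition used for the permutation tests.

## SC-FC coupling

Per region, the Spearman correlation between the region's SC and FC
profiles over the N−1 off-diagonal entries.  Zero SC entries are ranked
rather than dropped (indirect structural paths may still support FC), only
the self-entry is excluded, ties get average ranks, and a zero-variance
profile yields a missing value.  Coupling is invariant to strictly
monotone transforms of either profile.

## PLS analyses

Both analyses decompose a regions x design matrix R by SVD, R = U S V',
with U the brain saliences, V the design/behavior saliences, and S the
singular values; sum(s^2) equals ||R||^2_F.

* **Mean-centered task PLS**: R is the transposed matrix of per-condition
  column means after subtracting the unweighted grand mean of condition
  means.  With two conditions R has rank <= 1, exactly one nonzero singular
  value, and V proportional to (1, −1)/sqrt(2): the LV is the timepoint
  contrast.
* **Behavioral PLS**: within each condition, each behavior column is
  Pearson-correlated with each region column; the condition-by-behavior
  correlation rows are stacked (condition-major) and transposed.
  Per-condition correlations of the LV brain scores with each behavior are
  attached so the cross-sectional consistency of a pattern across
  timepoints can be read off.

Sign convention: each U column's largest-magnitude element is made
positive and V flipped accordingly.  All reported quantities are invariant
to this choice; saliences are compared by absolute cosine wherever sign
indeterminacy matters.  Brain scores are the raw panel values projected
onto U.

### Permutation significance

`permutation_pvalues()` recomputes the decomposition on permuted data and
reports p_l = #(s_perm,l >= s_obs,l)/n_perm (default 1000 permutations).
Two schemes are available:

* `"unrestricted"` (default): all scan rows of the panel are shuffled
  across the whole stack.  This is the classic scheme, and it breaks not
  only the condition labels / X-Y correspondence but also the within-
  subject dependence of the brain data.  When scans of the same subject are
  correlated (as with a subject fingerprint in FC), the observed singular
  value benefits from that dependence while permuted ones do not, making
  the test slightly anticonservative.
* `"paired"`: respects the paired design — within-subject condition swaps
  for the mean-centered analysis, whole subject-block permutations
  (timepoints held together) for the behavioral analysis.  Under subject
  exchangeability this null is exact, and the calibration test in the
  suite (200 null cohorts) verifies the rejection rate at alpha = 0.05
  falls inside its binomial interval.

The calibration test generates its null cohorts with the brain-behavior
effect *and* the age-modularity slope set to zero: a type-I-error rate is
only interpretable under a true null, and the generator's age slope plants
a genuine brain-age association that would otherwise be a real signal, not
a false positive.

### Bootstrap reliability

Subjects are resampled with replacement with both timepoints held together
(the same unit rule as the split-half tests; the resampling unit must be
the exchangeable one).  Each resample's U is procrustes-rotated onto the
original U before accumulating, so axis reflections and rotations between
resamples do not inflate the spread.  The bootstrap ratio
BSR = U / SD_boot(U) is thresholded at |BSR| > 2 to flag reliable regions,
and 2.5/97.5 percentile intervals of the per-condition brain-score-behavior
correlations flag LVs whose behavioral correlations cross zero.

A caveat the test suite quantifies: at 39 subjects the bootstrap SD of
correlation-based saliences underestimates the true sampling SD by roughly
10%, so the fraction of truly null regions exceeding |BSR| > 2 is nearer
0.09 than the nominal 0.05.  The recovery test therefore measures the
false-positive rate as an average over replicate cohorts, and users should
read |BSR| > 2 as "approximately 95% reliability", not an exact error rate.

### Reproducibility assessments

* **Test-train**: subjects are repeatedly split in half (timepoints held
  together; with an odd count the larger half trains — a fixed,
  documented rule).  The train half's singular vectors project the test
  half's decomposed matrix, s_test,l = u_l' R_test v_l, and
  z = mean/SD of the 500 test values.
* **Split-half**: both halves are decomposed independently and per-LV
  absolute cosine similarity of the brain saliences is recorded, with LVs
  matched greedily by maximal |cosine| (axis order can swap between
  halves); z = mean/SD of the similarities.  Absolute cosine is used
  because singular vectors are sign-indeterminate.

Each z is compared with a null z computed identically on row-permuted
data; an LV is called reproducible when z − z_null > 2.  The number of
permuted null datasets (default 100, each assessed with the same number of
splits) and the aggregation of per-permutation z values into z_null (their
mean) are choices the method description leaves open; both are exposed as
parameters.  When the split distribution is degenerate (identical halves),
the SD is zero and z is infinite — reported as-is.

### Specificity

`salience_cosine_specificity()` compares a salience against a second
analysis's salience by cosine, with a permutation p-value built by
permuting the second analysis's rows and collecting |cosine| values.

## Quality-control statistics

* **Fingerprinting**: each scan's upper-triangle FC vector is Pearson-
  correlated with every other scan; the match rate is the fraction of
  scans whose most-correlated other scan belongs to the same subject.
  Scans without a same-subject partner stay in the denominator as
  potential false matches, so the rate is conservative by construction.
* **QC-FC**: the fraction of edges whose across-scan values correlate with
  mean framewise displacement at uncorrected two-sided p < 0.05, plus the
  median edge-motion correlation.
* **Exclusion ledger**: sequential subtraction bookkeeping of QC stages
  with per-stage remaining counts.
* **Panel PCA**: variance fractions of the leading principal components of
  the column-centered metric panel.

## The synthetic cohort generator

The generator exists so every stage of the pipeline can be validated
against known ground truth.  It emulates:

* **Modular SC**: contiguous planted modules (default 4 over 193 regions);
  within-module edge intensities around 1 (presence probability 0.95),
  between-module around 0.25 (presence 0.6), truncated-normal draws, then
  row normalization and symmetrization through the same code path as real
  data.  Between-module intensity scales with the subject's age
  (`modularity_age_slope`, default 0.05/year relative to the 5.76-year
  cohort reference), so older children have relatively stronger
  between-module weights and lower Q — the test suite checks that the
  age-modularity correlation becomes more negative as the slope grows.
* **Coupled FC with retained negative weights**: a monotone map of SC
  (`fc_coupling_strength * sqrt(SC)`, default strength 3, putting values
  on a plausible Fisher-z scale) plus a subject-specific symmetric
  fingerprint component (variance share `fingerprint_icc`, default 0.6,
  identical at both timepoints) plus scan noise (total SD 0.15).  Negative
  weights arise from the noise, as they do from thresholded correlations.
* **A planted longitudinal change**: per-region deltas (default +-0.05 on
  regions 41-80) added to timepoint-2 edges as (delta_i + delta_j)/2, so
  the region's degree shifts by about delta/2.  The default is set so the
  planted change clearly dominates its noise budget — the scan latent
  described next contributes per-scan degree noise of the same order as a
  smaller delta would, which would leave the mean-centered reproducibility
  z-scores underpowered by design rather than by any property of the
  method.
* **A planted brain-behavior salience**: a unit-norm, zero-mean region
  pattern u* (+ on regions 1-20, − on 21-40 by default) loads a scan-level
  latent g onto FC edges as g * 0.2 * (u*_i + u*_j); behavior scores are
  age trends (slopes in the cohort's plausible range) plus beta * g
  (default beta = 3) plus noise.  The defaults are a deliberately strong
  effect: the generator's contract is that behavioral PLS recovers u* with
  |cosine| >= 0.9 and BSR sensitivity >= 0.8 at 39 subjects, and the
  design-stage power analysis showed the correlation sampling floor at
  n = 39 (r-noise SD ~ 1/sqrt(n)) makes weaker defaults sit on the margin
  of that contract.
* **Ages**: baseline uniform on 4.14-6.88 years, +1 year (with small
  jitter) at follow-up, matching the cohort ranges the pipeline targets.
* **Motion and QC-FC**: `generate_motion_confound()` returns per-scan
  motion and a scans x edges panel that is deliberately *unstructured*
  (iid noise edges, optionally contaminated by motion).  This isolates the
  calibration of the QC-FC estimator: with iid edges the pooled
  significant-edge count under no contamination is exactly binomial, so
  the test has a sharp reference distribution.

Everything is a pure function of (spec, subject, timepoint): per-scan
seeds are derived by hashing, generators save and restore the caller's RNG
state, and repeated calls are bitwise identical.

What the generator does **not** emulate: spatial embedding and
distance-dependent connectivity, hemispheric symmetry, realistic weight
distributions from tractography, BOLD autocorrelation, site/scanner
effects, or motion that correlates with age.  Passing tests on synthetic
cohorts therefore demonstrate that the estimators and resampling machinery
are correct and calibrated under the planted statistical structure — not
that any particular real-data finding is reproducible.

## Numerical choices and conventions

* Symmetry is enforced within 1e-12; diagonals are forced to zero on
  construction.
* Louvain move gains must exceed 1e-12 to count, preventing tie cycling;
  community ids are relabelled contiguously from 1 in first-appearance
  order.
* The two-condition mean-centered LV2 singular value is numerically zero;
  its permutation p-value is reported but meaningless (comparisons of
  floating-point zeros), and tests only interrogate informative LVs.
* Degenerate bootstrap resamples (e.g. a zero-variance behavior column
  after resampling) are skipped; a bootstrap SE of exactly zero yields a
  missing BSR with a warning.
* p-value denominators are n everywhere (not n + 1); zero counts are
  messaged as p < 1/n.

## Problem sizes in the test suite

The validation suite runs cohorts at the target scale (39 subjects x 2
timepoints x 193 regions) but scales resampling counts to keep the suite
fast: 200 calibration runs at 200 permutations, 30 recovery cohorts at 200
bootstraps, 50 reproducibility runs at 100 splits with 10-permutation
nulls, and 1000 null models on a 40-region planted network.  The
acceptance script uses the full defaults (1000 permutations, 500 splits)
for the single-cohort quantities it reports.

## Known limitations

* The Louvain optimizer is greedy; on large weakly-modular graphs it can
  return a local optimum (mitigated by restarts, quantified only for
  n <= 8).
* The strength sequence of the null models is approximated, not exact
  (~0.95 correlation on heterogeneous modular networks); annealing-based
  exact-strength nulls are out of scope.
* BSR thresholds behave approximately, as quantified above.
* The unrestricted permutation scheme is mildly anticonservative for
  paired cohorts with subject fingerprints; the paired scheme is provided
  and used for calibration-critical work.
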