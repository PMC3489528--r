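---
title: "Cross-validated semi-supervised rescoring of peptide-spectrum matches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated semi-supervised rescoring of peptide-spectrum matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmrescore)
```

## The problem

A shotgun-proteomics search engine matches each fragmentation spectrum to
the best-scoring peptide in a protein database, producing peptide-spectrum
matches (PSMs). Raw search scores separate correct from incorrect matches
imperfectly, and they carry no statistical interpretation on their own.
Two things are needed downstream: an *error rate* for any chosen score
threshold, and ideally a *better score* that combines several properties
of the match (score differences, peptide length, charge state, and so on)
into one discriminant.

Both needs are met with decoys. A decoy database of shuffled or reversed
protein sequences is searched separately from the target database; decoy
PSMs are incorrect by construction and are taken as a statistical model of
the incorrect target PSMs. `psmrescore` implements the standard
target-decoy error estimates and a semi-supervised learning scheme that
uses the decoys as negative examples — together with the cross-validation
protocol that keeps the learning honest.

## Target-decoy error estimation

For a score threshold $t$, with $D(t)$ decoy and $T(t)$ target PSMs
scoring at or above $t$,

$$\widehat{\mathrm{FDR}}(t) \;=\; \pi_0 \,\frac{D(t)}{T(t)} \;\wedge\; 1 ,$$

where $\pi_0$ is the expected fraction of incorrect matches among *all*
target PSMs. The q-value of a PSM with score $s$ is the minimum
$\widehat{\mathrm{FDR}}(t)$ over all thresholds $t \le s$ — the lowest
error rate at which that PSM would still be accepted
(`compute_qvalues()`). Two numerical conventions matter:

* **Ties.** At a tied score the decoy is counted as "at or above" the
  threshold before the target. This is the conservative direction; the
  alternative silently biases the FDR downward when scores are coarse.
* **$\pi_0$.** Each target score is converted to an empirical p-value
  against the decoy distribution, $p = (1 + \#\{d \ge s\})/(1 + \#d)$
  (the +1 avoids $p = 0$), and the fixed-$\lambda$ estimator
  $\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda)\,n_\text{targets})$ with
  $\lambda = 0.5$ is applied and clamped to $[0,1]$
  (`estimate_pi0()`). The fixed-$\lambda$ estimator is the simplest
  member of the family of low-score-based estimators used in this field;
  $\pi_0 = 1$ is available everywhere as the conservative fallback
  (`pi0_mode = "one"`).

## The self-training linear SVM

Correct and incorrect PSMs differ in more features than the raw score
alone. The learner combines the features $\mathbf{f}$ of a PSM into a
linear discriminant $s = \mathbf{w}\cdot\mathbf{f} + b$ by iterating, on
one training split (`self_train()`):

1. score every PSM with the current model — initially the single signed
   feature that alone yields the most targets at $q \le$ `q_select`
   (`choose_initial_direction()`; ties resolve to the lowest feature
   index, then to the + orientation, so initialization is deterministic);
2. select as *positives* the target PSMs at $q \le$ `q_select`
   (default 0.01); decoys are never positives;
3. fit a soft-margin linear SVM of the positives against **all** decoys,
   $$\min_{\mathbf w, b}\ \tfrac12\lVert\mathbf w\rVert^2
     + c_\text{pos}\!\!\sum_{i\in\text{pos}}\!\xi_i
     + c_\text{neg}\!\!\sum_{i\in\text{neg}}\!\xi_i ,$$
   with hinge slacks $\xi_i$ (`train_weighted_svm()`).

Ten iterations are run (`n_iter = 10`); a fixed count rather than a
convergence test keeps runs exactly reproducible. Targets that fail the
selection threshold are *unlabeled* — excluded from the objective, not
treated as negatives; treating ambiguous targets as negatives biases the
margin toward the decoy side. If an iteration selects no positives the
threshold is relaxed stepwise (0.01 → 0.05 → 0.10), and if selection is
still empty the current model is returned unchanged — this is the normal
exit on data with no signal.

Numerical choices:

* **Standardization.** Features are centred and scaled with statistics of
  the training split only; the model carries the transform back to the
  raw scale, so held-out PSMs are scored without touching held-out
  statistics. Hinge-loss solvers are scale sensitive, and per-split
  statistics avoid any information leak across the fold boundary.
* **Solver.** The weighted-hinge dual is solved by coordinate descent
  with liblinear-style shrinking, written for this package (in C++): the
  intercept is regularized via an augmented constant coordinate, sweeps
  visit examples in a seeded shuffled order, and iteration stops when the
  projected-gradient violation range falls below `tol = 0.1` (or after
  1000 sweeps). The solver is deterministic given its seed — it never
  touches R's RNG — and is validated in the test suite against an
  independent projected-gradient solution of the same dual and against
  libsvm. A dedicated solver is used because one full analysis performs
  on the order of $10^3$ SVM fits (see the fold/grid arithmetic below),
  which must complete in seconds, and because per-class costs and exact
  reproducibility are load-bearing here.
* **Costs.** The default grid crosses $c_\text{pos} \in \{0.1, 1, 10\}$
  with $c_\text{neg} = c_\text{pos}\cdot\{1, 3, 10\}$ — nine candidates.
  Asymmetric costs reflect the imbalance between the few selected
  positives and the full decoy set.

## Cross-validation

A model evaluated on its own training data is optimistically biased, and
with a target-decoy analysis that bias corrupts the *error estimates*
themselves, not just the ranking. The protocol (`assign_folds()`,
`run_cross_validation()`) therefore splits the **spectra** — not the
PSMs — into $k = 3$ folds by a seeded random permutation dealt
round-robin (fold sizes differ by at most one spectrum; all PSMs of one
spectrum share a fold, so near-duplicate matches of a spectrum cannot
straddle the training/validation boundary). For each fold, the other two
folds form the training split; the fold's PSMs are scored by a model that
never saw them.

Hyperparameters are chosen *inside* each training split by a nested
three-fold search (`grid_search()`): each candidate is self-trained on
each nested 2/3 and judged by the total number of held-out targets at
$q \le$ `q_select` on the nested 1/3s; ties resolve to the first
candidate in grid order. The nested search runs once per outer fold, so a
full 3-fold analysis performs $3 \times (9 \times 3 + 1) \times 10$ SVM
fits with the default grid. Every fold result records the identifiers of
its training PSMs, so the no-leakage guarantee is auditable after the
fact rather than assumed.

## Normalizing and merging the folds

The three folds are scored by three different classifiers whose decision
values are not mutually comparable, yet the user needs one ranked list.
Each fold gets an affine map fixed by two anchors of its own internal
target-decoy analysis (`fit_normalization()`): the lowest target score
with within-fold $q \le \alpha$ (default $\alpha = 0.01$, computed with
$\pi_0 = 1$ so the anchor is parameter-free) maps to **0**, and the
median decoy score maps to **−1**. Targets and decoys of a fold are
transformed identically, folds are concatenated, and one final
target-decoy analysis of the merged normalized scores yields the reported
q-values (`merge_folds()`). Affine maps with positive slope preserve
within-fold ranking exactly. This linear rescaling is a pragmatic
heuristic — there is no established method for placing separately
trained classifiers on a common scale — but the anchors give both fixed
points a direct error-rate meaning.

Degenerate folds are handled explicitly: if no target reaches
$q \le \alpha$, the threshold anchor falls back to the top-ranked
target's score with a warning (normal on signal-free data); if even that
score does not exceed the decoy median, the fold cannot be calibrated and
the run stops with an error. Even decoy counts use the mean-of-middle-two
median. Decoy PSMs appear in the output with the q-value of the best
target at or below their score, so the written table has a complete,
bounded q-value column.

## The simulation: what it emulates and what it shows

`generate_dataset()` builds datasets in which correctness is known: 2500
target and 2500 decoy PSMs, 50 i.i.d. $N(0,1)$ features, and an offset of
10.0 added to feature 1 of 1000 targets, which thereby become the
"correct" matches. Decoys and incorrect targets are exchangeable by
construction — exactly the assumption target-decoy analysis rests on. The
ground-truth flags are returned *next to* the learner-facing dataset, not
inside it, so truth cannot leak into features, labels, or fold decisions
by construction of the API. One synthetic spectrum per PSM; the
simulation has no spectrum structure to model.

`run_experiment()` repeats generation and rescoring over replicate
datasets and records, on a q grid from 0 to 0.1 in steps of 0.002 (a
smooth grid covering the range where thresholds are actually chosen), the
number of accepted targets and the realized false discovery proportion
(FDP) among them, aggregated as medians with 5%/95% quantile bands. A
perfectly calibrated procedure accepting at q-value $q$ reports
$n_\text{correct}/(1-q)$ PSMs (`ideal_identification_count()`); with
1000 correct matches that is ≈ 1010 at $q = 0.01$, and the
cross-validated pipeline's median lands within a few PSMs of it (the
acceptance script recomputes this).

With `with_cv = FALSE` the protective machinery is switched off:
hyperparameters are picked by performance on their own training data and
one model is trained on all PSMs and evaluated on those same PSMs. On
pure-noise datasets ($n_\text{correct} = 0$, where every acceptance is
false) this train-equals-test condition reports large numbers of
"significant" PSMs at $q \le 0.01$ while the cross-validated run reports
essentially none — the overfitting pathology the protocol exists to
prevent, reproduced by `run_experiment()` and asserted in the test suite.

Replicate counts are configurable; the package's own checks use 10
replicate datasets, which is enough for the medians to stabilize within
the tolerance bands asserted in the tests, and the FDP at a grid point is
undefined (NA, dropped from aggregation) for datasets accepting nothing
there.

## What the simulation does *not* show

The generator draws independent Gaussian features, so passing these
checks does not certify behaviour on real data, where features are
correlated, heavy-tailed, and confounded (precursor charge correlating
with the raw score is the classic example); where several PSMs share a
spectrum and peptides recur across spectra (the protocol splits by
spectrum, so peptide-level dependence across folds remains possible —
a documented caveat, not handled); and where the decoy model itself can
be imperfect, e.g. features like matches-per-peptide that differ subtly
between decoys and incorrect targets. Validating the decoy assumption
requires samples of known content and is outside this package's scope,
as are the search itself, decoy database construction, target-decoy
competition, and protein inference.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `q_select` | 0.01 | q threshold selecting positive examples (unitless FDR) |
| `n_iter` | 10 | self-training iterations, fixed count |
| grid | 9 candidates | $c_\text{pos}\in\{0.1,1,10\}$, $c_\text{neg}/c_\text{pos}\in\{1,3,10\}$ |
| `k` | 3 | cross-validation folds (by spectrum) |
| `alpha` | 0.01 | q anchor of the per-fold normalization |
| `pi0_mode` | fixed-lambda | $\lambda=0.5$ empirical-p-value estimator; `"one"` for $\pi_0=1$ |
| solver `tol` | 0.1 | projected-gradient stopping range (dual) |
| q grid | 0–0.1 by 0.002 | curve grid of the simulation experiment |

One master seed drives fold assignment, solver sweep order, and data
generation; derived sub-seeds keep the components independent while the
whole run stays bitwise reproducible.
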