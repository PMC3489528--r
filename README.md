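# psmrescore

Cross-validated semi-supervised rescoring of peptide-spectrum matches
(PSMs) from shotgun proteomics, with target-decoy error estimation.

In a shotgun-proteomics experiment each fragmentation spectrum is matched
against a protein database and the match is scored; a parallel search
against a *decoy* database of shuffled/reversed sequences yields matches
that are incorrect by construction and serve as a statistical model of
the incorrect target matches. `psmrescore` is for analysts who have such
separate target and decoy search results, one feature vector per PSM, and
want (i) calibrated error rates and (ii) a better discriminant score
learned from the features — without the learning step corrupting the
error rates.

The package implements:

* **Target-decoy FDR and q-values.** For a threshold *t*,
  `FDR(t) = pi0 * D(t) / T(t)` (capped at 1), with `D`, `T` the decoy and
  target counts at or above *t* and `pi0` the fraction of incorrect
  matches among targets, estimated from empirical p-values with a
  fixed-lambda estimator. The q-value of a PSM is the minimum FDR over
  all thresholds that accept it. (`compute_qvalues()`, `estimate_pi0()`)
* **A self-training linear SVM.** Decoys are negatives; targets at
  `q <= 0.01` under the current score are positives; a weighted
  soft-margin linear SVM (`min ½‖w‖² + c_pos·Σξ_pos + c_neg·Σξ_neg`) is
  refit for 10 iterations. (`self_train()`, `train_weighted_svm()`)
* **Three-fold cross-validation.** Spectra are split into three folds;
  each fold is scored by a model trained on the other two, with
  hyperparameters chosen by a *nested* three-fold grid search inside each
  training split. Every PSM is scored by a model that never saw it, and
  each fold result records its training PSM ids so this can be audited.
  (`assign_folds()`, `run_cross_validation()`, `grid_search()`)
* **Score normalization and merging.** Each fold's scores are mapped by
  the affine transform pinning the within-fold `q = 0.01` threshold score
  to 0 and the decoy median to −1; folds are merged and final q-values
  computed on the common scale. (`fit_normalization()`, `merge_folds()`)
* **A calibration/overfitting simulation.** Synthetic datasets with known
  correctness (2500 targets + 2500 decoys, 50 N(0,1) features, offset
  10.0 on feature 1 for 1000 targets) measure whether reported q-values
  match the realized false discovery proportion — and demonstrate how
  disabling cross-validation inflates the identification count.
  (`generate_dataset()`, `run_experiment()`)

The methods vignette (`vignettes/rescoring-methods.Rmd`) documents the
model, the defaults, and the numerical choices.

## Worked example

Rescore a tab-delimited PSM table (`SpecId`, `Label` = 1/−1, `ScanNr`,
feature columns, optional `Peptide`/`Proteins`):

```r
library(psmrescore)
cmd_rescore("spectra.pin", "spectra.psms.tsv", seed = 3)
```

On a 60-PSM toy input (30 targets, 30 decoys, 3 features, 15 targets with
an informative first feature) this prints:

```
config: input=spectra.pin output=spectra.psms.tsv k=3 q_select=0.01 alpha=0.01 pi0=fixed-lambda seed=3 cv=TRUE
read 60 PSMs (30 targets, 30 decoys), 3 features
fold sizes (spectra): 20/20/20
fold 1: c_pos=0.1 c_neg=0.3
fold 2: c_pos=1 c_neg=3
fold 3: c_pos=0.1 c_neg=0.3
pi0 = 0.2667; 17 target PSMs at q <= 0.01
wrote spectra.psms.tsv
```

Reading down: the 60 spectra were dealt into three folds of 20; the
nested grid search picked per-fold SVM costs; the estimated fraction of
incorrect matches among targets is 0.27 (15 of the 30 targets were
informative, plus a few lucky noise targets rank above the decoys); and
17 targets are accepted at a 1% FDR. The output table is sorted by
descending normalized score:

```
psm_id   label  score             q_value  peptide
psm012   1      7.42965518129174  0        PEP012K
psm015   1      7.08509221829947  0        PEP015K
psm013   1      7.0352479584204   0        PEP013K
```

Scores are on the normalized scale (0 = the fold's 1% FDR threshold,
−1 = the fold's decoy median), so a score above 0 means "accepted at 1%
FDR in its fold".

The same pipeline is callable on in-memory data via `rescore()`, and the
simulation via `run_experiment()` / `cmd_simulate()`. A thin shell
wrapper with the same options is installed at `inst/cli/psmrescore`:

```sh
Rscript inst/cli/psmrescore rescore --pin spectra.pin --out spectra.psms.tsv --seed 3
Rscript inst/cli/psmrescore simulate --out curves/ --datasets 10 --seed 1
```

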