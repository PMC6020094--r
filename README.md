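# admetkit

Tools for building and using QSAR models of ADMET endpoints — the
absorption, distribution, metabolism, excretion and toxicity properties
that decide whether a small molecule can become a drug. The package is
aimed at computational and medicinal chemists who want the full
model-building loop as inspectable, scriptable functions: from raw
SMILES/SDF through structure washing, featurization, diversity-based
splitting, descriptor selection, grid-searched and imbalance-aware
training, a complete metric suite, drug-likeness screening, per-molecule
ADMET profiles, and search over a local ADMET record store.

## The methods at its core

* **Washing**: salt disconnection (alkali/alkaline-earth metal–O/N/S
  bonds), largest-fragment retention, explicit hydrogens; idempotent,
  with every removal logged.
* **Features**: 11 classical 2D descriptor families (113 descriptors) and
  five fingerprints — FP2-style linear paths up to 7 atoms (2048 bits),
  MACCS keys (167-bit layout), ECFP2/4/6 (circular radius 1/2/3, 2048
  bits).
* **Diverse split**: max–min picking on Tanimoto distance over ECFP4,
  75/25 by default, so the training set covers chemical space.
* **Selection**: a three-rule pre-filter (near-zero variance, >95%
  identical values, pairwise |r| > 0.95) followed by recursive feature
  elimination with 1000-tree random forests (`mtry = √p`), removing the
  two least important descriptors per step with 5-fold CV scoring.
* **Models**: RF, RBF-SVM, PLS and CART regression; RF, RBF-SVM, naive
  Bayes and decision-tree classification. Two-stage grid searches:
  RF `mtry` ladder 1, 21, 41, … then ±50 at step 2 with
  `estimators ∈ {500, 1000}`; SVM exponent ladders `C = 2⁻⁵…2¹⁵`,
  `Sigma = 2⁻¹⁵…2³` then ±2 at step 2^0.25; PLS components 1…100.
* **Imbalance**: balanced per-tree sampling (every tree sees
  `samplesize` compounds of each class) and a 10-member resampling
  consensus averaging member probabilities; both close the SE/SP gap.
* **Evaluation**: R²_F/RMSE_F, Q²/RMSE_cv, R²_T/RMSE_T (all against the
  training-set mean), ACC/SP/SE/AUC, Cohen's kappa, and fold-error rates
  (`fold = 1 + |ŷ − y|/y`, within-2-fold / within-3-fold).
* **Screening and search**: Lipinski/Ghose/Oprea/Veber/Varma rule
  batteries with editable thresholds; accurate/range/similarity search
  (Tanimoto or Dice over any fingerprint) on a local record store;
  "+/−" symbol profiles for classification endpoints.

A synthetic-data module (fragment-grammar molecule corpora and
linear-model feature/label datasets with known ground truth) makes the
entire pipeline testable offline.

## Worked example

```r
library(admetkit)

# 1. a synthetic QSAR problem: 300 compounds, 50 descriptors, 5 informative
gen <- generate_qsar_dataset(synthetic_spec(
  300, "regression", n_features = 50, n_informative = 5,
  noise_sigma = 0.5, seed = 7))

# 2. pre-filter and recursive feature elimination
pf   <- prefilter(gen$dataset$features, seed = 7)
ds   <- labeled_dataset(pf$matrix, gen$dataset$y, task = "regression")
path <- rf_rfe(ds, cv_folds = 5, step = 2, estimators = 1000, seed = 7)
print(path)
#> <rfe_path: 25 steps, sizes 50..2, best 6 features (score 0.769)>
sum(gen$informative %in% select_best(path))
#> [1] 5

# 3. wash and screen real structures
rec <- molecule_record("CC(=O)Oc1ccccc1C(=O)O[Na]", id = "aspirin_na")
w   <- wash_molecule(rec)
w$smiles
#> [1] "CC(=O)Oc1ccccc1C(=O)[O-]"
evaluate_rule(w, default_rules()$lipinski)$overall_pass
#> [1] TRUE
```

The RFE path above recovers all five planted descriptors; washing the
sodium salt disconnects the metal and keeps the carboxylate fragment.

## Command line

A thin CLI over the same functions lives at `inst/cli/admetkit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","admetkit.R", package="admetkit"))')" \
  wash --in molecules.smi --out washed.smi --report report.csv
```

Subcommands: `wash`, `featurize`, `split`, `select`, `train`, `eval`,
`rules`, `search`, `profile`, `simulate`; all accept `--config FILE`
(key = value) with command-line flags taking precedence, and print their
fully resolved configuration.
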