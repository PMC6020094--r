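---
title: "Building ADMET QSAR models with admetkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building ADMET QSAR models with admetkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

admetkit implements the full model-building workflow used for ADMET
(absorption, distribution, metabolism, excretion, toxicity) endpoint
prediction: structure standardization, featurization, diversity-based
splitting, descriptor selection, grid-searched training with
imbalance-aware strategies, and a complete evaluation suite. This vignette
explains the methods, the tunable parameters, and the design choices made
where the procedure left genuine freedom.

## Structure handling and washing

Molecules enter as SMILES, SDF (V2000) or CSV and are parsed through Open
Babel; all downstream computation operates on an internal heavy-atom graph
(elements, formal charges, attached-hydrogen counts, kekulized bond
orders). Washing applies three steps, in order:

1. **Salt disconnection.** Bonds between alkali/alkaline-earth metals (Li,
   Na, K, Rb, Cs, Be, Mg, Ca, Sr, Ba) and O/N/S are cleaved
   heterolytically: the metal keeps a positive formal charge equal to the
   bond order, the heteroatom gains the matching negative charge. This
   approximates the conventional "simple salt" dictionaries of commercial
   washing tools; it does not claim bit-compatibility with any of them,
   and tautomer or charge standardization beyond this step is out of
   scope.
2. **Largest fragment.** The fragment with the most heavy atoms is kept.
   Ties are broken by molecular weight, then by lexicographically smallest
   canonical SMILES, so the output is deterministic.
3. **Hydrogen normalization.** Hydrogens are made explicit on the stored
   graph (they drive hydrogen-bond counts and E-state values); the stored
   SMILES stays in implicit-hydrogen canonical form.

Washing is idempotent: a washed molecule passes through unchanged. A
molecule left with no heavy atoms is removed with reason
`EMPTY_AFTER_WASH`; unparseable inputs are logged as `UNPARSEABLE`, never
silently dropped; duplicated ids are suffixed with an ordinal and logged.

## Features

Two feature classes share one container (`feature_matrix`, molecules x
named features with per-column family tags):

* **Fingerprints.** `fp2` hashes all linear paths of up to 7 atoms into
  2048 bits; `ecfp2`/`ecfp4`/`ecfp6` are extended-connectivity
  fingerprints with circular radius 1/2/3 folded to 2048 bits (the names
  follow the convention that reads the trailing number as a diameter);
  `maccs` is the 166 structural keys in the conventional 167-bit layout,
  computed by Open Babel. Path and circular identifiers are hashed with a
  package-defined deterministic polynomial hash: the enumeration, not any
  external toolkit's bit order, defines equality for `fp2` and the ECFPs.
  Unfolded ECFP identifier sets are nested by radius by construction,
  which the tests assert directly.
* **Descriptors.** Eleven families (constitutional, topological,
  connectivity chi, E-state, kappa shape, Basak information content,
  Burden eigenvalues, Moreau-Broto autocorrelation, charge, molecular
  property, MOE-type), 113 columns in total; `descriptor_manifest()`
  documents the exact membership. Family membership is the contract —
  counts differ from other descriptor engines because each engine chooses
  its own variants. The property family is exactly MW, LogP, TPSA, HBA,
  HBD and MR (from Open Babel, so LogP is a standard atom-contribution
  model). The charge family uses electronegativity-difference proxies
  rather than an iterative partial-charge scheme; Burden eigenvalues pad
  with the extreme eigenvalue for molecules smaller than the descriptor
  width. Matrices never contain NaN: molecules that fail are excluded and
  reported.

## Dataset pretreatment and the diverse split

Four pretreatments precede modeling: entries without an explicit value are
dropped; duplicated classification compounds keep one entry when their
labels agree and are dropped entirely on conflict (choosing a label
arbitrarily would inject noise); duplicated regression measurements are
replaced by their arithmetic mean when the relative spread
`(max - min)/|mean|` stays within `rel_spread_limit`, and deleted
otherwise. The limit is not quantified by convention, so the default is
0.5, configurable; when a group mean is numerically zero the absolute
range is compared against 1e-8 instead.

The train/test split follows chemical space, not uniform sampling:
max-min (Kennard-Stone-style) picking on Tanimoto distance over ECFP4
bits. The first pick is the molecule with the highest mean distance to
all others; each subsequent pick maximizes the minimum distance to the
selected set. The seed only breaks exact-distance ties, so the split is
effectively deterministic. The training size is `fraction * n` rounded
half up, 75% by default. Max-min picking guarantees (in expectation) that
the training set's nearest-neighbour distances dominate those of a random
subset of equal size, which the property tests verify over 20 corpora.

## Descriptor selection

The pre-filter applies three rules in order: (1) zero or near-zero
variance — judged scale-free, variance after dividing the column by its
largest absolute value below 1e-8; (2) modal-value frequency above 95%
(the rule speaks of "identical values", read here as the frequency of the
most common value); (3) absolute Pearson correlation above 0.95, removing
one member of each offending pair — at random under the supplied seed, or
the later column in name order when no seed is given.

Recursive feature elimination then iterates: fit a 1000-tree random
forest with `mtry = floor(sqrt(p))`, rank features by impurity importance
(Gini for classification, variance reduction for regression; permutation
importance is out of scope), record the 5-fold cross-validated score of
the current feature set, remove the two least important features, repeat
down to two features. The best step maximizes the CV score, ties broken
toward fewer features. The step index is folded into the seed so the
whole path is reproducible. The forests use the ranger implementation on
a single thread; determinism and the importance definition, not the
backend, are the contract.

## Models, grids and imbalance strategies

Regression supports random forest, RBF SVM, PLS and CART regression
trees; classification supports random forest, RBF SVM, naive Bayes and
CART decision trees (naive Bayes and PLS are intrinsically
task-specific). Naive Bayes uses a Bernoulli event model on fingerprint
bits and a Gaussian model on continuous descriptors. The SVM's `Sigma`
parametrizes the kernel as `exp(-||x - z||^2 / (2 Sigma^2))`; features
are z-score standardized inside the SVM and PLS pipelines using training
statistics, because RBF kernels and PLS loadings are scale-sensitive.
PLS fits go through the mixOmics implementation.

Hyperparameters come from two-stage grid searches with fixed schedules:

* Random forest: stage 1 crosses `estimators` in {500, 1000} with
  `mtry` in {1, 21, 41, ...} up to `p`; stage 2 rescans
  `mtry' - 50 .. mtry' + 50` at step 2. When that window leaves `[1, p]`
  it is clipped to the ladder's intersection with `[1, p]` rather than
  skipped, so small-p datasets still get a stage 2.
* RBF SVM: stage 1 scans exponent ladders `C = 2^-5 .. 2^15` (step
  `2^2`, 11 points) and `Sigma = 2^-15 .. 2^3` (10 points); stage 2
  jointly rescans both exponents within the stage-1 best +/- 2 (one
  coarse step) at step 0.25.
* PLS: `n_components` from 1 to `min(100, p, n - 2)`, best by Q2, ties
  toward fewer components.

All grid points are scored by 5-fold CV — Q2 for regression, accuracy for
classification. Classification folds that degenerate to a single class
are redrawn up to three times before erroring.

Two strategies address class imbalance:

* **Balanced per-tree sampling** grows every tree on exactly
  `samplesize` positives and `samplesize` negatives drawn without
  replacement (default `min(100, minority size)`). The tree count is
  chosen so that every training compound lands in at least one tree's
  sample with probability at least 0.99 — the operational reading of
  "every compound could be used" — with a floor of 500 trees; a
  user-supplied tree count below that bound only warns.
* **Resampling consensus** trains 10 members, each on all minority
  compounds plus an equal-size without-replacement subsample of the
  majority, and averages member probabilities (labels at 0.5). Mean
  probability was chosen over majority vote because it preserves ranking
  information for AUC.

On synthetic 9:1 data both strategies cut the mean |SE - SP| gap by an
order of magnitude relative to a standard forest; the acceptance tests
reproduce this at n = 1000 over 10 seeds.

## Evaluation

Regression reports the three R2/RMSE pairs (fit, cross-validation, test).
R2 is always computed against the training-set mean — including test-set
R2, which therefore measures improvement over predicting the training
mean rather than the test mean; this deliberate contract can make values
differ from implementations that re-center on the test set.
Classification reports ACC, SP, SE, rank-statistic AUC (ties count 1/2)
and Cohen's kappa (defined as 0 with a warning when both raters are
constant and equal). Fold errors use `fold = 1 + |y_pred - y_true| /
y_true`, with within-2-fold and within-3-fold rates using `<=` (the
boundary convention is not fixed anywhere authoritative; `<=` is this
package's choice) and are undefined at non-positive observations.
Cross-validation shuffles indices under the seed and deals them
round-robin, so fold sizes differ by at most one; classification CV is
not stratified by default (a `stratify` flag exists for skewed classes,
matching the plain "roughly equal-sized parts" recipe when off). Every
metric is
tested against an independent brute-force implementation to 1e-10 on
randomized instances.

## Drug-likeness rules and profiles

The five rule batteries (Lipinski, Ghose, Oprea lead-like, Veber, Varma)
are plain data over nine physicochemical descriptors; the published
threshold variants differ between sources, so the shipped values are a
documented choice and a `rule.descriptor = value` config file can
override any bound without code changes. Lipinski allows one violation;
the others none. Varma's logD criterion uses LogP as a proxy — logD
modeling is out of scope. Every criterion is evaluated and reported, and
a molecule whose descriptors cannot be computed is flagged
`INCOMPUTABLE`, never silently passed.

ADMET profiles run a registry of endpoint models on one molecule:
regression endpoints render value + unit, classification endpoints render
probability plus a symbol from fixed bands ([0, 0.1] -> "---" up to
(0.9, 1] -> "+++"); the bands are this package's convention, chosen so
symbol count tracks how decisively a probability sits in its class.
Store search supports accurate (canonical SMILES, case-insensitive
CAS/IUPAC), range (inclusive bounds over MW/AlogP/HBA/HBD, conjoined) and
similarity search (Tanimoto or Dice over any of the five fingerprints;
hits sorted by descending score, ties by entry id). The bundled
20-entry store is synthetic demonstration data, as its filename states.

## Synthetic data: what it does and does not show

The corpus generator assembles molecules from a fragment grammar (ring
cores x substituent alphabet), enforcing distinctness on canonical
SMILES; with salts enabled, 20% of records get a counter-ion (sodium
carboxylate for terminal acids, hydrochloride otherwise). The QSAR
generator draws i.i.d. standard-normal features and a linear score
`X beta + eps` with `eps ~ N(0, sigma^2)`; regression uses the score
directly, classification thresholds the logistic transform at the
empirical quantile hitting the requested class balance exactly (up to
ties). Default conditions used throughout the tests: n = 300, p = 50,
5 informative features with coefficient magnitudes in [1, 2] and
alternating signs, sigma = 0.5 for selection; n = 1000 with 10% positives
for the imbalance experiments. These sizes keep the full suite within
desktop minutes while leaving the recovery problems non-trivial.

Passing on this generator shows the pipeline recovers planted linear
signal and corrects sampling imbalance; it does not show anything about
real ADMET data, whose features are correlated, whose signal is
non-linear in descriptors, and whose label noise is structured.
Reproducing published per-endpoint performance additionally requires the
corresponding curated datasets, which are not bundled.

## Numerical choices and limitations

* Canonical SMILES, and therefore record identity, are Open Babel's; a
  different toolkit's canonical forms will differ textually.
* Fingerprint hashing uses a 31-bit polynomial hash; folded-bit
  collisions are possible at 2048 bits, as in any folded fingerprint.
* The RFE path refits CV folds at every step; with 1000-tree forests the
  n = 300, p = 50 study condition takes on the order of a minute per
  seed on one core.
* Gasteiger-style iterative partial charges, 3D descriptors, scaffold
  splits, probability calibration beyond the consensus mean, and
  applicability-domain estimation are out of scope.
* The command line (`inst/cli/admetkit.R`) is a thin veneer: every
  subcommand resolves defaults < config file < flags through
  `resolve_config()` and prints the resolved configuration for
  reproducibility.
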