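---
title: "Methods: multi-level screening for ESIPT fluorophores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level screening for ESIPT fluorophores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Excited-state intramolecular proton transfer (ESIPT) fluorophores carry
an intramolecular hydrogen-bond donor (typically a phenolic -OH, sometimes
-NH2) adjacent to an acceptor (=N- or C=O). Photoexcitation triggers an
enol-to-keto tautomerization whose products emit with very large Stokes
shifts, which makes these dyes attractive for bioimaging probes. Finding
new ones in a large purchasable-compound library is a needle-in-haystack
problem that this package attacks with a three-level prediction system:

1. **E-CM** -- a binary classifier separating ESIPT candidates from
   ordinary (non-fluorescent) small molecules;
2. **E-FL** -- a second classifier separating ESIPT candidates from
   *other fluorophores*, a deliberately harder contrast because generic
   dye features (conjugation, rings) no longer discriminate;
3. **E-Barrier** -- a regressor for the activation energy of the
   excited-state proton transfer in kcal/mol. A barrier above roughly
   15--20 kcal/mol means the transfer cannot occur, so predicted
   barriers annotate candidates with a feasibility call
   (`barrier_feasibility()`, closed cutoff, default 15, configurable to
   20).

A screening run (`run_cascade()`) prefilters a library on molecular
weight (50--200 Da) and logP (1--5, closed intervals), applies both
classifiers at a probability threshold (default 0.9, compared with
`>=`), and annotates survivors with predicted barriers. For
structural-innovation scoring, the threshold is relaxed to 0.8 and the
survivor pool deduplicated at Tanimoto 0.8
(`relax_and_diversify()`), mirroring the strategy of casting a wider
net and keeping one representative per structural family.

## Representations

Molecules enter as SMILES (`read_molecules()`: CSV, `.smi`, SDF) and are
canonicalized through Open Babel; salts are reduced to the largest
covalent fragment. Three representations are available:

* **ECFP4** (`compute_ecfp4()`): circular fingerprint of radius 2,
  folded from the raw 4096-bit vector to 2048 bits by OR-ing congruent
  positions. ECFP4-RF is the default classifier combination.
* **MACCS** (`compute_maccs()`): the 166 keyed substructure bits with
  standard key numbering, so that interpretation can name keys (key 139
  = O-H, key 151 = N-H). Used for similarity curation and for the
  interpretable MACCS-RF models.
* **2D descriptors** (`compute_descriptors_2d()`): a fixed panel of 161
  descriptors -- Open Babel bulk properties (MW, logP, TPSA, MR, H-bond
  donor/acceptor counts), an ESOL-style logS estimate, Gasteiger
  partial-charge summaries, graph statistics, and ~130 SMARTS
  substructure counts covering the property families that matter for
  proton transfer: donors/acceptors, acidity/basicity proxies,
  conjugation, oxygen content, formal charge. Commercial 3D/conformer
  descriptors are out of scope; pKa-type information is approximated by
  rule-based acidic/basic group counts.

Descriptor matrices are pruned before modelling (`prune_features()`):
zero-variance columns are dropped, then a single ordered pass drops any
feature correlating above |r| = 0.95 with an earlier kept feature (the
earlier-ordered feature wins -- deterministic and documented; pairs with
undefined correlation count as uncorrelated).

## Training protocol

`make_split()` holds out 25% for testing and partitions the rest into
five stratified cross-validation folds. Stratification uses
largest-remainder allocation for the test set and a class-blocked
round-robin for folds, so fold sizes balance globally to one sample and
class ratios within each fold to one sample. Everything is
deterministic under the seed.

Six learners are available behind one interface
(`model_config()` / `fit_model()`): random forest (500 trees by
default), RBF-kernel SVM with probability calibration (cascade
thresholds act on probabilities), gradient-boosted trees (300 rounds,
depth 6, eta 0.1), k-nearest neighbours (k = 5), a CART decision tree,
and a single-hidden-layer neural network behind the MLP flag.
Hyperparameters are deliberately fixed defaults rather than tuned;
reproducibility was preferred over squeezing accuracy, and every fit is
bit-reproducible under its seed. Evaluation follows the formulas in
`classification_metrics()` (ACC, SP, SE, F1, and rank-based AUC with
half-credit ties) and `regression_metrics()` (R^2, MAE, RMSE, Pearson
correlation, and fold rates, where `fold_i = 1 + |yhat - y| / y` and a
prediction succeeds when fold < 2, strictly -- the strict inequality is
taken from the stated success rule).

The barrier pipeline runs prune -> ECOD outlier exclusion -> RFE -> fit.
`ecod_outliers()` scores each sample by per-dimension empirical-CDF
tail probabilities (the larger of left/right/skewness-chosen aggregated
negative log tails) and removes the top fraction (default contamination
0.15, approximating the ~15% exclusion the method applies).
`rfe_select()` recursively drops lowest-importance features under a
random-forest base learner until 25 remain; elimination order is
recorded, making selections nested across target sizes. Whether
outlier removal precedes or follows pruning is not prescribed anywhere;
this package fixes the order prune -> outliers -> RFE -> fit and
documents it.

## Interpretation

`shapley_attribution()` explains classifier probabilities by Shapley
values. For random forests the values are **exact** interventional tree
Shapley values: for each background row the coalition game
v(S) = f(x with features S, background elsewhere) restricted to one
tree decomposes over leaves into AND-of-literals games with a
closed-form Shapley solution; contributions are averaged over trees and
a background sample (<= 200 rows, fixed seed). The additivity identity
`base + sum(shap) = prediction` holds to machine precision and is
asserted in tests, as is agreement with full coalition enumeration on
8-feature models. Non-tree models fall back to a seeded
permutation-sampling estimator. Global importance is the mean absolute
Shapley value over the evaluation set; `top_features()` ranks with
lexicographic tie-breaks, `overlap_features()` intersects two models'
top-k lists, `force_breakdown()` gives the per-molecule signed picture,
and `bit_to_substructure()` + `substructure_rules()` turn highly ranked
MACCS bits into SMARTS-backed structural rules (composite keys --
count-based or undefined -- are flagged rather than forced into a single
SMARTS).

## Candidate-scoring strategies

Three configurable strategies rank survivors (`strategy_rules()`,
`score_strategy()`):

* **safety** over LD50, AMES, skin sensitization, hERG, DILI;
* **pharmacokinetics** over VDss, Fu, CL, T1/2, PPB;
* **structural innovation** via `innovation_rank()`.

Ratings are consumed as categorical Excellent/Medium/Poor tables
(`property_rating_table()`): +1, +0.5, +0 points per property
(weights configurable, defaults 1, so five properties span 0--5).
ADMET predictors are web services and are *not* reimplemented; the
package defines a provider-agnostic rating-table contract with a CSV
importer and a synthetic provider. The innovation score combines
novelty (1 - maximum Tanimoto to the known-ESIPT reference set) with
Murcko-scaffold rarity (inverse scaffold frequency), equally weighted
by default. `diversity_score()` is defined as one minus the mean
pairwise Tanimoto similarity -- the most common [0, 1] diversity
statistic; a scaffold-count ratio is easy to compute from
`murcko_scaffolds()` if preferred. Murcko scaffolds are extracted by
iterative terminal-atom stripping (leaving rings plus linkers) followed
by re-attachment of multiply-bonded substituents such as carbonyl
oxygens; acyclic molecules map to the empty scaffold and are flagged.

## The synthetic study

Because the curated experimental datasets behind the method are not
deposited, the package ships a generator whose ground truth is known by
construction (`synthetic_spec()` and `gen_*`):

* **positives** decorate four classic ESIPT scaffolds -- HBT, HBO, HBI,
  and a salicylaldehyde azine -- with 0--3 substituents drawn from
  {F, Cl, Br, CH3, OCH3, N(CH3)2, CN, NO2}; every molecule matches the
  planted motif SMARTS `[OX2H]c1ccccc1[#6]~[#7X2]` (o-hydroxyaryl donor
  adjacent to a =N- acceptor);
* **conventional negatives** are ten drug-like mono/acyclic templates
  (amides, esters, sulfonamides, saturated heterocycles);
* **fluorescent negatives** are conjugated dye scaffolds (coumarins,
  a naphthalimide, stilbene, anthracene, a flavone) without the
  o-hydroxy donor -- verified to sit closer to the positives in
  fingerprint space than the conventional set, reproducing the
  two-tier difficulty of the real problem.

Rejection sampling guarantees motif precision/recall of exactly 1
against the labels, which tests assert to guard generator regressions.
Synthetic barriers are a smooth monotone function of descriptors, not
physics: with z-scored descriptor signal s (weights on TPSA, logP, MW,
aromatic-atom count, HBD) and relative noise sd 0.3,
`barrier = 0.3 + 2.2 * softplus(1.2 * (s + noise) + 2)` capped at 20 --
positive, right-skewed, spanning the feasible range with a floor far
enough from zero that fold errors remain informative. Rating tables
draw independent categorical ratings from a configurable distribution.

What passing on this study shows -- and what it does not: the tests
demonstrate that the statistical machinery (featurization, validation
protocol, cascade logic, attribution, scoring) is correct and that the
planted signal is recovered; template-based molecules are far more
separable than curated experimental sets, so the near-perfect synthetic
accuracies say nothing about accuracy on real libraries, where the
published figures are around 0.90 ACC for the classifiers and much
weaker (R^2 ~ 0.43) for barrier regression.

## Problem sizes and numerical choices

The validation studies use 500 molecules per class for classification
recovery (5 seeds; 10 seeds for the MACCS interpretation check), 600
molecules for barrier regression, 500-molecule libraries for cascade
sweeps, and 150--200 random-forest trees in the recovery experiments
(the saturated synthetic signal makes more trees pure runtime; the
package default stays at 500). The acceptance script trains at 400 per
class, screens 500, and regresses on 600 with RFE step 5. Tolerances:
metric oracles agree to 1e-12; exact Shapley to 1e-6 against coalition
enumeration; ECOD scores to machine rounding (the independent oracle
sums in a different order). Ties are broken deterministically
everywhere: first-kept-wins in greedy dedup, earlier column wins in
correlation pruning, lexicographic feature names in Shapley rankings,
id order in candidate rankings. Degenerate inputs (single-class labels,
non-finite features, unparseable SMILES, non-positive barriers) raise
typed errors or per-molecule failure records rather than silent
results; a screening run never aborts on one bad molecule.

## Known limitations

* Open Babel's logP/descriptors differ from the ZINC/MOE values used in
  the original screen; prefilter boundaries are therefore approximate
  relative to vendor-annotated property windows.
* MACCS key 125 (aromatic-ring count) follows Open Babel's ring
  counting, which differs from RDKit's on fused systems; the other 165
  keys are verified bit-exact against RDKit on a 65-molecule reference.
* Exact tree Shapley is implemented for random forests; boosted trees
  use the sampling estimator (their built-in path-dependent attribution
  is a different quantity and is deliberately not substituted).
* The barrier generator tests regression machinery, not chemistry; no
  physical meaning attaches to its coefficients.
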