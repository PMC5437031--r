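---
title: "Ensemble fingerprint models for chemical carcinogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble fingerprint models for chemical carcinogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CarcinoEnsemble)
```

## The modeling problem

Rodent carcinogenicity is a binary toxicological endpoint: a compound
either induced tumors in long-term rat bioassays (label 1, "carcinogen")
or it did not (label 0). Mechanisms are heterogeneous — genotoxic
compounds damage DNA directly, others act through receptor-mediated or
metabolic routes — so no single molecular descriptor separates the
classes. What does carry signal is two-dimensional substructure: motifs
such as N-nitroso, azo, nitro-aromatic or certain alkylating groups recur
among carcinogens, which is why expert systems built from structural
alerts reach roughly 70% accuracy on this endpoint.

CarcinoEnsemble models the endpoint from exactly that information.
Molecules enter as SMILES, are curated, and are encoded as twelve
fingerprint families — fixed-length bit or count vectors marking the
presence of substructures or hashed atom paths. One base classifier is
trained per family, and the per-family class probabilities are fused by
arithmetic averaging into an ensemble:

\[
  \hat p(x) = \frac{1}{|M|}\sum_{m \in M} \hat p_m(x), \qquad
  \text{carcinogen} \iff \hat p(x) \ge 0.5 .
\]

Three ensembles are built in parallel — radial-kernel SVM, random
forest, and gradient-boosted trees — and their agreement is used for
consensus screening of compound libraries.

The decision rule is *inclusive* at 0.5 (a mean probability of exactly
0.5 is called positive). For this endpoint a false negative (a missed
carcinogen) is the costlier error, so the boundary case goes to the
positive class.

## Compound curation

Four rules are applied in a fixed order after salt stripping, and the
first rule that fires is recorded as the exclusion reason:

1. fewer than three carbon atoms;
2. any element outside H, B, C, N, O, F, Si, P, S, Cl, Br, I (the
   "heavy metal" rule — the allowed set is the organic scope of rodent
   bioassay modeling sets);
3. polymers — structurally undetectable from SMILES, so honored only
   through an optional per-row flag column;
4. mixtures — two or more fragments that each carry at least three
   carbons.

Salt stripping retains the fragment with the most heavy atoms, breaking
ties by molecular weight and then by lexicographically smallest canonical
SMILES. These tie rules are this package's own deterministic choices; the
upstream tooling that inspired the workflow does not document its rules.
A corollary of the fixed rule order: a salt whose retained fragment is
inorganic (e.g. `[Na+].[Cl-]`) is excluded as `too_few_carbons`, not
`heavy_metal`, because rule 1 fires first.

Canonicalization, and therefore structural identity for deduplication, is
OpenBabel canonical SMILES of the salt-stripped structure (a single
dependency surface; InChIKey would be a second one).

## Fingerprint families

The twelve families and their sizes:

```{r}
fingerprintFamilies()
```

The family sizes and the split into hashed, structural-key and key-count
kinds follow the established fingerprint sets of the same names. Bit-level
compatibility with the historical Java implementations is *not* a goal
and is not claimed: what matters for the method is that each family has
its declared length and documented, deterministic semantics. The
structural-key dictionaries are assembled from a grammar of key types:

* **fg** — a curated list of 45 functional-group patterns, each with its
  exact SMARTS (N-N, N=O, N-nitroso, nitro, azo, carboxylic acid, ester,
  amide, amines, sulfone, epoxide, aryl halide, ...). These are the
  interpretable hooks for importance mining; an independent SMARTS
  matcher (OpenBabel) is used in the test suite to verify every such bit.
* **bond** — element-pair bond patterns (single, double, triple,
  aromatic) over the organic elements, e.g. `[#6]=[#8]`.
* **elem** — element-count keys (`>= m` atoms of an element); threshold
  keys (`m > 1`) appear only in bit-only families.
* **ring** — ring-count keys by size, aromaticity and heteroatom
  content, over the perceived ring set.
* **pair** — atom-class pairs at a fixed topological (shortest-path)
  distance of 1-10 bonds, over a 12-class scheme (AP2D-sized families)
  or a 30-class scheme (the Klekota-Roth-sized 4860-key family). These
  keys are not expressible as plain SMARTS (SMARTS paths cannot pin the
  *shortest* distance), so their `smarts` field is `NA`.
* **estate** — 79 atom-type signatures in the Kier-Hall style
  (element, implicit H count, and counts of single/double/triple/aromatic
  bonds), e.g. `sCH3`, `aaCH`, `ddsN`.

Count families (FP4C, KRC, AP2DC) share their parent's dictionary and
report match counts; because those dictionaries use only match-count key
types, the parent bit always equals `count > 0` — an invariant the test
suite checks molecule by molecule.

The hashed trio enumerates simple linear paths of up to 8 atoms. Each
path string (atom tokens joined by bond-order symbols) is canonicalized
as the lexicographic minimum of its two reading directions and hashed by
`h = (h * 31 + byte) mod 1048573`, `bit = h mod 1024`. `CDK` uses element
symbols and bond orders; `CDKExt` adds ring-membership and formal-charge
tokens to the atoms; `CDKGraph` ignores bond orders. Because paths are
enumerated on the molecular graph, any SMILES spelling of the same
structure yields identical bits.

**Aromaticity and hydrogens.** One perception model is frozen for all
matching: aromaticity is taken from ChemmineR ring perception on the
OpenBabel-derived structure (an atom is aromatic iff it lies in an
aromatic ring), and implicit hydrogens are assigned from standard
valences (B 3; C 4; N 3; O 2; halogens 1; Si 4; P 3/5; S 2/4/6) with
formal-charge adjustment for N, O, S, P. SMARTS semantics in curated keys
were chosen to agree with OpenBabel's matcher under this model — e.g.
`[OX2H0]` is aliphatic-only, so the ether key excludes furan oxygens.

## Feature selection

Two steps, in order:

1. **Zero-variance removal** — any column with a single unique value.
2. **Correlation filter** — repeatedly find the pair with the largest
   |Pearson r| above the cutoff (default 0.7) and drop the member with
   the larger mean absolute correlation to all remaining columns. Ties in
   the pair search are resolved in column-major order; ties in the mean
   drop the later column. This is the classic greedy collinearity
   pruning, pinned down so the kept set is a deterministic function of
   the input column order. The removal partner of every dropped column is
   recorded, so a dropped key can always be traced to the kept column
   that represents it (`selectionRepresentatives()`) — essential when
   reading importance tables, because planted or chemically meaningful
   bits are often perfectly collinear with a partner key and only one
   survivor carries their shared importance.

Scope is configurable. The default, `scope = "fold"`, recomputes the
selection on the training rows of every cross-validation fold: selection
is part of the model-building pipeline, and running it on the full data
before cross-validation leaks test-fold information. `scope = "global"`
reproduces the historical protocol (select once on the whole training
set) and is what the packaged acceptance runs use, both for fidelity to
that protocol and because it prices selection once per family rather than
once per fold.

## Base classifiers and tuning

* **Random forest** (`ranger`): `ntree = 500`, `mtry = floor(sqrt(p))` —
  the standard forest defaults; probabilities are per-class vote
  fractions. Impurity importance is the mean decrease in Gini.
* **SVM-RBF** (`e1071`): Platt-calibrated probability output. By default
  `C = 1`, `gamma = 1/p` (fixed, documented). With `tune = TRUE`, C and
  gamma are drawn log-uniformly from \([2^{-5}, 2^{15}]\) and
  \([2^{-15}, 2^{3}]\) (30 draws) and selected by 5-fold inner
  cross-validated accuracy *on the training rows only*.
* **XGBoost**: logistic output; defaults `eta = 0.1`, `max_depth = 6`,
  `min_child_weight = 1`, `nrounds = 100`. With `tune = TRUE` the grid
  eta {0.05, 0.1, 0.3} x max_depth {3, 6, 9} x min_child_weight {1, 5} x
  nrounds {100, 300} is searched by inner CV.

Tuning is off by default: the search spaces are this package's declared
choices (the named tuned parameters are standard, their ranges are not
published anywhere authoritative for this workflow), and on
fingerprint-bit inputs the fixed settings are competitive while keeping a
500-fold repeated CV affordable. Every fit and every tuning draw derives
its seed from the run seed through `deriveSeed()`, a Lehmer-style mix of
the seed with a stage tag — so fold assignment, fixture generation and
each member fit use disjoint, individually reproducible streams, and no
stage perturbs another's results when configurations change.

## Evaluation protocol

Repeated stratified five-fold cross-validation: per repeat the data are
split into five folds (stratified by class; a non-stratified mode gives
the literal "randomly divided" protocol), an ensemble is trained on four
folds and scored on the fifth, and per-fold confusion counts are kept.
With `k = 5` and `repeats = 100` that is 500 metric records; summaries
report mean and SD. Metrics:

\[
Q = 100\,\frac{TP+TN}{TP+TN+FP+FN},\quad
SE = 100\,\frac{TP}{TP+FN},\quad
SP = 100\,\frac{TN}{TN+FP},
\]

and AUC as the Mann-Whitney rank statistic (tied probabilities count
one half), verified in the tests against exhaustive \(O(n^2)\) pair
counting and against an independent implementation. In the per-fold
records AUC is a fraction in \([0,1]\); summary tables multiply it by 100
so all four metrics share the percent scale of the field's reporting
convention. Cross-validation tables report mean ± SD; learning curves
report mean ± standard error, matching how each is conventionally
plotted. A training fold that lost a class (possible only in tiny or
heavily imbalanced data) is rejected and the repeat's folds are
resampled, with a message.

Learning curves subsample the training set without replacement at each
size (plain random draws), run one five-fold CV per draw and optionally
score an externally trained ensemble, then aggregate across repeats.

## Substructure importance

`giniImportance()` fits `repeats` independently seeded forests on the
feature-selected matrix of the *full* labeled dataset and averages the
per-key mean decrease in Gini impurity; the SD across reseeds quantifies
forest-to-forest variability. Aggregating over forest reseeds on the full
data (rather than over CV folds) matches the single-model analysis this
workflow descends from; the reseeding scheme is recorded in the output.
Occurrence counts per class (molecules containing the key, not match
counts) accompany each key, and `occurrenceCounts()` provides the same
for arbitrary SMARTS through OpenBabel — an independent route from the
fingerprint engine. Hashed families are refused: a hashed bit has no
single substructure reading.

## Consensus screening

`screenLibrary()` predicts a curated library with all three ensembles and
flags: *consensus* (all three call carcinogen) and *high confidence*. The
high-confidence rule is "all three probabilities strictly above 0.8"
(`strict`, the default, following the stricter published reading); a
`permissive` mode (consensus plus any probability at or above 0.8) is
also shipped because the two readings genuinely coexist in the source
material's own tables. Structural duplicates of the training set are
flagged via canonical-SMILES keys. The count ordering — high-confidence
⊆ consensus ⊆ each per-model positive set — is a structural invariant
checked on every run.

## The synthetic fixture generator

`generateFixture()` builds labeled compound sets in which substructure
motifs are *planted* with known class association: by default 300
compounds, balanced classes, an N-nitrosamine branch present with
probability 0.8 in carcinogens and 0.2 in non-carcinogens, and a
carboxylic-acid branch with the mirrored association — echoing the
field's observation that N-N/N=O motifs concentrate in carcinogens and
carboxylic-acid derivatives in non-carcinogens. Scaffolds are random
alkyl chains (3-8 carbons, optionally a benzene ring), so every generated
structure is organic, connected and at least three carbons — fixtures
exercise the curation rules without fighting them. The manifest records
the planted ground truth, and `fixtureMotifKeys()` maps each motif to the
fingerprint keys that detect it.

What the generator emulates: binary-labeled molecule sets of realistic
size and class balance whose signal lives in substructure bits at a
known, configurable strength. What it does not emulate: the chemical
diversity, scaffold complexity, label noise and class-conditional
property shifts of real bioassay data. Passing the packaged checks
therefore demonstrates that the pipeline recovers planted substructure
signal under controlled conditions — it does not certify any particular
accuracy on real chemistry, where published workflows of this design
reach roughly 70% cross-validated accuracy, not the ~83% seen on the
deliberately cleaner fixtures.

## Numerical choices and degenerate inputs

* Decision threshold: inclusive (`>= 0.5` is positive).
* Correlation-filter ties: column-major pair selection; later column
  dropped on equal means.
* Importance ties: equal mean importance orders by key index.
* Fingerprint ranking (`rankFingerprints`): stable sort, input order
  preserved on ties.
* Unparseable SMILES never vanish: records are kept with
  `exclusion_reason = "unparseable"` so row accounting survives.
* Single-class truth in `computeMetrics`: AUC is `NA` with a warning;
  the confusion-based metrics are still returned.
* A fold whose feature selection keeps zero columns predicts 0.5 (an
  uninformed member) rather than failing the whole run.
* Model bundles record a format version; loading an incompatible
  archive is refused rather than silently misread.

## Problem sizes in the packaged runs

The shipped tests and the acceptance script run on generated fixtures:
300 compounds for the main recovery checks (10-repeat five-fold CV per
ensemble, global selection scope), 40-120 compounds for unit-level
checks, a 100-compound library for screening, and a 50-compound
longer-chain external set (the scaffold grammar is shifted to 9-14
carbon chains so external structures are disjoint from training). The
500-record bookkeeping contract is exercised at full `repeats = 100` on a
50-compound, single-family configuration. These sizes are the package's
own choices for its reference runs; all of them scale with configuration.

## Known limitations

* Fingerprint bits are dictionary-compatible in *semantics and size*,
  not in bit position, with the historical implementations of the same
  names; models and importance tables are therefore portable only within
  this package.
* Polymer detection depends entirely on an input flag.
* Aromaticity and implicit-H perception follow one fixed model;
  exotic tautomers or organometallics outside the curated element set
  are out of scope (the latter are excluded by rule 2).
* No applicability-domain estimation: predictions for compounds far from
  the training chemistry carry no reliability measure.
* The SVM/XGB tuning ranges are declared package defaults, not values
  recovered from any publication.
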