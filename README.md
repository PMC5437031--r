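# CarcinoEnsemble

Ensemble fingerprint models for predicting the carcinogenicity of organic
chemicals from their 2D structure.

## The problem and who this is for

Rodent carcinogenicity is a binary toxicological endpoint that is
expensive and slow to measure (multi-year animal bioassays), yet it must
be assessed early in drug discovery and chemical-safety work. Because
carcinogenic activity tracks recurring substructures (N-nitroso, azo,
nitro-aromatic and related motifs), it can be modeled from molecular
fingerprints — fixed-length bit/count vectors that mark the presence of
substructures or hashed atom paths.

This package is for computational toxicologists and cheminformaticians
who want a self-contained, reproducible R implementation of the
fingerprint-ensemble workflow: compound curation from SMILES, twelve
fingerprint families, fingerprint-specific base classifiers, ensemble
fusion, rigorous repeated cross-validation, substructure-importance
mining, and consensus batch screening of compound libraries.

## The model

For a fingerprint set *M* (by default seven families: the CDK hashed
trio, MACCS, PubChem, and the Klekota-Roth bit and count families), one
base classifier per family is trained — radial-kernel SVM, random forest
(ntree = 500, mtry = ⌊√p⌋), or gradient-boosted trees — after
zero-variance and pairwise-correlation (|r| > 0.7) feature filtering.
The ensemble probability is the arithmetic mean

p̂(x) = (1/|M|) Σₘ p̂ₘ(x),  class = carcinogen ⟺ p̂(x) ≥ 0.5.

Performance is estimated by five-fold cross-validation repeated (by
default) 100 times, reporting

Q = 100·(TP+TN)/(TP+TN+FP+FN), SE = 100·TP/(TP+FN),
SP = 100·TN/(TN+FP),

and AUC as the Mann-Whitney rank statistic. Random-forest mean decrease
in Gini impurity, aggregated over reseeded forests, ranks fingerprint
keys to surface the substructures driving the predictions.

See the vignette (`vignettes/carcinogenicity-ensembles.Rmd`) for the full
account: dictionary grammar of the fingerprint families, aromaticity and
implicit-hydrogen model, tuning spaces, selection-scope (leakage)
options, and the synthetic-fixture design.

## Worked example

```r
library(CarcinoEnsemble)

# a seeded synthetic set with planted substructure-label associations
fx <- generateFixture(fixtureConfig(n_total = 120, seed = 42))
cs <- fx$compounds
cs
#> CompoundSet: 120 records ( 120 curated )
#>   labels:  60 carcinogen / 60 non-carcinogen, 0 unlabeled
#>   provenance: synthetic fixture (seed 42)

# repeated five-fold cross-validation of a two-family XGBoost ensemble
res <- repeatedCV(cs, c("MACCS", "Pubchem"), "xgboost",
                  cv = cvConfig(repeats = 5, seed = 42))
cvSummary(res)
#>   metric     mean        sd
#> 1      Q 86.00000  7.103729
#> 2     SE 89.33333 10.628404
#> 3     SP 82.66667 10.183502
#> 4    AUC 93.43056  5.039629

# which substructures carry the signal?
imp <- giniImportance(cs, "MACCS", repeats = 5, seed = 42)
topFeatures(imp, 3)[, c("key", "description", "mean_decrease_gini",
                        "n_present_positives", "n_present_negatives")]
#>        key       description mean_decrease_gini n_present_positives n_present_negatives
#> 1  MACCS-7   carboxylic acid          15.912646                  11                  53
#> 2  MACCS-3 N-nitroso (N-N=O)          14.291637                  51                  12
#> 3 MACCS-42       oxygen atom           1.360339                  53                  55

occurrenceCounts(cs, "[#7]~[#7]")
#> n_positives_with_match n_negatives_with_match
#>                     51                     12
```

Reading the output: the ensemble reaches a cross-validated accuracy (Q)
of 86% on this fixture, and the importance table recovers exactly the
planted chemistry — the N-nitroso key enriched in the positives (51 of
60 carcinogens vs 12 of 60 non-carcinogens carry an N-N bond) and the
carboxylic-acid key enriched in the negatives. The remaining keys score
an order of magnitude lower.

A command-line interface wrapping the same functions ships at
`inst/exec/carcinoEnsemble.R` (`curate`, `fingerprint`, `crossval`,
`train`, `validate`, `screen`, `importance`, `learning-curve`,
`make-fixture`).

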