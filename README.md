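# solcurate

Curation and weighted model evaluation for multi-source aqueous-solubility
datasets.

Public solubility compilations are stitched together from many sources, and
the same measurement often re-enters a compilation several times under a
different structure text — as a salt form, an ionized species, or a SMILES
with the stereochemistry stripped. When such representation-variant
duplicates straddle a train/test split, cross-validated errors are
optimistically biased; and when records carry curation weights, the weighted
error metric is no longer comparable to a plain RMSE. `solcurate` implements
the full counter-measure pipeline for people who build or audit solubility
(logS) models: structure standardization and InChI-key deduplication, the
cleaning and weighting rules of compilation curation, weighted and unweighted
error metrics kept strictly apart, molecule-aware cross-validation, bootstrap
confidence intervals, paired model comparison, and a nested validation
protocol that is immune to hyperparameter selection. A synthetic multi-source
generator with known ground truth makes every stage testable offline.

## The statistics at the core

For predictions ȳᵢ against measurements yᵢ over n records:

- **RMSE** = √( Σᵢ (ȳᵢ − yᵢ)² / n ) — unweighted, comparable across models
  on the same records.
- **cuRMSE** = √( Σᵢ (wᵢ·(ȳᵢ − yᵢ))² / n ) — the record-weighted variant
  used with curated sets. A molecule measured k times gets weight 1/k per
  record ("inter-dataset curation", so each molecule carries total weight 1),
  and its error contribution is divided by k: two records with error 0.6 and
  weight 0.5 yield cuRMSE 0.3, half the RMSE of the same predictions. The two
  metrics are therefore **never** comparable to each other, only within
  themselves.
- **Challenge score** = 1000000·(2 − RMSE).

Cleaning ("clean" sets): structures are standardized (de-salted to the
largest fragment, optionally neutralized) and indexed by the first,
connectivity-only block of the standard InChI key, so stereoisomers and
protonation states collapse onto one molecule. Records of the same molecule
agreeing within 0.01 log units are deduplicated; records measured outside
temperature 25 ± 5 °C or pH 7 ± 1 are dropped (missing metadata passes);
metal-containing and single-heavy-atom species are removed.

Curation ("curated" sets): each source gets a quality weight in (0, 1];
each set is extended with other sets' records for its molecules, and values
agreeing within d = 0.5 log units (the experimental accuracy of solubility
measurements) are merged into their quality-weighted mean.

Validation: ten-fold cross-validation splits by the connectivity key
(`by_molecule`), with each fold's remainder divided 90/10 into internal
training and early stopping — an 81/9/10 partition overall. The `by_record`
policy splits records independently and exists to *measure* duplicate
leakage, not to report with.

## Worked example

```r
library(solcurate)

# the cuRMSE halving effect: one molecule, two half-weight records
tab <- data.frame(record_id = c("r1", "r2"),
                  y_pred = c(-1.7, -1.7), y_obs = c(-2.3, -2.3),
                  weight = c(0.5, 0.5))
rmse(tab)     # 0.6
curmse(tab)   # 0.3

# full pipeline on a synthetic three-source compilation
run <- run_pipeline(solcurate_config(seed = 1))
run$results[, c("model", "policy", "RMSE", "cuRMSE")]
#>      model      policy  RMSE cuRMSE
#>      ridge by_molecule 0.562 0.0819
#>       mean by_molecule 1.878 0.2887
#>  memorizer by_molecule 1.878 0.2887
#>      ridge   by_record 0.555 0.0817
#>       mean   by_record 1.854 0.2860
#>  memorizer   by_record 0.583 0.0930
```

Reading the table: under the honest `by_molecule` split the memorizer is
exactly as bad as the mean predictor (1.878) — it has never seen any test
molecule. Under `by_record` its error collapses to 0.583, purely because
injected duplicates of test molecules sit in its training folds. That gap is
the leakage the curation pipeline exists to remove. The cuRMSE column is
smaller than the RMSE column throughout — an artifact of the weights, not an
improvement — which is why the two are reported as separate labelled columns
and never mixed. The run directory (`run$dir`) holds per-stage CSVs, the
generation and merge logs (JSON lines), per-source curation reports, and
`report.json` / `summary.txt`.

A thin command-line front end with subcommands
`simulate | clean | curate | split | evaluate | compare | run` is installed
at `inst/cli/solcurate`.

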