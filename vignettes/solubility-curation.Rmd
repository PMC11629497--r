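---
title: "Curating multi-source solubility data and evaluating models without leakage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-source solubility data and evaluating models without leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solcurate)
```

## The problem

Aqueous solubility (logS, log mol/L) compilations are assembled from many
sources that each applied their own structure processing — salt stripping,
neutralization, aromatization, stereo handling. The same physical
measurement therefore recurs under different SMILES strings, and a large
compilation can easily carry a third of its records as such
representation-variant duplicates. Two distinct failure modes follow:

1. **Leakage.** If cross-validation splits *records*, a duplicated molecule
   sits in training and evaluation simultaneously, and any model with
   memorization capacity reports an error it will never achieve on new
   molecules.
2. **Metric confusion.** Curation schemes attach weights to records (to
   down-weight repeated molecules or low-quality sources). An error metric
   that folds those weights in is systematically smaller than the plain
   RMSE of the same predictions, so comparing a weighted value against an
   unweighted one fabricates an improvement.

`solcurate` implements the curation rules, the weighted metric, the
molecule-aware validation protocols, and a synthetic data generator that
reproduces the duplication structure with known ground truth, so every
claim the package makes about bias is demonstrated by its own test suite.

## Standardization and identity keys

`standardize_smiles()` parses each structure with OpenBabel, de-salts by
keeping the fragment with the most heavy atoms (ties go to the
lexicographically smallest canonical SMILES, making the choice
deterministic), optionally neutralizes charges, and emits:

- the **full key**: the standard InChI key of the de-salted structure,
  stereo-aware;
- the **connectivity key**: the key's first 14-character block, which
  encodes molecular formula and connectivity but neither stereochemistry
  nor protonation state.

The connectivity key is the package's notion of "the same molecule": salt
forms, ionized/neutral pairs and stereoisomers all collapse onto it. It
drives deduplication *and* data splitting, so stereo errors in source data
cannot leak a molecule across folds. Neutralization is off by default —
graph-model pipelines commonly skip it because some structures fail
chemistry checks after neutralization — and when it is requested but fails
for a record, the record is kept un-neutralized and flagged rather than
dropped.

Duplicate keys pair the connectivity key with the value rounded to a
precision step (default 0.01 log units, the reporting precision of large
property databases). Rounding uses round-half-to-even; the step is part of
the key's identity.

## Cleaning and weighting rules

`clean_dataset()` applies, in order, with full per-rule accounting
(`input = output + Σ removals` is asserted in the report constructor):

- parse failures out (with the parser diagnostic retained);
- condition filter: temperature outside 25 ± 5 °C or pH outside 7 ± 1
  removes a record; *missing* metadata passes, because most compiled
  records carry none and the field still uses them;
- near-duplicates: within a connectivity group, a record closer than
  0.01 log units to an already-kept record is collapsed onto it (first in
  stable input order survives); comparison is on raw values, rounding is
  only for keys;
- metal-containing and single-heavy-atom species out (no bonds between
  heavy atoms — unusable by graph models), counted separately;
- inter-dataset weights: each record gets weight 1/(records of its
  molecule), so every molecule carries total weight exactly 1.

`curate_across_sets()` implements the cross-set step: records first carry
their source's quality weight (user configuration, never inferred — the
reference weights were assigned manually), each analyzed set is extended
with other sets' records for its molecules, and within a molecule the
records are merged greedily — the highest-weight record (ties by value,
then id) absorbs everything within d = 0.5 log units of it, the merged
value being the weight-weighted mean. d defaults to the estimated
experimental accuracy of solubility measurements. Two details are genuinely
underdetermined in the literature and were fixed here as documented
defaults: the merged record's **weight update** (default: maximum of member
weights, capped at 1 — monotone and bounded; sum-capped-at-1 and mean are
available) and the **transitivity rule** when values chain across d
(greedy seeding by descending weight is deterministic and
order-insensitive, which the tests verify by permuting input rows).

## The weighted metric

The package computes, over n evaluated records,

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i (\bar y_i - y_i)^2},
\qquad
\mathrm{cuRMSE} = \sqrt{\tfrac{1}{n}\sum_i \big(w_i(\bar y_i - y_i)\big)^2}.$$

The defining property of cuRMSE, and the reason it exists, is that a
molecule split over k records of weight 1/k contributes its error divided
by k — "artificially halved" at k = 2: two records with error 0.6 and
weight 0.5 give cuRMSE 0.3 against an RMSE of 0.6. The reference
formulation is typeset ambiguously on this point (a literal reading of the
displayed equation, with the weight outside the square, would give
sqrt(0.18) ≈ 0.424 on its own worked example); this package follows the
worked example and the halving semantics, with the weight inside the
square. The divisor is deliberately n, not Σw — that is precisely what
makes the metric incomparable to RMSE whenever weights are below 1, and the
pipeline therefore always reports the two as separately labelled columns,
never merged, never differenced across metrics.

## Validation protocols

`assign_folds()` maps each unit — connectivity key under `by_molecule`,
record id under `by_record` — to a fold by hashing the unit together with
the seed (32-bit FNV-1a, platform-independent), ranking units by hash, and
dealing ranks round-robin over folds. The assignment is a pure function of
(key, seed): insensitive to input order, reproducible everywhere, and
balanced, so 1000 records in 10 folds split exactly 810/90/100 into
internal training / early stopping / evaluation (the early-stop tenth of
each fold's remainder is drawn with a per-fold derived seed over sorted
record ids). Reusing one assignment across model factories puts all models
on identical splits, which is what licenses paired comparisons.

`compare_models()` runs a paired two-sided t-test on per-record squared
errors — the pairing unit of choice when both models were evaluated on the
same splits; a zero-variance difference (a model compared with itself)
reports p = 1. `bootstrap_ci()` resamples prediction-table rows (B = 1000
by default, percentile interval); resampling is by record, not molecule,
and both the estimate and the interval are deterministic per seed.

`nested_validation()` implements the two-step protocol against overfitting
by hyperparameter selection: build the final model on all data; estimate
its accuracy by re-running the *entire* development procedure — including
whatever tuning it contains — on each of n − 1 subset unions and predicting
the held-out subset. The acceptance suite includes a negative control: a
deliberately leaky builder that selects, among many jittered candidates,
the one with the best error on a small internal slice and then reports that
selected minimum as its accuracy. Averaged over ten seeds its self-report
undershoots the nested estimate — the selection-bias signature the
protocol exists to catch.

## The synthetic generator

`generate_universe()` assembles molecules from ~35 built-in organic
fragments (alkyl/aryl/heterocyclic linkers plus polar and halogen
terminals), 1–4 fragments per molecule, all distinct by connectivity key
and validated by the parser. The synthetic true solubility is a fixed
linear function of five descriptors (heavy atoms, aromatic rings, H-bond
donors, H-bond acceptors, heteroatom fraction) with default coefficients
chosen to land logS in the −8..0 range typical of drug-like sets:
solubility falls with size and aromaticity, rises with polarity.

`generate_sources()` draws per-source records as truth + bias +
N(0, noise_sd), rounded to 0.01 log units. The default noise_sd of 0.5 log
units matches the commonly quoted experimental accuracy of solubility
measurements. A configurable fraction of records are representation
variants of existing records — appended counterions (Na⁺, Cl⁻, K⁺),
deprotonated terminal acids / protonated terminal amines, stereo markers
stripped or added — carrying the *same* value, exactly the duplication
mechanism seen in real compilations; 37% is the documented fraction for the
worst real case and is what the leakage tests use. A variant that fails to
parse, or would not preserve its parent's connectivity key, falls back to a
verbatim copy and is logged as such. A minority of records can be drawn
from a hard-coded metal/single-heavy-atom list to exercise the organic
filter. Every random draw flows from one master seed through stable stage
labels, so identical (specs, seed) reproduce identical tables.

What the generator does *not* emulate: real solubility physics, assay
heterogeneity, tautomer ambiguity, or the size and chemical distribution of
real compilations. Passing tests therefore demonstrate the correctness of
the bookkeeping, weighting, and validation machinery — not the accuracy of
any particular solubility model on laboratory data.

## Numerical and design choices

- Chemistry is delegated wholesale to OpenBabel (`obabel`, batch mode);
  the package contains no SMILES parser of its own. The single exception is
  the aromatic-ring count, derived by scanning ring-closure digits in
  OpenBabel's canonical aromatic SMILES, because no installed backend
  reported fused aromatic systems correctly.
- Ridge regression is solved in closed form on the 5-descriptor design
  (intercept unpenalized, weighted normal equations); its penalty is chosen
  on the early-stopping subset only, and the grid includes 0 so noiseless
  synthetic data is fit exactly. A degenerate design falls back to the
  intercept model. The unpenalized limit is cross-checked against `lm()` in
  the tests.
- Deduplication survivor: first record in stable input order. De-salting
  tie-break: lexicographically smallest canonical fragment. Fold hash
  ranking ties: broken by key. All three exist to make re-runs
  byte-identical.
- Problem sizes in the test suite (universes of 30–150 molecules, sources
  of 100–2000 records, B = 100–1000 bootstrap replicates) were chosen so
  the statistical checks — noise recovery within three standard errors,
  CI shrinkage with n, t-test calibration — have adequate power while the
  whole suite stays desk-scale.

## Known limitations

- OpenBabel's standardization is not a full MolVS replication: no tautomer
  canonicalization, no 3D handling; neutralization covers what
  `--neutralize` covers.
- The heteroatom-fraction descriptor treats all non-carbon heavy atoms
  alike; the baseline models are deliberately simple stand-ins that
  exercise the evaluation machinery, not competitive predictors.
- Cross-set merge weight updates are a documented convention (see above),
  not a reproduction of any specific published implementation, which is
  not publicly specified at that level of detail.
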