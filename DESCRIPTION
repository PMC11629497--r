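Package: solcurate
Title: Curation and Weighted Evaluation of Multi-Source Solubility Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling, standardizing and curating aqueous solubility
    (logS) compilations drawn from several data sources, and for evaluating
    regression models on them without the optimistic bias introduced by
    duplicated records. Structures are standardized (de-salting, optional
    neutralization) and indexed by InChI keys; duplicates are detected with
    connectivity keys combined with property values rounded to 0.01 log units;
    records are weighted so every molecule contributes unit weight, and
    cross-set curation merges measurements that agree within the experimental
    accuracy of 0.5 log units using source-quality weights. Model evaluation
    provides the weighted error metric cuRMSE alongside plain RMSE,
    molecule-aware ten-fold cross-validation with an internal 81/9/10
    train/early-stopping/evaluation split, bootstrap confidence intervals,
    paired model comparisons, and a nested validation protocol that guards
    against overfitting by hyperparameter selection. A synthetic multi-source
    data generator with known ground truth makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (the obabel command-line tool)
Config/testthat/edition: 3
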