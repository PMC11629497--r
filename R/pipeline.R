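# End-to-end orchestration: simulate -> standardize/clean -> curate ->
# split -> evaluate -> compare, as one reproducible run driven by a
# serializable config. Every stage writes its artifacts (CSV tables, JSON
# reports, JSON-lines logs) into the run directory, so each removal and
# merge decision is inspectable afterwards.

#' Build a pipeline run configuration
#'
#' All parameters of a run in one serializable list. A run is reproducible
#' from `(config)` alone: every stage derives its own seed from the master
#' seed by a stable label.
#'
#' @param seed Master integer seed.
#' @param n_molecules Size of the synthetic molecule universe.
#' @param sources List of [source_spec()] objects (or lists of their
#'   fields, as read back from YAML).
#' @param precision Duplicate threshold in log units (default 0.01).
#' @param merge_d Cross-set merge threshold in log units (default 0.5).
#' @param quality_weights Named vector of per-source quality weights in
#'   (0, 1].
#' @param neutralize Neutralize charges during standardization.
#' @param n_folds Outer folds for cross-validation (default 10).
#' @param models Character subset of `c("ridge", "mean", "memorizer")`.
#' @param bootstrap_B Bootstrap replicates for confidence intervals.
#' @param ci_level Confidence level.
#' @return An object of class `sol_config`.
#' @export
solcurate_config <- function(seed = 1L, n_molecules = 60,
                             sources = NULL, precision = 0.01,
                             merge_d = 0.5, quality_weights = NULL,
                             neutralize = FALSE, n_folds = 10,
                             models = c("ridge", "mean", "memorizer"),
                             bootstrap_B = 200, ci_level = 0.95) {
  if (is.null(sources))
    sources <- list(
      source_spec("HIGHQ", 160, noise_sd = 0.3, dup_fraction = 0.1),
      source_spec("MIDQ", 200, noise_sd = 0.5, dup_fraction = 0.25,
                  frac_inorganic = 0.05),
      source_spec("LOWQ", 140, noise_sd = 0.8, bias = 0.2,
                  dup_fraction = 0.15, frac_inorganic = 0.05))
  sources <- lapply(sources, function(s)
    if (inherits(s, "source_spec")) s else do.call(source_spec, s))
  if (is.null(quality_weights)) {
    quality_weights <- c(1, 0.85, 0.4)[seq_along(sources)]
    names(quality_weights) <- vapply(sources, `[[`, "", "name")
  }
  structure(list(seed = as.integer(seed), n_molecules = n_molecules,
                 sources = sources, precision = precision,
                 merge_d = merge_d, quality_weights = quality_weights,
                 neutralize = neutralize, n_folds = n_folds,
                 models = match.arg(models, several.ok = TRUE),
                 bootstrap_B = bootstrap_B, ci_level = ci_level),
            class = "sol_config")
}

#' @export
print.sol_config <- function(x, ...) {
  cat("solcurate run config (seed", x$seed, ")\n")
  for (s in x$sources) print(s)
  cat(sprintf("  precision %.3g, merge d %.3g, %d folds, models: %s\n",
              x$precision, x$merge_d, x$n_folds,
              paste(x$models, collapse = ", ")))
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' @param config A `sol_config`.
#' @param path File path.
#' @return `write_config` the path, invisibly; `read_config` a
#'   `sol_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sol_config"))
  lst <- unclass(config)
  lst$sources <- lapply(lst$sources, unclass)
  lst$quality_weights <- as.list(lst$quality_weights)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$quality_weights <- unlist(lst$quality_weights)
  do.call(solcurate_config, lst)
}

write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the full curation-and-evaluation pipeline
#'
#' Executes, in order: synthetic-data generation, per-source cleaning
#' (standardization, condition filter, deduplication, organic filter,
#' intra-set weighting), cross-set curation, fold assignment under both
#' split policies, cross-validation of every configured model under both
#' policies, metric computation (RMSE and cuRMSE side by side, always as
#' separate labelled columns — the two are not comparable to each other),
#' bootstrap confidence intervals and pairwise model comparisons. All
#' artifacts land in `dir`.
#'
#' @param config A `sol_config` from [solcurate_config()].
#' @param dir Run directory (created; default a fresh temporary
#'   directory).
#' @return An object of class `sol_run`: list with `dir`, `compilation`,
#'   `clean`, `cured`, `duplicate_report`, `results` (data.frame of
#'   model x policy metrics), `comparisons`, `config`.
#' @export
run_pipeline <- function(config = solcurate_config(),
                         dir = tempfile("solcurate_run_")) {
  stopifnot(inherits(config, "sol_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # --- simulate ---
  universe <- generate_universe(config$n_molecules,
                                derive_seed(seed, "universe"))
  truth <- ground_truth(universe)
  comp <- generate_sources(universe, truth, config$sources,
                           derive_seed(seed, "sources"))
  write_compilation(comp, file.path(dir, "simulated"))

  # --- standardize raw sources once; audit duplicates before cleaning ---
  std_raw <- lapply(comp$sources, function(s) {
    std <- standardize_smiles(s$smiles, neutralize = config$neutralize)
    cbind(s, std[, c("canonical", "full_key", "connectivity_key",
                     "n_heavy_atoms", "contains_metal",
                     "is_single_heavy_atom", "hbd", "hba",
                     "n_aromatic_rings", "heteroatom_fraction",
                     "parse_ok")])
  })
  dup_report <- cross_source_duplicate_report(
    lapply(std_raw, function(s) s[s$parse_ok, , drop = FALSE]))
  write_json(list(n_pairs = dup_report$n_pairs,
                  by_source_pair = dup_report$by_source_pair),
             file.path(dir, "cross_source_duplicates.json"))

  # --- clean each source ---
  clean <- list()
  for (nm in names(comp$sources)) {
    cs <- clean_dataset(std_raw[[nm]], precision = config$precision,
                        neutralize = config$neutralize)
    clean[[nm]] <- cs
    utils::write.csv(cs$records[, c("smiles", "logS", "source", "weight",
                                    "temperature", "pH", "record_id")],
                     file.path(dir, paste0("clean_", nm, ".csv")),
                     row.names = FALSE)
    write_json(c(list(input = cs$report$input, output = cs$report$output),
                 cs$report$removed),
               file.path(dir, paste0("clean_report_", nm, ".json")))
  }

  std_sets <- lapply(clean, function(cs) cs$records)

  # --- cross-set curation ---
  cured <- curate_across_sets(std_sets, config$quality_weights,
                              d = config$merge_d)
  for (nm in names(cured$sets))
    utils::write.csv(cured$sets[[nm]],
                     file.path(dir, paste0("cured_", nm, ".csv")),
                     row.names = FALSE)
  if (nrow(cured$merge_log))
    writeLines(vapply(seq_len(nrow(cured$merge_log)), function(i)
      as.character(jsonlite::toJSON(as.list(cured$merge_log[i, ]),
                                    auto_unbox = TRUE)), character(1)),
      file.path(dir, "merge_log.jsonl"))

  # --- pooled analysis set: all cleaned sources, re-weighted jointly ---
  pooled <- do.call(rbind, std_sets)
  pooled$record_id <- paste0(pooled$source, ":", pooled$record_id)
  pooled <- assign_intra_weights(pooled)
  rownames(pooled) <- NULL

  # --- evaluate models under both split policies ---
  factories <- list(ridge = model_ridge(), mean = model_mean(),
                    memorizer = model_memorizer())[config$models]
  results <- list(); tables <- list()
  for (policy in c("by_molecule", "by_record")) {
    folds <- assign_folds(pooled, n_folds = config$n_folds, policy = policy,
                          seed = derive_seed(seed, "folds"))
    for (mname in names(factories)) {
      tab <- cross_validate(pooled, factories[[mname]], folds)
      utils::write.csv(
        tab, file.path(dir, sprintf("predictions_%s_%s.csv", mname, policy)),
        row.names = FALSE)
      ci_r <- bootstrap_ci(tab, "rmse", B = config$bootstrap_B,
                           level = config$ci_level,
                           seed = derive_seed(seed, paste0("boot-", mname,
                                                           policy)))
      ci_c <- bootstrap_ci(tab, "curmse", B = config$bootstrap_B,
                           level = config$ci_level,
                           seed = derive_seed(seed, paste0("bootc-", mname,
                                                           policy)))
      results[[length(results) + 1L]] <- data.frame(
        model = mname, policy = policy,
        RMSE = ci_r$estimate, RMSE_lower = ci_r$lower,
        RMSE_upper = ci_r$upper,
        cuRMSE = ci_c$estimate, cuRMSE_lower = ci_c$lower,
        cuRMSE_upper = ci_c$upper,
        n = nrow(tab), stringsAsFactors = FALSE)
      tables[[paste(mname, policy, sep = "_")]] <- tab
    }
  }
  results <- do.call(rbind, results)

  comparisons <- list()
  if (length(factories) > 1L) {
    nm <- names(factories)
    for (policy in c("by_molecule", "by_record"))
      for (i in seq_len(length(nm) - 1L))
        for (j in seq((i + 1L), length(nm))) {
          cmp <- compare_models(tables[[paste(nm[i], policy, sep = "_")]],
                                tables[[paste(nm[j], policy, sep = "_")]])
          comparisons[[sprintf("%s_vs_%s_%s", nm[i], nm[j], policy)]] <-
            list(a = nm[i], b = nm[j], policy = policy,
                 rmse_a = cmp$metric_a, rmse_b = cmp$metric_b,
                 delta = cmp$delta, p_value = cmp$p_value,
                 significant = cmp$significant, lower = cmp$lower)
        }
  }

  write_json(list(seed = seed, results = results,
                  comparisons = comparisons,
                  duplicate_pairs = dup_report$n_pairs),
             file.path(dir, "report.json"))
  summary_lines <- c(
    "solcurate pipeline report",
    sprintf("seed %d; %d molecules; %d sources", seed, config$n_molecules,
            length(config$sources)),
    "",
    utils::capture.output(print(results, row.names = FALSE)))
  writeLines(summary_lines, file.path(dir, "summary.txt"))

  structure(list(dir = dir, compilation = comp, clean = clean,
                 cured = cured, duplicate_report = dup_report,
                 results = results, comparisons = comparisons,
                 tables = tables, config = config),
            class = "sol_run")
}

#' @export
print.sol_run <- function(x, ...) {
  cat("solcurate pipeline run:", x$dir, "\n\n")
  print(x$results, row.names = FALSE)
  cat(sprintf("\ncross-source duplicate pairs: %d\n",
              x$duplicate_report$n_pairs))
  invisible(x)
}
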