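# Synthetic universe, ground truth, and multi-source record generation.

test_that("generated universes are valid, distinct by connectivity, deterministic", {
  u <- generate_universe(30, seed = 7)
  expect_length(u, 30)
  std <- standardize_smiles(u)
  expect_true(all(std$parse_ok))
  expect_equal(length(unique(std$connectivity_key)), 30L)
  expect_identical(generate_universe(30, seed = 7), u)
  expect_false(identical(generate_universe(30, seed = 8), u))
  one <- generate_universe(1, seed = 0)
  expect_true(standardize_smiles(one)$parse_ok)
})

test_that("true solubility is a deterministic linear map of the descriptors", {
  smis <- c("c1ccccc1", "CCO", "CC(=O)O")
  expect_equal(true_solubility(smis, rep(0, 5)), rep(0, 3))
  # only the heavy-atom coefficient: benzene has 6 heavy atoms
  expect_equal(true_solubility("c1ccccc1", c(-0.1, 0, 0, 0, 0)), -0.6)
  expect_identical(true_solubility(smis), true_solubility(smis))
  expect_error(true_solubility("bad(("), "featurize")
})

test_that("featurize sees through salt forms and counts benzene correctly", {
  f <- featurize("c1ccccc1")
  expect_equal(unname(f[1, c("heavy_atoms", "aromatic_rings")]), c(6, 1))
  expect_equal(featurize("CCN.[Na+]"), featurize("CCN"))
})

test_that("generated sources honour duplication, noise, and rounding contracts", {
  truth <- fix_truth(30, 42)
  u <- fix_universe(30, 42)

  # exact duplicate bookkeeping: round(0.37 * 200) records flagged
  comp <- generate_sources(u, truth,
                           list(source_spec("A", 200, dup_fraction = 0.37)),
                           seed = 5)
  recs <- comp$sources$A
  expect_equal(nrow(recs), 200L)
  expect_equal(sum(nzchar(recs$is_duplicate_of)), round(0.37 * 200))
  # every duplicate copies its parent's value exactly
  dup <- recs[nzchar(recs$is_duplicate_of), ]
  parent_val <- recs$logS[match(dup$is_duplicate_of, recs$record_id)]
  expect_equal(dup$logS, parent_val)

  # degenerate noise: values are the truth rounded to 2 decimals
  comp0 <- generate_sources(u, truth,
                            list(source_spec("Z", 80, noise_sd = 0,
                                             bias = 0)), seed = 9)
  z <- comp0$sources$Z
  true_val <- truth$true_logS[match(z$smiles, truth$smiles)]
  expect_equal(z$logS, round_to_precision(true_val, 0.01))
  expect_true(all(abs(z$logS - true_val) <= 0.005 + 1e-12))

  # determinism: identical (specs, seed) reproduce identical tables
  comp2 <- generate_sources(u, truth,
                            list(source_spec("A", 200, dup_fraction = 0.37)),
                            seed = 5)
  expect_identical(comp2$sources, comp$sources)
  expect_identical(comp2$log, comp$log)
})

test_that("duplicate log pairs agree with standardization as oracle", {
  truth <- fix_truth(30, 42)
  comp <- generate_sources(fix_universe(30, 42), truth,
                           list(source_spec("A", 120, dup_fraction = 0.3)),
                           seed = 13)
  recs <- comp$sources$A
  std <- standardize_smiles(recs$smiles)
  key <- std$connectivity_key
  dup <- which(nzchar(recs$is_duplicate_of))
  parent <- match(recs$is_duplicate_of[dup], recs$record_id)
  # each logged duplicate shares connectivity and value with its parent
  expect_equal(key[dup], key[parent])
  expect_equal(recs$logS[dup], recs$logS[parent])
})

test_that("inorganic records come from the metal/single-atom fixture list", {
  truth <- fix_truth(30, 42)
  comp <- generate_sources(fix_universe(30, 42), truth,
                           list(source_spec("A", 100, frac_inorganic = 0.1)),
                           seed = 3)
  inorg <- comp$log$record_id[comp$log$event == "inorganic"]
  expect_length(inorg, 10L)
  recs <- comp$sources$A
  smi <- recs$smiles[match(inorg, recs$record_id)]
  std <- standardize_smiles(smi)
  expect_true(all(classify_organic(std) != "organic"))
})

test_that("compilations round-trip to CSV plus JSON-lines log", {
  truth <- fix_truth(30, 42)
  comp <- generate_sources(fix_universe(30, 42), truth,
                           list(source_spec("A", 40, dup_fraction = 0.2)),
                           seed = 2)
  dir <- tempfile("comp_")
  paths <- write_compilation(comp, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "source_A.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(back), 40L)
  expect_equal(names(back),
               c("smiles", "logS", "source", "record_id", "is_duplicate_of"))
  log_lines <- readLines(file.path(dir, "generation_log.jsonl"))
  expect_equal(length(log_lines), 40L)
  expect_silent(lapply(log_lines, jsonlite::fromJSON))
})
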