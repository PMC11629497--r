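# Cleaning rules, record weighting, and cross-set curation.

make_records <- function(keys, values, ids = NULL, source = "S") {
  data.frame(record_id = ids %||% sprintf("r%03d", seq_along(keys)),
             connectivity_key = keys, logS = values, source = source,
             temperature = NA_real_, pH = NA_real_,
             contains_metal = FALSE, is_single_heavy_atom = FALSE,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("condition filter keeps the standard window and missing metadata", {
  recs <- make_records(paste0("K", 1:4), rep(-2, 4))
  recs$temperature <- c(25, 37, NA, 28)
  recs$pH <- c(7, 7, NA, 8.5)
  out <- filter_conditions(recs)
  expect_equal(out$records$record_id, c("r001", "r003"))
  expect_equal(out$report$removed$condition_filter, 2)
  expect_equal(out$report$input, out$report$output +
                 sum(unlist(out$report$removed)))
})

test_that("near-duplicates collapse to the first record; spread groups survive", {
  recs <- make_records(c("K1", "K1", "K2", "K2", "K3"),
                       c(-2.344, -2.341, -2.3, -2.9, 0.5))
  out <- deduplicate(recs, precision = 0.01)
  expect_equal(out$records$record_id, c("r001", "r003", "r004", "r005"))
  expect_equal(out$report$removed$exact_duplicate, 1)
  expect_equal(out$removed_ids$survivor_id, "r001")

  # identical-value stereo-pair pattern: one survivor, logged as duplicate
  pair <- make_records(c("KX", "KX"), c(-1.5, -1.5))
  out2 <- deduplicate(pair)
  expect_equal(nrow(out2$records), 1L)
  expect_equal(out2$report$removed$exact_duplicate, 1)
})

test_that("deduplication is idempotent", {
  set.seed(4)
  recs <- make_records(sample(paste0("K", 1:10), 40, replace = TRUE),
                       round(rnorm(40), 2))
  once <- deduplicate(recs)
  twice <- deduplicate(once$records)
  expect_identical(twice$records, once$records)
  expect_equal(twice$report$removed$exact_duplicate, 0)
})

test_that("non-organic removal counts metals and single atoms separately", {
  recs <- make_records(paste0("K", 1:12), rnorm(12))
  recs$contains_metal[1:2] <- TRUE
  recs$is_single_heavy_atom[3] <- TRUE
  out <- remove_nonorganic(recs)
  expect_equal(nrow(out$records), 9L)
  expect_equal(out$report$removed$metal, 2)
  expect_equal(out$report$removed$single_heavy_atom, 1)
})

test_that("intra-set weights give every molecule total weight one", {
  recs <- make_records(c("K1", "K1", "K2", "K3", "K3", "K3", "K3"),
                       rnorm(7))
  w <- assign_intra_weights(recs)
  expect_equal(w$weight, c(0.5, 0.5, 1, 0.25, 0.25, 0.25, 0.25))
  # property: per-molecule weight sums are exactly 1 over random tables
  for (s in 1:10) {
    set.seed(s)
    r <- make_records(sample(paste0("K", 1:20), 60, replace = TRUE),
                      rnorm(60), ids = sprintf("q%03d", 1:60))
    sums <- tapply(assign_intra_weights(r)$weight, r$connectivity_key, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("clean_dataset composes all rules with a closed accounting report", {
  raw <- data.frame(
    smiles = c("CCO", "OCC", "c1ccccc1", "[Mo]", "CC(=O)O.Cl", "CC(=O)O",
               "bad((", "CCN"),
    logS = c(-0.5, -0.5, -2.1, 0, -1.0, -1.0, 0, -0.3),
    temperature = c(NA, NA, NA, NA, NA, NA, NA, 60),
    pH = NA_real_, stringsAsFactors = FALSE)
  cs <- clean_dataset(raw)
  rep <- cs$report
  expect_equal(rep$input, 8)
  expect_equal(rep$removed$parse_failure, 1)     # bad((
  expect_equal(rep$removed$condition_filter, 1)  # CCN at 60 C
  expect_equal(rep$removed$exact_duplicate, 2)   # OCC, desalted acetic acid
  expect_equal(rep$removed$single_heavy_atom, 1) # [Mo]
  expect_equal(rep$input, rep$output + sum(unlist(rep$removed)))
  expect_true(all(abs(tapply(cs$records$weight,
                             cs$records$connectivity_key, sum) - 1) < 1e-12))
})

test_that("cross-set merging takes the quality-weighted mean within d", {
  a <- make_records("K1", -2.0, ids = "a1", source = "A")
  b <- make_records("K1", -2.1, ids = "b1", source = "B")
  cured <- curate_across_sets(list(A = a, B = b),
                              quality = c(A = 1.0, B = 0.85), d = 0.5)
  expect_equal(nrow(cured$sets$A), 1L)
  expect_equal(cured$sets$A$logS, (1.0 * -2.0 + 0.85 * -2.1) / 1.85)
  expect_equal(cured$sets$A$weight, 1.0)      # max rule
  expect_equal(cured$sets$A$n_merged, 2L)
  expect_equal(nrow(cured$merge_log), 2L)     # merged in both analyzed sets

  # values further apart than d stay separate with their dataset weights
  b2 <- make_records("K1", -3.0, ids = "b1", source = "B")
  cured2 <- curate_across_sets(list(A = a, B = b2),
                               quality = c(A = 1.0, B = 0.85), d = 0.5)
  expect_equal(nrow(cured2$sets$A), 2L)
  expect_equal(sort(cured2$sets$A$weight), c(0.85, 1.0))

  # single-set molecules pass through with their quality weight
  c1 <- make_records("K9", 0.3, ids = "c1", source = "A")
  cured3 <- curate_across_sets(list(A = c1, B = b2),
                               quality = c(A = 0.7, B = 0.85))
  expect_equal(cured3$sets$A$weight, 0.7)
})

test_that("alternative weight-update rules behave as documented", {
  a <- make_records("K1", -2.0, ids = "a1", source = "A")
  b <- make_records("K1", -2.1, ids = "b1", source = "B")
  sets <- list(A = a, B = b); q <- c(A = 0.6, B = 0.5)
  expect_equal(curate_across_sets(sets, q, weight_update = "max")$sets$A$weight, 0.6)
  expect_equal(curate_across_sets(sets, q, weight_update = "sum")$sets$A$weight, 1.0)
  expect_equal(curate_across_sets(sets, q, weight_update = "mean")$sets$A$weight, 0.55)
})

test_that("missing quality weights are a configuration error", {
  a <- make_records("K1", -2.0, source = "A")
  expect_error(curate_across_sets(list(A = a), quality = c(B = 1)),
               "missing quality weight")
})

test_that("merging is insensitive to input record order", {
  set.seed(11)
  keys <- sample(paste0("K", 1:8), 30, replace = TRUE)
  recs <- make_records(keys, rnorm(30), ids = sprintf("m%03d", 1:30))
  half <- seq_len(15)
  sets <- list(A = recs[half, ], B = recs[-half, ])
  sets$B$source <- "B"
  q <- c(A = 1.0, B = 0.8)
  cured <- curate_across_sets(sets, q)
  sets2 <- lapply(sets, function(s) s[rev(seq_len(nrow(s))), ])
  cured2 <- curate_across_sets(sets2, q)
  for (nm in names(cured$sets)) {
    o1 <- cured$sets[[nm]][order(cured$sets[[nm]]$record_id), ]
    o2 <- cured2$sets[[nm]][order(cured2$sets[[nm]]$record_id), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2, tolerance = 1e-12)
  }
})

test_that("cross-source duplicate report matches the generator log", {
  truth <- fix_truth(30, 42)
  comp <- generate_sources(fix_universe(30, 42), truth,
                           list(source_spec("A", 60, dup_fraction = 0.25),
                                source_spec("B", 50, dup_fraction = 0.2)),
                           seed = 21)
  sets <- lapply(comp$sources, function(s) {
    std <- standardize_smiles(s$smiles)
    cbind(s, std[, c("connectivity_key", "contains_metal",
                     "is_single_heavy_atom")])
  })
  rep <- cross_source_duplicate_report(sets)
  # every injected duplicate appears among the reported pairs
  injected <- comp$log[comp$log$event %in%
                         c("duplicate", "duplicate_verbatim_fallback"), ]
  pair_ids <- c(paste(rep$pairs$record_a, rep$pairs$record_b),
                paste(rep$pairs$record_b, rep$pairs$record_a))
  found <- paste(injected$record_id, injected$parent_id) %in% pair_ids
  expect_true(all(found))

  # disjoint-molecule sources have zero duplicate pairs
  d1 <- make_records(c("K1", "K2"), c(0, 1), ids = c("x1", "x2"))
  d1$smiles <- c("CCO", "CCN")
  d2 <- make_records(c("K3", "K4"), c(0, 1), ids = c("y1", "y2"))
  d2$smiles <- c("CCC", "CCCC")
  expect_equal(cross_source_duplicate_report(list(A = d1, B = d2))$n_pairs, 0)

  # a stereo-stripped copy is classified as a stereo variant
  s1 <- make_records("KS", -1, ids = "s1"); s1$smiles <- "C[C@H](O)CC"
  s2 <- make_records("KS", -1, ids = "s2"); s2$smiles <- "CC(O)CC"
  cls <- cross_source_duplicate_report(list(A = s1, B = s2))
  expect_equal(cls$pairs$variant, "stereo")
})

test_that("duplicate excess reproduces compilation bookkeeping arithmetic", {
  # deduplicated records minus primary-assay measurements = injected copies
  expect_equal(duplicate_excess(100, 80), 20)
  truth <- fix_truth(30, 42)
  comp <- generate_sources(fix_universe(30, 42), truth,
                           list(source_spec("A", 100, dup_fraction = 0.3)),
                           seed = 8)
  n_originals <- sum(comp$log$event == "original")
  expect_equal(duplicate_excess(nrow(comp$sources$A), n_originals), 30)
})
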