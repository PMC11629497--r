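# Cross-validation, bootstrap intervals, model comparison, nested
# validation.

test_that("cross-validation covers all records once and is deterministic", {
  recs <- fix_linear_records(60, records_per_mol = 2, seed = 20)
  fa <- assign_folds(recs, policy = "by_molecule", seed = 1)
  tab1 <- cross_validate(recs, model_mean(), fa)
  expect_equal(nrow(tab1), nrow(recs))
  expect_false(anyNA(tab1$y_pred))
  tab2 <- cross_validate(recs, model_mean(), fa)
  expect_identical(tab1, tab2)
})

test_that("a mean predictor on constant data cross-validates to zero error", {
  recs <- fix_linear_records(30, seed = 21)
  recs$logS <- -2
  fa <- assign_folds(recs, policy = "by_record", seed = 1)
  expect_equal(rmse(cross_validate(recs, model_mean(), fa)), 0)
})

test_that("duplicated data deflates the memorizer's by-record error", {
  # every record gets one exact duplicate; a memorizer sees most test
  # twins in training under by_record, never under by_molecule
  base <- fix_linear_records(60, noise_sd = 0.5, seed = 22)
  dup <- base
  dup$record_id <- paste0(dup$record_id, "_copy")
  recs <- rbind(base, dup)
  fr <- assign_folds(recs, policy = "by_record", seed = 2)
  fm <- assign_folds(recs, policy = "by_molecule", seed = 2)
  rmse_r <- rmse(cross_validate(recs, model_memorizer(), fr))
  rmse_m <- rmse(cross_validate(recs, model_memorizer(), fm))
  expect_lt(rmse_r, rmse_m)
  # twins in the training part are reproduced exactly
  expect_lt(rmse_r, 0.45 * rmse_m)
})

test_that("bootstrap intervals are seeded, degenerate on constant errors, and shrink with n", {
  tab <- fix_prediction_table(rep(0.5, 50))
  ci <- bootstrap_ci(tab, "rmse", B = 200, seed = 5)
  expect_equal(ci$lower, 0.5)
  expect_equal(ci$upper, 0.5)
  expect_equal(ci$estimate, 0.5)

  set.seed(6)
  tabn <- fix_prediction_table(rnorm(100))
  ci1 <- bootstrap_ci(tabn, "rmse", B = 300, seed = 9)
  ci2 <- bootstrap_ci(tabn, "rmse", B = 300, seed = 9)
  expect_identical(ci1$replicates, ci2$replicates)
  expect_true(ci1$lower <= ci1$estimate && ci1$estimate <= ci1$upper)

  # CI width decreases with dataset size (averaged over seeds)
  widths <- vapply(1:20, function(s) {
    set.seed(s)
    small <- fix_prediction_table(rnorm(400))
    big <- fix_prediction_table(rnorm(4000))
    c(bootstrap_ci(small, B = 200, seed = s)$upper -
        bootstrap_ci(small, B = 200, seed = s)$lower,
      bootstrap_ci(big, B = 200, seed = s)$upper -
        bootstrap_ci(big, B = 200, seed = s)$lower)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
  expect_error(bootstrap_ci(tab, B = 50), "at least 100")
})

test_that("model comparison handles self, dominated, and equivalent models", {
  set.seed(7)
  tab <- data.frame(record_id = sprintf("r%03d", 1:80),
                    y_pred = rnorm(80), y_obs = rnorm(80), weight = 1,
                    fold = rep(0:9, 8), stringsAsFactors = FALSE)
  self <- compare_models(tab, tab)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)
  expect_false(self$significant)

  worse <- tab
  worse$y_pred <- tab$y_pred + 0.5   # shift every prediction by a constant
  cmp <- compare_models(tab, worse)
  expect_true(cmp$significant)
  expect_equal(cmp$lower, "a")

  expect_error(compare_models(tab, tab[1:10, ]), "different record sets")
})

test_that("comparison of two equivalent noise processes rejects at about the nominal rate", {
  reject <- vapply(1:40, function(s) {
    set.seed(100 + s)
    a <- data.frame(record_id = as.character(1:150), y_pred = rnorm(150),
                    y_obs = 0, weight = 1, stringsAsFactors = FALSE)
    b <- a; b$y_pred <- rnorm(150)
    compare_models(a, b)$significant
  }, logical(1))
  expect_lte(mean(reject), 0.2)   # ~0.05 nominal; binomial slack at 40 reps
})

test_that("nested validation with an untuned builder equals plain cross-validation", {
  recs <- fix_linear_records(50, records_per_mol = 2, seed = 23)
  builder <- function(data) {
    fit <- model_mean()$fit(data)
    function(newdata) fit(newdata)
  }
  nest <- nested_validation(recs, builder, n_subsets = 5,
                            policy = "by_record", seed = 11)
  fa <- assign_folds(recs, n_folds = 5, policy = "by_record", seed = 11)
  cv <- cross_validate(recs, model_mean(), fa)
  expect_equal(nest$estimate, rmse(cv), tolerance = 1e-12)
})

test_that("an honest tuner's nested estimate predicts fresh-data error", {
  builder <- function(data) {
    # tunes the ridge penalty by proper internal CV on its own data only
    grid <- c(0, 0.01, 0.1, 1, 10)
    fa <- assign_folds(data, n_folds = 4, policy = "by_record",
                       seed = nrow(data))
    cv_err <- vapply(grid, function(l) {
      rmse(cross_validate(data, model_ridge(lambda_grid = l), fa))
    }, numeric(1))
    best <- grid[which.min(cv_err)]
    fit <- model_ridge(lambda_grid = best)$fit(data, NULL)
    structure(function(newdata) fit(newdata),
              self_estimate = min(cv_err))
  }
  recs <- fix_linear_records(150, noise_sd = 0.4, seed = 24)
  nest <- nested_validation(recs, builder, n_subsets = 5,
                            policy = "by_record", seed = 12)
  fresh <- fix_linear_records(400, noise_sd = 0.4, seed = 25)
  final_pred <- nest$final_model(fresh)
  fresh_err <- sqrt(mean((final_pred - fresh$logS)^2))
  expect_lt(abs(nest$estimate - fresh_err) / fresh_err, 0.15)
})
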