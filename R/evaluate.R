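# Model evaluation: out-of-fold cross-validation predictions, bootstrap
# confidence intervals, paired model comparison, and the two-step nested
# validation protocol that keeps hyperparameter selection honest.

#' Cross-validate a model over a fold assignment
#'
#' For each outer fold, fits the model factory on that fold's internal
#' training and early-stopping subsets and predicts the held-out
#' evaluation records. Concatenated over folds this yields exactly one
#' out-of-fold prediction per record. Reusing one `fold_assignment` across
#' model factories puts every model on identical data splits, which is
#' what makes their results directly comparable.
#'
#' @param records Standardized record data.frame with `record_id`, `logS`
#'   and whatever columns the model needs; an optional `weight` column is
#'   carried into the prediction table (default 1).
#' @param model A model factory (e.g. [model_ridge()]).
#' @param folds A `fold_assignment` from [assign_folds()] on the same
#'   records.
#' @return A prediction table: data.frame `record_id`, `y_pred`, `y_obs`,
#'   `weight`, `fold`, one row per record, ordered like `records`.
#' @export
cross_validate <- function(records, model, folds) {
  stopifnot(inherits(folds, "fold_assignment"))
  require_columns(records, c("record_id", "logS"), "records")
  if (!setequal(records$record_id, names(folds$fold)))
    stop("`folds` was built for a different set of records")
  w <- record_weights(records)
  out <- data.frame(record_id = records$record_id, y_pred = NA_real_,
                    y_obs = records$logS, weight = w,
                    fold = unname(folds$fold[records$record_id]),
                    stringsAsFactors = FALSE)
  for (k in seq_len(folds$n_folds) - 1L) {
    role <- folds$roles[records$record_id, k + 1L]
    evali <- which(role == "eval")
    if (!length(evali)) next
    fitted <- tryCatch(
      model$fit(records[role == "train", , drop = FALSE],
                records[role == "early_stop", , drop = FALSE]),
      error = function(e)
        stop("model '", model$name, "' failed on fold ", k, ": ",
             conditionMessage(e), call. = FALSE))
    out$y_pred[evali] <- fitted(records[evali, , drop = FALSE])
  }
  out
}

resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(match.arg(metric, c("rmse", "curmse")),
         rmse = rmse, curmse = curmse)
}

#' Bootstrap confidence interval for an error metric
#'
#' Resamples the rows of a prediction table with replacement `B` times,
#' recomputes the metric on each replicate, and reports the percentile
#' interval. Deterministic for a fixed seed.
#'
#' @param table Prediction table (see [cross_validate()]).
#' @param metric `"rmse"`, `"curmse"`, or a function of a prediction
#'   table.
#' @param B Number of bootstrap replicates (>= 100; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return An object of class `evaluation_result`: list with `metric`,
#'   `estimate`, `lower`, `upper`, `level`, `n`, `B`, `seed`,
#'   `replicates`.
#' @export
bootstrap_ci <- function(table, metric = "rmse", B = 1000, level = 0.95,
                         seed = 1L) {
  if (B < 100) stop("`B` must be at least 100")
  fn <- resolve_metric(metric)
  est <- fn(table)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    fn(table[sample(nrow(table), replace = TRUE), , drop = FALSE])
  }, numeric(1)))
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(metric = if (is.character(metric)) metric else "custom",
                 estimate = est, lower = qs[1], upper = qs[2],
                 level = level, n = nrow(table), B = B, seed = seed,
                 replicates = reps),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %.*f  [%.*f, %.*f] %d%% bootstrap CI (n = %d, B = %d)\n",
              x$metric, digits, x$estimate, digits, x$lower, digits,
              x$upper, round(100 * x$level), x$n, x$B))
  invisible(x)
}

#' Paired comparison of two models' predictions
#'
#' Compares two prediction tables that cover the same records and folds
#' with a paired two-sided t-test on the per-record squared errors, the
#' natural pairing unit when both models were evaluated on identical data
#' splits.
#'
#' @param table_a,table_b Prediction tables over identical record ids
#'   (and folds, when present).
#' @param metric Metric used for the reported point estimates
#'   (`"rmse"` or `"curmse"`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `model_comparison`: list with `metric_a`,
#'   `metric_b`, `delta` (a minus b), `p_value`, `significant`, `lower`
#'   (`"a"`, `"b"` or `"tie"`), `n`.
#' @export
compare_models <- function(table_a, table_b, metric = "rmse", alpha = 0.05) {
  require_columns(table_a, c("record_id", "y_pred", "y_obs"), "table_a")
  require_columns(table_b, c("record_id", "y_pred", "y_obs"), "table_b")
  if (!setequal(table_a$record_id, table_b$record_id))
    stop("prediction tables cover different record sets")
  b <- table_b[match(table_a$record_id, table_b$record_id), , drop = FALSE]
  if (!is.null(table_a$fold) && !is.null(b$fold) &&
      any(table_a$fold != b$fold))
    stop("prediction tables use different fold partitions")
  fn <- resolve_metric(metric)
  ma <- fn(table_a); mb <- fn(b)
  d <- (table_a$y_pred - table_a$y_obs)^2 - (b$y_pred - b$y_obs)^2
  p <- if (stats::sd(d) == 0 || length(d) < 2L) {
    if (all(d == 0)) 1 else NA_real_
  } else stats::t.test(d)$p.value
  significant <- !is.na(p) && p < alpha
  structure(list(metric = if (is.character(metric)) metric else "custom",
                 metric_a = ma, metric_b = mb, delta = ma - mb,
                 p_value = p, significant = significant,
                 lower = if (ma < mb) "a" else if (mb < ma) "b" else "tie",
                 n = nrow(table_a), alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("paired comparison (%s): a = %.*f, b = %.*f, delta = %+.*f\n",
              x$metric, digits, x$metric_a, digits, x$metric_b, digits,
              x$delta))
  cat(sprintf("  t-test on squared errors: p = %s -> %s\n",
              format(x$p_value, digits = 3),
              if (isTRUE(x$significant))
                sprintf("'%s' significantly lower", x$lower)
              else "not significant"))
  invisible(x)
}

#' Nested validation of a full model-development procedure
#'
#' Implements the two-step protocol that guards against overfitting by
#' hyperparameter selection: the final model is built once from all data;
#' its accuracy is estimated by dividing the data into `n_subsets`,
#' repeating the *entire* development procedure (including any tuning or
#' selection the builder performs internally) on each union of
#' `n_subsets - 1` parts, and predicting the held-out part. The pooled
#' out-of-sample predictions are untouched by any selection step, so the
#' resulting estimate is honest even when the builder tunes aggressively.
#'
#' @param records Standardized record data.frame (`record_id`, `logS`,
#'   plus whatever the builder needs).
#' @param model_builder Function taking a record data.frame and returning
#'   a prediction function `function(newdata) numeric`. It must
#'   encapsulate everything, including hyperparameter selection.
#' @param n_subsets Number of outer subsets (>= 2; default 5).
#' @param policy Fold policy passed to [assign_folds()]
#'   (default `"by_molecule"`).
#' @param seed Integer seed for the subset division.
#' @param metric Metric for the pooled estimate.
#' @return List with `estimate` (pooled out-of-sample metric), `table`
#'   (pooled prediction table), `final_model` (prediction function built
#'   from all data), and `builder_reports` (whatever the builders attached
#'   as attribute `"self_estimate"`, one per subset plus `"final"`).
#' @export
nested_validation <- function(records, model_builder, n_subsets = 5,
                              policy = "by_molecule", seed = 1L,
                              metric = "rmse") {
  if (n_subsets < 2) stop("`n_subsets` must be at least 2")
  folds <- assign_folds(records, n_folds = n_subsets, policy = policy,
                        seed = seed)
  w <- record_weights(records)
  out <- data.frame(record_id = records$record_id, y_pred = NA_real_,
                    y_obs = records$logS, weight = w,
                    fold = unname(folds$fold[records$record_id]),
                    stringsAsFactors = FALSE)
  reports <- list()
  for (k in seq_len(n_subsets) - 1L) {
    holdout <- out$fold == k
    mdl <- model_builder(records[!holdout, , drop = FALSE])
    out$y_pred[holdout] <- mdl(records[holdout, , drop = FALSE])
    reports[[paste0("subset", k)]] <- attr(mdl, "self_estimate")
  }
  final_model <- model_builder(records)
  reports[["final"]] <- attr(final_model, "self_estimate")
  fn <- resolve_metric(metric)
  list(estimate = fn(out), table = out, final_model = final_model,
       builder_reports = reports)
}
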