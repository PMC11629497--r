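# Error metrics. A "prediction table" is a data.frame with one row per
# evaluated record: `y_pred`, `y_obs`, and (for the weighted metric) a
# non-negative `weight`.

#' Root-mean-squared error of a prediction table
#'
#' `sqrt(sum((y_pred - y_obs)^2) / n)`. Record weights are ignored: this
#' is the plain, unweighted error that makes models comparable across
#' datasets.
#'
#' @param table Data.frame with numeric columns `y_pred` and `y_obs`.
#' @return A single number (log units).
#' @export
rmse <- function(table) {
  require_columns(table, c("y_pred", "y_obs"), "table")
  if (nrow(table) == 0L) stop("empty prediction table")
  sqrt(sum((table$y_pred - table$y_obs)^2) / nrow(table))
}

#' Weighted (curated) RMSE of a prediction table
#'
#' `sqrt(sum((w * (y_pred - y_obs))^2) / n)` — the record-weighted error
#' used with curated compilations: each record's residual is scaled by its
#' weight before squaring, so a molecule split over `k` records of weight
#' `1/k` contributes its error divided by `k`. A molecule with two records
#' of weight 0.5 and error 0.6 each yields 0.3, half its RMSE — the
#' "artificial halving" that makes this metric incomparable to plain RMSE.
#' The divisor is the record count `n`, not the weight sum, so with
#' weights below 1 the value is systematically smaller than the RMSE of
#' the same predictions; the two metrics must never be compared to each
#' other.
#'
#' @param table Data.frame with numeric columns `y_pred`, `y_obs` and
#'   non-negative `weight`.
#' @return A single number (log units).
#' @export
curmse <- function(table) {
  require_columns(table, c("y_pred", "y_obs", "weight"), "table")
  if (nrow(table) == 0L) stop("empty prediction table")
  if (any(is.na(table$weight)) || any(table$weight < 0))
    stop("weights must be non-negative")
  sqrt(sum((table$weight * (table$y_pred - table$y_obs))^2) / nrow(table))
}

#' Challenge score of an RMSE value
#'
#' The linear score used by blind prediction challenges:
#' `1000000 * (2 - RMSE)`.
#'
#' @param rmse_value Numeric RMSE value(s).
#' @return Numeric score(s).
#' @examples
#' challenge_score(0.6) # 1400000
#' @export
challenge_score <- function(rmse_value) 1e6 * (2 - rmse_value)
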