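# Cross-validation fold assignment. Folds are a deterministic function of
# (identity key, seed): each unit is hashed together with the seed, units
# are ranked by hash value, and ranks are dealt round-robin over folds.
# This keeps the assignment insensitive to input order, reproducible
# across platforms, and balanced. Under the molecule-aware policy the unit
# is the connectivity key, so stereoisomers and repeated measurements of
# one molecule always land in the same fold.

#' Assign cross-validation folds and inner roles
#'
#' Produces the fold structure of ten-fold cross-validation with an
#' internal split: for each outer fold, the records of that fold form the
#' evaluation set (10%), and the remaining records are divided 90/10 into
#' internal training (81% overall) and early stopping (9% overall) with a
#' seeded draw.
#'
#' The `by_molecule` policy assigns whole molecules (connectivity keys) to
#' folds, so a molecule never straddles training and evaluation; the
#' `by_record` policy assigns records independently and therefore lets
#' duplicated molecules leak across the split — it exists to measure that
#' effect.
#'
#' @param records Data.frame with `record_id` (and `connectivity_key`
#'   under `by_molecule`).
#' @param n_folds Number of outer folds (default 10).
#' @param policy `"by_molecule"` (default) or `"by_record"`.
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `fold` (named
#'   integer vector, fold of each record, 0-based), `roles` (character
#'   matrix records x folds with entries `"train"`, `"early_stop"`,
#'   `"eval"`), `policy`, `n_folds`, `seed`.
#' @export
assign_folds <- function(records, n_folds = 10, policy = c("by_molecule",
                                                           "by_record"),
                         seed = 1L) {
  policy <- match.arg(policy)
  require_columns(records, "record_id", "records")
  if (n_folds < 2) stop("`n_folds` must be at least 2")
  n <- nrow(records)
  if (anyDuplicated(records$record_id)) stop("record ids must be unique")

  if (policy == "by_molecule") {
    require_columns(records, "connectivity_key", "records")
    units <- unique(records$connectivity_key)
    if (length(units) < n_folds)
      stop("fewer distinct molecules (", length(units),
           ") than folds (", n_folds, ")")
    unit_of <- records$connectivity_key
  } else {
    units <- records$record_id
    unit_of <- records$record_id
  }

  h <- fnv1a32(paste0(units, "#", seed))
  rank <- order(h, units)               # ties broken by key for determinism
  unit_fold <- integer(length(units))
  unit_fold[rank] <- (seq_along(units) - 1L) %% n_folds
  names(unit_fold) <- units
  fold <- unname(unit_fold[unit_of])
  names(fold) <- records$record_id

  roles <- matrix(NA_character_, nrow = n, ncol = n_folds,
                  dimnames = list(records$record_id, NULL))
  ord_ids <- sort(records$record_id)    # order-insensitive sampling frame
  for (k in seq_len(n_folds) - 1L) {
    in_eval <- fold == k
    roles[in_eval, k + 1L] <- "eval"
    rest <- ord_ids[!(ord_ids %in% records$record_id[in_eval])]
    n_es <- round(0.1 * length(rest))
    es <- with_seed(derive_seed(seed, paste0("early-stop-", k)),
                    sample(rest, n_es))
    roles[match(es, records$record_id), k + 1L] <- "early_stop"
    roles[is.na(roles[, k + 1L]), k + 1L] <- "train"
  }

  structure(list(fold = fold, roles = roles, policy = policy,
                 n_folds = as.integer(n_folds), seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Fold assignment: %d records, %d folds, policy %s, seed %s\n",
              length(x$fold), x$n_folds, x$policy, format(x$seed)))
  tab <- table(factor(x$fold, levels = 0:(x$n_folds - 1L)))
  cat("  records per fold:", paste(tab, collapse = " "), "\n")
  frac <- colMeans(x$roles == "train")
  cat(sprintf("  mean role fractions: train %.3f / early_stop %.3f / eval %.3f\n",
              mean(x$roles == "train"), mean(x$roles == "early_stop"),
              mean(x$roles == "eval")))
  invisible(x)
}

#' @export
summary.fold_assignment <- function(object, ...) {
  counts <- t(vapply(seq_len(object$n_folds), function(k)
    c(train = sum(object$roles[, k] == "train"),
      early_stop = sum(object$roles[, k] == "early_stop"),
      eval = sum(object$roles[, k] == "eval")), numeric(3)))
  rownames(counts) <- paste0("fold", seq_len(object$n_folds) - 1L)
  counts
}
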