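# Curation of standardized record tables: the cleaning rules that turn a
# raw compilation into a "clean" set (condition filter, duplicate removal,
# metal/single-atom removal, intra-set weighting), and the cross-set
# "curated" procedure (quality weights, extension with other sets'
# records, merging of concordant values).

new_curation_report <- function(input, removed, output) {
  stopifnot(input == output + sum(unlist(removed)))
  structure(list(input = input, removed = removed, output = output),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", x$input, "records in,", x$output, "out\n")
  for (nm in names(x$removed))
    if (x$removed[[nm]] > 0)
      cat(sprintf("  removed %-18s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  invisible(x)
}

#' Remove records measured under non-standard conditions
#'
#' Drops records whose reported temperature or pH lies outside the
#' standard experimental window (temperature 25 +/- 5 degrees C, pH 7 +/- 1
#' by default). Records with missing metadata pass: most compiled records
#' carry no conditions and are still used.
#'
#' @param records Data.frame with columns `temperature` and `pH` (either
#'   may be all-`NA`).
#' @param temperature_center,temperature_tol Window center and half-width
#'   in degrees C.
#' @param pH_center,pH_tol Window center and half-width (unitless).
#' @return List with `records` (kept rows) and `report`
#'   (a `curation_report`).
#' @export
filter_conditions <- function(records, temperature_center = 25,
                              temperature_tol = 5, pH_center = 7,
                              pH_tol = 1) {
  require_columns(records, c("temperature", "pH"), "records")
  bad_t <- !is.na(records$temperature) &
    abs(records$temperature - temperature_center) > temperature_tol
  bad_p <- !is.na(records$pH) & abs(records$pH - pH_center) > pH_tol
  drop <- bad_t | bad_p
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = new_curation_report(nrow(records),
                                    list(condition_filter = sum(drop)),
                                    nrow(out)))
}

#' Remove near-duplicate records
#'
#' Within each connectivity-key group, records whose values differ by less
#' than `precision` from an already-kept record are collapsed onto that
#' record (the survivor is the first in stable input order). Groups whose
#' values spread by more than the precision keep all their distinct
#' members: only agreement closer than the reporting precision counts as a
#' duplicate. Comparison is on raw values; rounding is used only for key
#' construction elsewhere.
#'
#' @param records Standardized data.frame with columns `connectivity_key`
#'   and `logS`.
#' @param precision Duplicate threshold in log units (default 0.01).
#' @return List with `records`, `report`, and `removed_ids` (a data.frame
#'   mapping each removed `record_id` to its `survivor_id` when record ids
#'   are present).
#' @export
deduplicate <- function(records, precision = 0.01) {
  require_columns(records, c("connectivity_key", "logS"), "records")
  n <- nrow(records)
  keep <- rep(TRUE, n)
  removed_of <- character(0); removed_ids <- character(0)
  groups <- split(seq_len(n), records$connectivity_key)
  for (idx in groups) {
    if (length(idx) < 2L) next
    kept_idx <- integer(0)
    for (i in idx) {                       # idx is in stable input order
      if (length(kept_idx)) {
        d <- abs(records$logS[kept_idx] - records$logS[i])
        hit <- which(d < precision)
        if (length(hit)) {
          keep[i] <- FALSE
          if (!is.null(records$record_id)) {
            removed_ids <- c(removed_ids, records$record_id[i])
            removed_of <- c(removed_of, records$record_id[kept_idx[hit[1]]])
          }
          next
        }
      }
      kept_idx <- c(kept_idx, i)
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = new_curation_report(n, list(exact_duplicate = sum(!keep)),
                                    nrow(out)),
       removed_ids = data.frame(record_id = removed_ids,
                                survivor_id = removed_of,
                                stringsAsFactors = FALSE))
}

#' Remove metal-containing and single-heavy-atom records
#'
#' Graph-based models cannot process species without bonds between heavy
#' atoms or with metal atoms; compilation cleaning removes both, counted
#' separately.
#'
#' @param records Standardized data.frame with columns `contains_metal`
#'   and `is_single_heavy_atom`.
#' @return List with `records` and `report`.
#' @export
remove_nonorganic <- function(records) {
  require_columns(records, c("contains_metal", "is_single_heavy_atom"),
                  "records")
  cls <- classify_organic(records)
  out <- records[cls == "organic", , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = new_curation_report(
         nrow(records),
         list(metal = sum(cls == "metal_containing"),
              single_heavy_atom = sum(cls == "single_heavy_atom")),
         nrow(out)))
}

#' Assign inter-dataset record weights
#'
#' Gives each record a weight inversely proportional to the number of
#' records sharing its molecule (connectivity key), so every molecule
#' carries total weight 1 regardless of how often it was measured.
#'
#' @param records Standardized data.frame with column `connectivity_key`.
#' @return The records with a `weight` column (added or overwritten).
#' @examples
#' \dontrun{
#' # a molecule with two records gets weight 1/2 = 0.5 per record
#' }
#' @export
assign_intra_weights <- function(records) {
  require_columns(records, "connectivity_key", "records")
  counts <- table(records$connectivity_key)
  records$weight <- 1 / as.numeric(counts[records$connectivity_key])
  records
}

#' Run the full cleaning pipeline on one raw source table
#'
#' Standardizes the structures, then applies in order: parse-failure
#' removal, the condition filter, near-duplicate removal, the
#' metal/single-heavy-atom filter, and inter-dataset weighting. This is
#' the raw-to-clean transformation for a single set.
#'
#' @param records Data.frame with at least `smiles` and `logS`;
#'   `temperature`/`pH`/`record_id` are honoured when present.
#' @param precision Duplicate threshold in log units.
#' @param neutralize Passed to [standardize_smiles()].
#' @param ... Condition-window arguments for [filter_conditions()].
#' @return An object of class `clean_set`: list with `records` (clean,
#'   standardized, weighted) and `report` (consolidated
#'   `curation_report`).
#' @export
clean_dataset <- function(records, precision = 0.01, neutralize = FALSE, ...) {
  require_columns(records, c("smiles", "logS"), "records")
  if (is.null(records$temperature)) records$temperature <- NA_real_
  if (is.null(records$pH)) records$pH <- NA_real_
  if (is.null(records$record_id))
    records$record_id <- sprintf("R%05d", seq_len(nrow(records)))
  n_in <- nrow(records)

  std_cols <- c("canonical", "full_key", "connectivity_key",
                "n_heavy_atoms", "contains_metal", "is_single_heavy_atom",
                "hbd", "hba", "n_aromatic_rings", "heteroatom_fraction",
                "parse_ok")
  if (all(std_cols %in% names(records))) {
    recs <- records                     # already standardized upstream
  } else {
    std <- standardize_smiles(records$smiles, neutralize = neutralize)
    recs <- cbind(records, std[, std_cols])
  }
  n_parse_fail <- sum(!recs$parse_ok)
  recs <- recs[recs$parse_ok, , drop = FALSE]

  st1 <- filter_conditions(recs, ...)
  st2 <- deduplicate(st1$records, precision = precision)
  st3 <- remove_nonorganic(st2$records)
  out <- assign_intra_weights(st3$records)
  rownames(out) <- NULL

  report <- new_curation_report(
    n_in,
    c(list(parse_failure = n_parse_fail),
      st1$report$removed, st2$report$removed, st3$report$removed),
    nrow(out))
  structure(list(records = out, report = report), class = "clean_set")
}

#' @export
print.clean_set <- function(x, ...) {
  cat("Clean solubility set\n")
  print(x$report)
  cat(sprintf("  mean record weight: %.3f\n", mean(x$records$weight)))
  invisible(x)
}

#' Cross-set curation with source-quality weights
#'
#' Implements the clean-to-curated transformation. Every record first
#' carries the quality weight of its source. Each analyzed set is then
#' extended with the records for its molecules found in the other sets.
#' Within a molecule's cross-set record group, records are merged greedily:
#' the highest-weight record (ties by value, then record id) absorbs every
#' record whose value lies within `d` of it; the merged value is the
#' weight-weighted mean of the absorbed members and the merged weight
#' follows `weight_update`. Records further apart than `d` stay separate
#' with their dataset weights.
#'
#' @param sets Named list of standardized record data.frames (each with
#'   `record_id`, `connectivity_key`, `logS`, `source`).
#' @param quality Named numeric vector or list mapping every source label
#'   to a weight in (0, 1].
#' @param d Merge threshold in log units (default 0.5, the estimated
#'   experimental accuracy of solubility measurements).
#' @param weight_update Rule for the merged record's weight: maximum of
#'   the member weights (default), their sum capped at 1, or their mean.
#' @return An object of class `cured_collection`: list with `sets` (named
#'   list of curated data.frames with columns of the seed record plus
#'   `weight` and `n_merged`) and `merge_log` (data.frame of merge
#'   events).
#' @export
curate_across_sets <- function(sets, quality, d = 0.5,
                               weight_update = c("max", "sum", "mean")) {
  weight_update <- match.arg(weight_update)
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  quality <- unlist(quality)
  missing_q <- setdiff(names(sets), names(quality))
  if (length(missing_q))
    stop("missing quality weight for source(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  if (any(quality[names(sets)] <= 0 | quality[names(sets)] > 1))
    stop("quality weights must lie in (0, 1]")

  for (nm in names(sets))
    require_columns(sets[[nm]], c("record_id", "connectivity_key", "logS"),
                    paste0("sets$", nm))

  all_recs <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    data.frame(record_id = s$record_id, connectivity_key = s$connectivity_key,
               logS = s$logS, source = nm,
               weight = unname(quality[nm]), stringsAsFactors = FALSE)
  }))

  merge_log <- list()
  out_sets <- list()
  for (nm in names(sets)) {
    own_keys <- unique(sets[[nm]]$connectivity_key)
    ext <- all_recs[all_recs$connectivity_key %in% own_keys, , drop = FALSE]
    merged_rows <- list()
    for (key in own_keys) {
      grp <- ext[ext$connectivity_key == key, , drop = FALSE]
      # deterministic greedy order: weight desc, then value, then id
      grp <- grp[order(-grp$weight, grp$logS, grp$record_id), , drop = FALSE]
      while (nrow(grp)) {
        seedr <- grp[1L, ]
        inband <- abs(grp$logS - seedr$logS) < d
        members <- grp[inband, , drop = FALSE]
        value <- sum(members$weight * members$logS) / sum(members$weight)
        weight <- switch(weight_update,
                         max = max(members$weight),
                         sum = min(1, sum(members$weight)),
                         mean = mean(members$weight))
        merged_rows[[length(merged_rows) + 1L]] <- data.frame(
          record_id = seedr$record_id, connectivity_key = key,
          logS = value, source = seedr$source, weight = weight,
          n_merged = nrow(members), stringsAsFactors = FALSE)
        if (nrow(members) > 1L)
          merge_log[[length(merge_log) + 1L]] <- data.frame(
            set = nm, connectivity_key = key,
            seed_id = seedr$record_id,
            member_ids = paste(members$record_id, collapse = ";"),
            merged_value = value, merged_weight = weight,
            stringsAsFactors = FALSE)
        grp <- grp[!inband, , drop = FALSE]
      }
    }
    res <- do.call(rbind, merged_rows)
    rownames(res) <- NULL
    out_sets[[nm]] <- res
  }
  structure(list(sets = out_sets,
                 merge_log = if (length(merge_log))
                   do.call(rbind, merge_log)
                 else data.frame()),
            class = "cured_collection")
}

#' @export
print.cured_collection <- function(x, ...) {
  cat("Curated (cross-set) collection\n")
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %-10s %5d records, mean weight %.3f, %d merged groups\n",
                nm, nrow(s), mean(s$weight), sum(s$n_merged > 1)))
  }
  invisible(x)
}

#' Report duplicates shared between sources
#'
#' Counts, per pair of sources and overall, the record pairs that share a
#' connectivity key and an identical reported value, and classifies each
#' pair's representation variant (stereo, salt, ionization, verbatim, or
#' other) by comparing the pre-standardization structure texts.
#'
#' @param sets Named list of standardized record data.frames (columns
#'   `record_id`, `smiles`, `connectivity_key`, `logS`).
#' @return List with `pairs` (one row per duplicate pair, with sources and
#'   variant class) and `by_source_pair` (pair counts per source
#'   combination).
#' @export
cross_source_duplicate_report <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  all_recs <- do.call(rbind, lapply(names(sets), function(nm) {
    require_columns(sets[[nm]],
                    c("record_id", "smiles", "connectivity_key", "logS"),
                    paste0("sets$", nm))
    cbind(sets[[nm]][, c("record_id", "smiles", "connectivity_key", "logS")],
          source = nm, stringsAsFactors = FALSE)
  }))
  key <- paste0(all_recs$connectivity_key, "@", all_recs$logS)
  groups <- split(seq_len(nrow(all_recs)), key)
  pairs <- list()
  for (idx in groups) {
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      pairs[[length(pairs) + 1L]] <- data.frame(
        record_a = all_recs$record_id[a], record_b = all_recs$record_id[b],
        source_a = all_recs$source[a], source_b = all_recs$source[b],
        connectivity_key = all_recs$connectivity_key[a],
        logS = all_recs$logS[a],
        variant = classify_variant_pair(all_recs$smiles[a],
                                        all_recs$smiles[b]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(record_a = character(0), record_b = character(0),
               source_a = character(0), source_b = character(0),
               connectivity_key = character(0), logS = numeric(0),
               variant = character(0), stringsAsFactors = FALSE)
  by_pair <- if (nrow(pairs))
    as.data.frame(table(paste(pmin(pairs$source_a, pairs$source_b),
                              pmax(pairs$source_a, pairs$source_b),
                              sep = " & ")),
                  stringsAsFactors = FALSE)
  else data.frame(Var1 = character(0), Freq = integer(0))
  names(by_pair) <- c("source_pair", "n_pairs")
  list(pairs = pairs, by_source_pair = by_pair, n_pairs = nrow(pairs))
}

#' Duplicate-excess bookkeeping check
#'
#' When a compilation is built from sources that all re-processed one
#' primary assay, the number of records surviving deduplication minus the
#' number of primary measurements is the count of representation-variant
#' copies that slipped through as "new" data. A quick audit identity for
#' compilation accounting tables.
#'
#' @param n_deduplicated Record count after deduplication.
#' @param n_primary Number of measurements in the originating assay.
#' @return `n_deduplicated - n_primary`, the surviving duplicate count.
#' @export
duplicate_excess <- function(n_deduplicated, n_primary)
  n_deduplicated - n_primary

# Classify how two structure texts of the same molecule differ.
classify_variant_pair <- function(a, b) {
  if (identical(a, b)) return("verbatim")
  strip <- function(s) {
    s <- gsub("[/\\\\]", "", s)
    s <- gsub("[C@@H]", "C", s, fixed = TRUE)
    s <- gsub("[C@H]", "C", s, fixed = TRUE)
    gsub("@", "", s, fixed = TRUE)
  }
  nfrag <- function(s) length(strsplit(s, ".", fixed = TRUE)[[1]])
  decharge <- function(s) {
    s <- gsub("[O-]", "O", s, fixed = TRUE)
    s <- gsub("[NH3+]", "N", s, fixed = TRUE)
    s <- gsub("[NH+]", "N", s, fixed = TRUE)
    s
  }
  if (identical(strip(a), strip(b))) "stereo"
  else if (nfrag(a) != nfrag(b)) "salt"
  else if (identical(decharge(a), decharge(b))) "ionization"
  else "other"
}
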