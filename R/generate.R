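#' Describe one synthetic data source
#'
#' A source emulates one solubility compilation: records are drawn from the
#' molecule universe with replacement (so molecules recur between sources),
#' values are the true logS plus a source bias and Gaussian noise, rounded
#' to the reporting precision. A fraction of the records are
#' representation-variant copies of an existing record (same value,
#' different structure text: appended counterion, toggled protonation,
#' stereo markers stripped or added), and a minority are metal/inorganic or
#' single-heavy-atom species.
#'
#' @param name Source label.
#' @param n_records Number of records the source contributes.
#' @param noise_sd Standard deviation of the measurement noise in log
#'   units. Default 0.5, the typical experimental accuracy of solubility
#'   measurements.
#' @param bias Additive offset in log units (systematic source error).
#' @param dup_fraction Fraction in `[0, 1)` of records that are
#'   representation-variant duplicates of another record in any source.
#' @param variant_kinds Which variant classes the duplicates may use;
#'   subset of `"salt"`, `"ionize"`, `"stereo_strip"`, `"stereo_add"`.
#' @param value_precision Rounding step of reported values (default 0.01
#'   log units).
#' @param frac_inorganic Fraction of records drawn from a built-in
#'   metal/single-heavy-atom list.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(name, n_records, noise_sd = 0.5, bias = 0,
                        dup_fraction = 0,
                        variant_kinds = c("salt", "ionize", "stereo_strip",
                                          "stereo_add"),
                        value_precision = 0.01, frac_inorganic = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n_records >= 1, noise_sd >= 0, value_precision > 0,
            dup_fraction >= 0, dup_fraction < 1,
            frac_inorganic >= 0, frac_inorganic < 1,
            dup_fraction + frac_inorganic < 1)
  variant_kinds <- match.arg(variant_kinds, several.ok = TRUE)
  structure(list(name = name, n_records = as.integer(n_records),
                 noise_sd = noise_sd, bias = bias,
                 dup_fraction = dup_fraction, variant_kinds = variant_kinds,
                 value_precision = value_precision,
                 frac_inorganic = frac_inorganic),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf(
    "Source '%s': %d records, noise sd %.3g, bias %.3g, %.0f%% duplicates, %.0f%% inorganic\n",
    x$name, x$n_records, x$noise_sd, x$bias, 100 * x$dup_fraction,
    100 * x$frac_inorganic))
  invisible(x)
}

# Representation variants. Each returns a modified SMILES or NA when the
# molecule has no handle for that variant; callers fall back to a verbatim
# copy (logged) when the variant is NA or fails to parse.
make_variant <- function(smiles, kind, counterion) {
  switch(kind,
    salt = paste0(smiles, ".", counterion),
    ionize = {
      if (endsWith(smiles, "C(=O)O"))   # deprotonate the terminal acid
        paste0(substr(smiles, 1L, nchar(smiles) - 6L), "C(=O)[O-]")
      else if (grepl("[A-Za-z0-9)]N$", smiles))  # terminal single-bonded amine
        sub("N$", "[NH3+]", smiles)
      else NA_character_
    },
    stereo_strip = {
      out <- gsub("[/\\\\]", "", smiles)
      out <- gsub("[C@@H]", "C", out, fixed = TRUE)
      out <- gsub("[C@H]", "C", out, fixed = TRUE)
      out <- gsub("@", "", out, fixed = TRUE)
      if (identical(out, smiles)) NA_character_ else out
    },
    stereo_add = {
      # only a carbon with a predecessor, a single-bonded branch and a
      # successor (three heavy neighbours, one implicit H) can safely be
      # rewritten as [C@@H] without changing the molecular formula
      m <- regexpr("[A-Za-z0-9)]C\\([A-Z][^)=]*\\)[A-Za-z0-9[]", smiles)
      if (m == -1L) NA_character_
      else paste0(substr(smiles, 1L, m), "[C@@H]",
                  substr(smiles, m + 2L, nchar(smiles)))
    },
    NA_character_)
}

#' Generate multi-source solubility record tables
#'
#' Draws records for each source specification against a shared molecule
#' universe with known ground truth, injecting representation-variant
#' duplicates and inorganic species as specified, and keeps a generation
#' log recording which records duplicate which. Deterministic for fixed
#' `(specs, seed)`.
#'
#' @param universe Character vector of SMILES from [generate_universe()].
#' @param truth Ground-truth table from [ground_truth()].
#' @param specs Non-empty list of [source_spec()] objects.
#' @param seed Integer seed.
#' @return An object of class `sol_compilation`: a list with
#'   * `sources`: named list of record data.frames with columns
#'     `record_id`, `smiles`, `logS`, `source`, `temperature`, `pH`,
#'     `is_duplicate_of` (empty string for originals);
#'   * `log`: data.frame of generation events (`record_id`, `event`,
#'     `parent_id`, `variant_kind`);
#'   * `truth`: the ground-truth table.
#' @export
generate_sources <- function(universe, truth, specs, seed) {
  if (!length(specs)) stop("`specs` must be non-empty")
  if (inherits(specs, "source_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "source_spec")))
  counterions <- c("[Na+]", "[Cl-]", "[K+]")

  counts <- lapply(specs, function(sp) {
    n_dup <- round(sp$dup_fraction * sp$n_records)
    n_inorg <- round(sp$frac_inorganic * sp$n_records)
    list(orig = sp$n_records - n_dup - n_inorg, dup = n_dup, inorg = n_inorg)
  })

  # --- originals for every source first, so duplicates can cite any source
  originals <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    n <- counts[[i]]$orig
    originals[[i]] <- with_seed(derive_seed(seed, paste0("orig-", sp$name)), {
      idx <- sample(nrow(truth), n, replace = TRUE)
      value <- truth$true_logS[idx] + sp$bias + stats::rnorm(n, 0, sp$noise_sd)
      data.frame(
        record_id = sprintf("%s-%04d", sp$name, seq_len(n)),
        smiles = truth$smiles[idx],
        logS = round_to_precision(value, sp$value_precision),
        source = sp$name, temperature = NA_real_, pH = NA_real_,
        is_duplicate_of = "", stringsAsFactors = FALSE)
    })
  }
  pool <- do.call(rbind, originals)

  log <- data.frame(record_id = pool$record_id, event = "original",
                    parent_id = "", variant_kind = "", stringsAsFactors = FALSE)

  # --- duplicates and inorganics per source
  sources <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    recs <- originals[[i]]
    n_dup <- counts[[i]]$dup
    if (n_dup > 0L) {
      dup <- with_seed(derive_seed(seed, paste0("dup-", sp$name)), {
        parent <- pool[sample(nrow(pool), n_dup, replace = TRUE), ]
        kind <- sample(sp$variant_kinds, n_dup, replace = TRUE)
        ion <- sample(counterions, n_dup, replace = TRUE)
        list(parent = parent, kind = kind, ion = ion)
      })
      vtext <- mapply(make_variant, dup$parent$smiles, dup$kind, dup$ion,
                      USE.NAMES = FALSE)
      # a variant must still parse and keep its parent's connectivity;
      # otherwise fall back to a verbatim copy
      chk <- standardize_smiles(ifelse(is.na(vtext), "", vtext))
      pstd <- standardize_smiles(dup$parent$smiles)
      mismatch <- is.na(chk$connectivity_key) |
        chk$connectivity_key != pstd$connectivity_key
      fell_back <- is.na(vtext) | !chk$parse_ok | mismatch
      vtext[fell_back] <- dup$parent$smiles[fell_back]
      dup_df <- data.frame(
        record_id = sprintf("%s-D%04d", sp$name, seq_len(n_dup)),
        smiles = vtext,
        logS = dup$parent$logS,
        source = sp$name, temperature = NA_real_, pH = NA_real_,
        is_duplicate_of = dup$parent$record_id, stringsAsFactors = FALSE)
      recs <- rbind(recs, dup_df)
      log <- rbind(log,
        data.frame(record_id = dup_df$record_id,
                   event = ifelse(fell_back, "duplicate_verbatim_fallback",
                                  "duplicate"),
                   parent_id = dup$parent$record_id,
                   variant_kind = ifelse(fell_back, "verbatim", dup$kind),
                   stringsAsFactors = FALSE))
    }
    n_inorg <- counts[[i]]$inorg
    if (n_inorg > 0L) {
      inorg <- with_seed(derive_seed(seed, paste0("inorg-", sp$name)), {
        data.frame(
          record_id = sprintf("%s-I%04d", sp$name, seq_len(n_inorg)),
          smiles = sample(inorganic_species(), n_inorg, replace = TRUE),
          logS = round_to_precision(
            stats::rnorm(n_inorg, sp$bias, max(sp$noise_sd, 1)),
            sp$value_precision),
          source = sp$name, temperature = NA_real_, pH = NA_real_,
          is_duplicate_of = "", stringsAsFactors = FALSE)
      })
      recs <- rbind(recs, inorg)
      log <- rbind(log,
        data.frame(record_id = inorg$record_id, event = "inorganic",
                   parent_id = "", variant_kind = "",
                   stringsAsFactors = FALSE))
    }
    rownames(recs) <- NULL
    sources[[sp$name]] <- recs
  }

  structure(list(sources = sources, log = log, truth = truth),
            class = "sol_compilation")
}

#' @export
print.sol_compilation <- function(x, ...) {
  cat("Synthetic solubility compilation\n")
  for (nm in names(x$sources)) {
    s <- x$sources[[nm]]
    cat(sprintf("  %-10s %5d records (%d duplicates)\n", nm, nrow(s),
                sum(nzchar(s$is_duplicate_of))))
  }
  cat(sprintf("  universe: %d molecules\n", nrow(x$truth)))
  invisible(x)
}

#' Write a compilation to CSV files plus a JSON-lines generation log
#'
#' One CSV per source (columns `smiles`, `logS`, `source`, `record_id`,
#' `is_duplicate_of`) and the generation log as JSON lines.
#'
#' @param compilation A `sol_compilation` from [generate_sources()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_compilation <- function(compilation, dir) {
  stopifnot(inherits(compilation, "sol_compilation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(compilation$sources)) {
    p <- file.path(dir, paste0("source_", nm, ".csv"))
    utils::write.csv(compilation$sources[[nm]][
      , c("smiles", "logS", "source", "record_id", "is_duplicate_of")],
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  logp <- file.path(dir, "generation_log.jsonl")
  writeLines(vapply(seq_len(nrow(compilation$log)), function(i)
    jsonlite::toJSON(as.list(compilation$log[i, ]), auto_unbox = TRUE),
    character(1)), logp)
  invisible(c(paths, logp))
}
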