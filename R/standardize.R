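#' Standardize chemical structures and compute identity keys
#'
#' Normalizes a vector of SMILES the way solubility-compilation curation
#' expects: parse and aromatize, de-salt by keeping the fragment with the
#' most heavy atoms, optionally neutralize charges, and emit the canonical
#' SMILES together with the identifiers used for deduplication and data
#' splitting: the full (stereo-aware) standard InChI key and its first
#' 14-character block, the *connectivity key*, which is identical for
#' stereoisomers and across protonation states.
#'
#' De-salting ties (several fragments with the same, maximal heavy-atom
#' count) are broken by the lexicographically smallest canonical SMILES so
#' the choice is deterministic. Neutralization failures do not discard the
#' record: it is kept un-neutralized and flagged in `neutralize_failed`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param neutralize Logical; neutralize charges after de-salting
#'   (default `FALSE`: graph-model pipelines typically skip it).
#' @param metal_elements Character vector of element symbols treated as
#'   metal/inorganic. Defaults to every element outside the common organic
#'   set (H, B, C, N, O, Si, P, S, Se, halogens, noble gases).
#' @return A data.frame with one row per input: `input`, `canonical`,
#'   `full_key`, `connectivity_key`, `n_heavy_atoms`,
#'   `n_fragments_before_desalt`, `contains_metal`, `is_single_heavy_atom`,
#'   `hbd`, `hba`, `n_aromatic_rings`, `heteroatom_fraction`, `parse_ok`,
#'   `parse_error`, `neutralize_failed`.
#' @examples
#' \dontrun{
#' standardize_smiles(c("CCO", "C(C(=O)O)N.Cl"))
#' }
#' @seealso [standardize_structure()] for a single structure,
#'   [classify_organic()], [duplicate_key()]
#' @export
standardize_smiles <- function(smiles, neutralize = FALSE,
                               metal_elements = NULL) {
  n <- length(smiles)
  res <- data.frame(
    input = as.character(smiles),
    canonical = NA_character_, full_key = NA_character_,
    connectivity_key = NA_character_, n_heavy_atoms = NA_integer_,
    n_fragments_before_desalt = NA_integer_, contains_metal = NA,
    is_single_heavy_atom = NA, hbd = NA_integer_, hba = NA_integer_,
    n_aromatic_rings = NA_integer_, heteroatom_fraction = NA_real_,
    parse_ok = FALSE, parse_error = NA_character_, neutralize_failed = FALSE,
    stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  # --- de-salt: analyze every fragment, keep the largest ---
  frags <- strsplit(ifelse(is.na(smiles), "", smiles), ".", fixed = TRUE)
  nfrag <- lengths(frags)
  res$n_fragments_before_desalt <- ifelse(nfrag == 0L, NA_integer_, nfrag)
  flat <- unlist(frags, use.names = FALSE)
  owner <- rep(seq_len(n), nfrag)
  fa <- ob_batch(flat, fields = c("formula"))
  fheavy <- vapply(fa$formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    cnt <- parse_formula(f)
    as.integer(sum(cnt[setdiff(names(cnt), "H")]))
  }, integer(1), USE.NAMES = FALSE)

  kept <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    idx <- which(owner == i)
    if (!length(idx)) { res$parse_error[i] <- "empty structure text"; next }
    if (anyNA(fa$canonical[idx])) {
      res$parse_error[i] <- "OpenBabel could not parse the structure"
      next
    }
    hm <- fheavy[idx]
    cand <- idx[hm == max(hm)]
    if (length(cand) > 1L) {
      cano <- fa$canonical[cand]
      cand <- cand[order(cano)][1L]
    }
    kept[i] <- flat[cand]
  }

  # --- final pass on the de-salted fragment ---
  todo <- which(!is.na(kept))
  if (length(todo)) {
    fields <- c("InChIKey", "formula", "atoms", "HBA1", "HBD")
    fin <- ob_batch(kept[todo], fields = fields, neutralize = neutralize)
    if (neutralize && anyNA(fin$canonical)) {
      # keep records whose neutralization failed, un-neutralized but flagged
      bad <- which(is.na(fin$canonical))
      redo <- ob_batch(kept[todo][bad], fields = fields, neutralize = FALSE)
      fin[bad, ] <- redo
      res$neutralize_failed[todo[bad]] <- !is.na(redo$canonical)
    }
    ok <- !is.na(fin$canonical) & !is.na(fin$InChIKey)
    rows <- todo[ok]
    res$canonical[rows] <- fin$canonical[ok]
    res$full_key[rows] <- fin$InChIKey[ok]
    res$connectivity_key[rows] <- substr(fin$InChIKey[ok], 1L, 14L)
    counts <- lapply(fin$formula[ok], parse_formula)
    heavy <- vapply(counts, function(cnt)
      as.integer(sum(cnt[setdiff(names(cnt), "H")])), integer(1))
    carbon <- vapply(counts, function(cnt)
      as.integer(sum(cnt[names(cnt) == "C"])), integer(1))
    res$n_heavy_atoms[rows] <- heavy
    res$contains_metal[rows] <- vapply(counts, function(cnt) {
      els <- names(cnt)
      if (is.null(metal_elements)) any(!(els %in% organic_elements()))
      else any(els %in% metal_elements)
    }, logical(1))
    res$is_single_heavy_atom[rows] <- heavy <= 1L
    res$hbd[rows] <- as.integer(fin$HBD[ok])
    res$hba[rows] <- as.integer(fin$HBA1[ok])
    res$n_aromatic_rings[rows] <- count_aromatic_rings(fin$canonical[ok])
    res$heteroatom_fraction[rows] <-
      ifelse(heavy > 0L, (heavy - carbon) / heavy, 0)
    res$parse_ok[rows] <- TRUE
    failed <- todo[!ok]
    res$parse_error[failed] <- "OpenBabel could not process the structure"
  }
  res
}

#' Standardize one structure
#'
#' Single-structure wrapper around [standardize_smiles()] that errors on an
#' unparseable input (carrying the parser diagnostic) and returns a classed
#' object.
#'
#' @inheritParams standardize_smiles
#' @param smiles A single SMILES string.
#' @return An object of class `std_mol`: a one-row list with the fields
#'   documented in [standardize_smiles()].
#' @export
standardize_structure <- function(smiles, neutralize = FALSE,
                                  metal_elements = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  df <- standardize_smiles(smiles, neutralize = neutralize,
                           metal_elements = metal_elements)
  if (!df$parse_ok)
    stop("cannot standardize ", sQuote(smiles), ": ", df$parse_error,
         call. = FALSE)
  structure(as.list(df[1L, ]), class = "std_mol")
}

#' @export
print.std_mol <- function(x, ...) {
  cat("Standardized molecule\n")
  cat("  input:            ", x$input, "\n")
  cat("  canonical:        ", x$canonical, "\n")
  cat("  full key:         ", x$full_key, "\n")
  cat("  connectivity key: ", x$connectivity_key, "\n")
  cat(sprintf("  heavy atoms: %d   fragments before de-salt: %d\n",
              x$n_heavy_atoms, x$n_fragments_before_desalt))
  cat(sprintf("  class: %s\n", classify_organic(x)))
  invisible(x)
}

#' Classify a standardized structure for the organic filter
#'
#' Compilation cleaning removes records that graph-based models cannot
#' process: species containing metal elements and species with at most one
#' heavy atom (no bonds between heavy atoms).
#'
#' @param mol A `std_mol` object from [standardize_structure()] or a
#'   data.frame row from [standardize_smiles()].
#' @return One of `"organic"`, `"metal_containing"`, `"single_heavy_atom"`
#'   (vectorized when given a multi-row data.frame).
#' @examples
#' \dontrun{
#' classify_organic(standardize_structure("[Mo]"))   # single_heavy_atom
#' classify_organic(standardize_structure("CCO"))    # organic
#' }
#' @export
classify_organic <- function(mol) {
  metal <- mol$contains_metal
  single <- mol$is_single_heavy_atom
  ifelse(single %in% TRUE, "single_heavy_atom",
         ifelse(metal %in% TRUE, "metal_containing", "organic"))
}

#' Duplicate key: connectivity key plus rounded value
#'
#' Duplicate detection indexes records by molecule connectivity together
#' with the property value rounded to a fixed precision (0.01 log units by
#' default), the convention used by large property databases. The precision
#' is part of the key's identity.
#'
#' @param mol A `std_mol` object, a standardized data.frame, or a character
#'   vector of connectivity keys.
#' @param value Numeric logS value(s).
#' @param precision Positive rounding step (default 0.01 log units).
#' @return Character vector of keys `"<connectivity>@<rounded value>"`.
#' @examples
#' duplicate_key("ABCDEFGHIJKLMN", -2.344)  # "ABCDEFGHIJKLMN@-2.34"
#' @export
duplicate_key <- function(mol, value, precision = 0.01) {
  key <- if (is.character(mol)) mol else mol$connectivity_key
  rounded <- round_to_precision(value, precision)
  digits <- max(0L, as.integer(ceiling(-log10(precision))))
  paste0(key, "@", formatC(rounded, format = "f", digits = digits))
}
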