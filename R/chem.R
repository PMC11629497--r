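# OpenBabel backend. All chemistry (parsing, canonicalization, InChI keys,
# descriptor calculation, neutralization) is delegated to the `obabel`
# command-line tool in batch mode; this file is the only place that talks
# to it. Molecules travel with synthetic titles so that records skipped by
# the parser can be identified and reported rather than silently dropped.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("The `obabel` executable (OpenBabel) was not found on the PATH; ",
         "it is required for structure standardization.", call. = FALSE)
  p
}

# Run one batch of SMILES through obabel. Returns a data.frame aligned with
# the input: parse failures come back as NA rows. `fields` are obabel
# descriptor names appended after the title (must not produce spaces).
ob_batch <- function(smiles, fields = c("InChIKey", "formula", "atoms"),
                     neutralize = FALSE) {
  n <- length(smiles)
  out <- data.frame(canonical = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (f in fields) out[[f]] <- rep(NA_character_, n)
  if (n == 0L) return(out)

  ok_in <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  if (!any(ok_in)) return(out)

  ids <- paste0("SC", seq_len(n))
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles[ok_in], ids[ok_in]), fin)

  args <- c("-ismi", fin, "-ocan", "-O", fout,
            "--append", paste(fields, collapse = " "))
  if (neutralize) args <- c(args, "--neutralize")
  suppressWarnings(
    system2(obabel_path(), args, stdout = FALSE, stderr = FALSE)
  )
  if (!file.exists(fout)) return(out)

  lines <- readLines(fout, warn = FALSE)
  lines <- lines[nzchar(lines)]
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    rest <- strsplit(trimws(parts[2]), " +")[[1]]
    idx <- match(rest[1], ids)
    if (is.na(idx) || length(rest) != length(fields) + 1L) next
    out$canonical[idx] <- trimws(parts[1])
    for (j in seq_along(fields)) out[[fields[j]]][idx] <- rest[j + 1L]
  }

  # OpenBabel's SMILES reader swallows the line after a parse error, so a
  # bad record can take its innocent neighbour down with it: retry every
  # unresolved input on its own before declaring it unparseable.
  missing <- which(ok_in & is.na(out$canonical))
  if (length(missing) && n > 1L) {
    for (i in missing)
      out[i, ] <- ob_batch(smiles[i], fields = fields,
                           neutralize = neutralize)[1L, ]
  }
  out
}

# Parse a Hill-style molecular formula (possibly with a trailing charge such
# as "C2H3O2-" or "Mg+2") into named element counts.
parse_formula <- function(formula) {
  formula <- sub("[+-][0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  if (m[1] == -1L) return(integer(0))
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  tapply(cnt, el, sum)
}

# Elements tolerated in an "organic" record. Everything else counts as a
# metal/inorganic element for the curation filter. Configurable at the
# standardization surface.
organic_elements <- function() {
  c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I",
    "He", "Ne", "Ar", "Kr", "Xe", "Rn")
}

# Count rings whose closure bond is opened on an aromatic atom, from an
# OpenBabel canonical aromatic SMILES. Each ring-closure digit pair is one
# ring of the SSSR; the digit's first occurrence sits on the opening atom,
# which is aromatic iff written in lowercase (or as a lowercase bracket
# atom). Two-letter elements outside brackets (Cl, Br) contain no
# ring-opening lowercase aromatic symbol, so a simple scan suffices.
count_aromatic_rings <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    chars <- strsplit(s, "")[[1]]
    open <- list()          # digit -> aromatic flag of opening atom
    n_arom <- 0L
    in_bracket <- FALSE
    last_arom <- FALSE
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "[") {
        in_bracket <- TRUE
        # bracket atom: aromatic iff element symbol starts lowercase
        j <- i + 1L
        while (j <= length(chars) && chars[j] %in% c("0","1","2","3","4","5","6","7","8","9")) j <- j + 1L
        last_arom <- j <= length(chars) && chars[j] %in% letters
      } else if (ch == "]") {
        in_bracket <- FALSE
      } else if (!in_bracket) {
        if (ch %in% c("b", "c", "n", "o", "p", "s")) {
          last_arom <- TRUE
        } else if (ch %in% LETTERS) {
          last_arom <- FALSE
        } else if (ch == "%") {
          d <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 2L
          if (is.null(open[[d]])) open[[d]] <- last_arom
          else { if (isTRUE(open[[d]])) n_arom <- n_arom + 1L; open[[d]] <- NULL }
        } else if (ch %in% c("0","1","2","3","4","5","6","7","8","9")) {
          if (is.null(open[[ch]])) open[[ch]] <- last_arom
          else { if (isTRUE(open[[ch]])) n_arom <- n_arom + 1L; open[[ch]] <- NULL }
        }
      }
      i <- i + 1L
    }
    n_arom
  }, integer(1), USE.NAMES = FALSE)
}
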