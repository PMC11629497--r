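# Synthetic chemical universe. Molecules are assembled by concatenating
# self-contained SMILES fragments: every fragment closes its own rings, so
# concatenation attaches the next fragment to the previous fragment's last
# written atom. Linker fragments can appear anywhere; terminal fragments
# only at the end (their last atom cannot take another bond). Candidates
# that OpenBabel rejects are dropped, so every emitted structure parses.

linker_fragments <- function() {
  c("C", "CC", "CCC", "CCCC", "C(C)C", "CO", "CCO", "CN", "CCN", "CS",
    "C(=O)N", "C(=O)O", "CC(C)C", "c1ccccc1", "c1ccc(F)cc1", "c1ccncc1",
    "C1CCCCC1", "C1CCNCC1", "c1ccsc1", "CCCO", "COC", "CNC")
}

terminal_fragments <- function() {
  c("O", "N", "Cl", "F", "Br", "C#N", "C(=O)O", "C(=O)N", "N(C)C",
    "C(F)(F)F", "S(=O)(=O)N", "OC", "C=O")
}

# Metal / single-heavy-atom species used for the inorganic minority of
# records (the kind of entries a graph model cannot process).
inorganic_species <- function() {
  c("[Mo]", "[Re]", "C", "[Mg+2]", "[H+].[F-]",
    "[O-2].[O-2].[Mg+2].[Ca+2]", "[Al+3].[Cl-].[Cl-].[Cl-]",
    "[Na+].[Cl-]", "[K+].[Br-]", "[Zn+2].[Cl-].[Cl-]")
}

#' Generate a universe of distinct synthetic molecules
#'
#' Builds `n_molecules` chemically parseable SMILES by concatenating 1-4
#' fragments from a built-in library of organic linkers plus an optional
#' polar/halogen terminal substituent. All returned structures are distinct
#' by connectivity key, and the output is deterministic for a fixed seed.
#'
#' @param n_molecules Number of distinct molecules to generate (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return Character vector of `n_molecules` SMILES.
#' @examples
#' \dontrun{
#' generate_universe(10, seed = 1)
#' }
#' @export
generate_universe <- function(n_molecules, seed) {
  stopifnot(n_molecules >= 1)
  linkers <- linker_fragments()
  terminals <- terminal_fragments()
  found <- character(0)
  seen_keys <- character(0)
  round <- 0L
  while (length(found) < n_molecules && round < 60L) {
    round <- round + 1L
    batch_n <- max(32L, 2L * (n_molecules - length(found)))
    cand <- with_seed(derive_seed(seed, paste0("universe-", round)), {
      vapply(seq_len(batch_n), function(i) {
        k <- sample(1:3, 1L, prob = c(0.3, 0.45, 0.25))
        body <- paste(sample(linkers, k, replace = TRUE), collapse = "")
        if (stats::runif(1) < 0.7)
          body <- paste0(body, sample(terminals, 1L))
        body
      }, character(1))
    })
    std <- standardize_smiles(cand)
    ok <- std$parse_ok & !std$contains_metal & !std$is_single_heavy_atom &
      std$n_fragments_before_desalt == 1L
    for (j in which(ok)) {
      key <- std$connectivity_key[j]
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      found <- c(found, cand[j])
      if (length(found) == n_molecules) break
    }
  }
  if (length(found) < n_molecules)
    stop("could not assemble ", n_molecules, " distinct molecules")
  found
}

#' Compute the descriptor vector of a structure
#'
#' Deterministic five-element descriptor vector computed from the
#' standardized (de-salted) structure: heavy-atom count, aromatic-ring
#' count, hydrogen-bond donor count, hydrogen-bond acceptor count and
#' heteroatom fraction. Salt forms and their parent map to identical
#' vectors; so do all records sharing a connectivity key.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix with one row per input and columns
#'   `heavy_atoms`, `aromatic_rings`, `hbd`, `hba`, `heteroatom_fraction`.
#'   Unparseable inputs raise an error carrying the parser message.
#' @examples
#' \dontrun{
#' featurize("c1ccccc1")
#' }
#' @export
featurize <- function(smiles) {
  std <- standardize_smiles(smiles)
  if (any(!std$parse_ok))
    stop("cannot featurize: ", std$parse_error[which(!std$parse_ok)[1]],
         " [", std$input[which(!std$parse_ok)[1]], "]", call. = FALSE)
  descriptor_matrix(std)
}

# Descriptor matrix straight from an already-standardized table.
descriptor_matrix <- function(std) {
  m <- cbind(heavy_atoms = as.numeric(std$n_heavy_atoms),
             aromatic_rings = as.numeric(std$n_aromatic_rings),
             hbd = as.numeric(std$hbd),
             hba = as.numeric(std$hba),
             heteroatom_fraction = as.numeric(std$heteroatom_fraction))
  rownames(m) <- NULL
  m
}

#' Default descriptor coefficients of the synthetic ground truth
#'
#' The synthetic true solubility is a fixed linear function of the
#' descriptor vector (see [featurize()]). The defaults give logS values
#' roughly in the -8..0 range typical of drug-like compilations: solubility
#' falls with size and aromaticity and rises with polarity.
#'
#' @return Named numeric vector of length 5.
#' @export
default_truth_coefficients <- function() {
  c(heavy_atoms = -0.35, aromatic_rings = -0.6, hbd = 0.35, hba = 0.25,
    heteroatom_fraction = 1.5)
}

#' Synthetic true solubility of structures
#'
#' Purely deterministic linear map of the descriptor vector; the ground
#' truth against which generated noisy records and model recoveries are
#' checked.
#'
#' @param smiles Character vector of SMILES (parseable).
#' @param coefficients Numeric vector of length 5, one coefficient per
#'   descriptor in [featurize()] order.
#' @return Numeric vector of true logS values (log mol/L).
#' @export
true_solubility <- function(smiles, coefficients = default_truth_coefficients()) {
  stopifnot(length(coefficients) == 5L)
  drop(featurize(smiles) %*% as.numeric(coefficients))
}

#' Ground-truth table for a universe
#'
#' One entry per unique connectivity in the generated universe, carrying
#' the true logS and the coefficients used.
#'
#' @param universe Character vector of SMILES from [generate_universe()].
#' @inheritParams true_solubility
#' @return A data.frame `molecule_id`, `smiles`, `connectivity_key`,
#'   `true_logS`, with the coefficient vector in attribute
#'   `"coefficients"`.
#' @export
ground_truth <- function(universe, coefficients = default_truth_coefficients()) {
  std <- standardize_smiles(universe)
  if (any(!std$parse_ok)) stop("universe contains unparseable structures")
  if (anyDuplicated(std$connectivity_key))
    stop("universe contains repeated connectivities")
  gt <- data.frame(
    molecule_id = sprintf("M%04d", seq_along(universe)),
    smiles = universe,
    connectivity_key = std$connectivity_key,
    true_logS = drop(descriptor_matrix(std) %*% as.numeric(coefficients)),
    stringsAsFactors = FALSE)
  attr(gt, "coefficients") <- coefficients
  gt
}
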