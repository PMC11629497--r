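# Shared fixtures. Chemistry-backed objects (universe, ground truth) are
# built once per test run and cached; purely numeric fixtures are built
# fresh from seeded RNG so each test controls its own conditions.

.fix <- new.env(parent = emptyenv())

fix_universe <- function(n = 30, seed = 42) {
  key <- paste0("u", n, "_", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- generate_universe(n, seed)
  .fix[[key]]
}

fix_truth <- function(n = 30, seed = 42) {
  key <- paste0("t", n, "_", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- ground_truth(fix_universe(n, seed))
  .fix[[key]]
}

# Record table with synthetic connectivity keys and descriptor columns but
# no real chemistry: logS is a linear function of the descriptors plus
# noise. Fast fixture for curation / fold / evaluation tests.
fix_linear_records <- function(n_molecules = 50, records_per_mol = 1,
                               noise_sd = 0.3, seed = 1,
                               beta = c(0.5, -0.3, -0.5, 0.3, 0.2, 1.0)) {
  set.seed(seed)
  desc <- data.frame(
    n_heavy_atoms = sample(3:25, n_molecules, replace = TRUE),
    n_aromatic_rings = sample(0:3, n_molecules, replace = TRUE),
    hbd = sample(0:4, n_molecules, replace = TRUE),
    hba = sample(0:6, n_molecules, replace = TRUE),
    heteroatom_fraction = round(runif(n_molecules, 0, 0.5), 3))
  idx <- rep(seq_len(n_molecules), each = records_per_mol)
  X <- as.matrix(cbind(1, desc[idx, ]))
  n <- length(idx)
  data.frame(
    record_id = sprintf("r%05d", seq_len(n)),
    connectivity_key = sprintf("KEY%04d", idx),
    desc[idx, , drop = FALSE],
    logS = drop(X %*% beta) + rnorm(n, 0, noise_sd),
    weight = 1,
    stringsAsFactors = FALSE, row.names = NULL)
}

# Prediction table with prescribed errors (y_obs = 0, y_pred = error).
fix_prediction_table <- function(errors, weights = rep(1, length(errors))) {
  data.frame(record_id = sprintf("p%04d", seq_along(errors)),
             y_pred = as.numeric(errors), y_obs = rep(0, length(errors)),
             weight = as.numeric(weights),
             fold = rep(0L, length(errors)), stringsAsFactors = FALSE)
}

# Direct-formula RMSE, kept deliberately naive as an independent oracle.
brute_force_rmse <- function(pred, obs) {
  total <- 0
  for (i in seq_along(pred)) total <- total + (pred[i] - obs[i])^2
  sqrt(total / length(pred))
}
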