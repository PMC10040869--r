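# Shared fixtures, generated in code at test time.

# Synthetic fingerprint matrix with a planted separable signal: actives carry
# 20 high-frequency signal bits over a sparse random background.
make_planted_fp <- function(n_per_class = 150, n_bits = 1024,
                            n_signal = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rbinom(2 * n_per_class * n_bits, 1, 0.05),
              2 * n_per_class, n_bits)
  y <- rep(c(1L, 0L), each = n_per_class)
  x[y == 1, seq_len(n_signal)] <- matrix(
    stats::rbinom(n_per_class * n_signal, 1, 0.9), n_per_class, n_signal)
  list(x = x, y = y)
}

# Activity-record table with hand-checked medians: four compounds designed to
# label active and four to label inactive at the 1000 nM / 50% cutoffs.
#   ethanol       IC50 {500}            -> median 500    active
#   benzene       IC50 {900, 1100}      -> median 1000   active (inclusive)
#   pyridine      IC50 {0.8 uM}         -> 800 nM        active
#   toluene       IC50 {200, 100, 5000} -> median 200    active
#   phenol        IC50 {2000}           -> inactive
#   aniline       IC50 {1500, 3000}     -> median 2250   inactive
#   benzaldehyde  IC50 {2 uM}           -> 2000 nM       inactive
#   anisole       IC50 {1001}           -> inactive (just over the cutoff)
toy_records <- function() {
  tibble::tibble(
    smiles = c("CCO",
               "c1ccccc1", "c1ccccc1",
               "c1ccncc1",
               "Cc1ccccc1", "Cc1ccccc1", "Cc1ccccc1",
               "Oc1ccccc1",
               "Nc1ccccc1", "Nc1ccccc1",
               "O=Cc1ccccc1",
               "COc1ccccc1"),
    target_uniprot = "P10001",
    value_type = "IC50",
    standard_value = c(500, 900, 1100, 0.8, 200, 100, 5000, 2000,
                       1500, 3000, 2, 1001),
    standard_units = c("nM", "nM", "nM", "uM", "nM", "nM", "nM", "nM",
                       "nM", "nM", "uM", "nM")
  )
}

toy_active_keys <- function() {
  std <- standardize_molecules(c("CCO", "c1ccccc1", "c1ccncc1", "Cc1ccccc1"))
  std$inchikey
}

toy_inactive_keys <- function() {
  std <- standardize_molecules(c("Oc1ccccc1", "Nc1ccccc1", "O=Cc1ccccc1",
                                 "COc1ccccc1"))
  std$inchikey
}

# Small end-to-end fixture (kept light; the default-scale fixture is exercised
# in the acceptance suite).
mini_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(n_targets = 3, identities = c(100, 70, 45),
                           n_actives_per_target = 15, n_inactives_per_target = 30,
                           library_size = 300, seed = 11)
      cache <<- generate_fixture(spec, dir = file.path(tempdir(), "lvs_mini_fixture"))
    }
    cache
  }
})

mini_training_config <- function(seed = 7) {
  training_config(n_folds = 5, seed = seed,
                  rf_grid = list(num_trees = 50, max_depth = 6),
                  mlp_grid = list(hidden = list(50), activation = "relu",
                                  alpha = 0.0001))
}
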