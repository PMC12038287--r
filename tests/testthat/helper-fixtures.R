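# Shared test fixtures: small deterministic cohorts built in code.

small_dataset <- function(n_patients = 400, seed = 11, ...) {
  generate_ehr(generator_config(n_patients = n_patients, seed = seed, ...))
}

# cache one medium cohort (with events) for reuse across test files
.fixture_env <- new.env(parent = emptyenv())

medium_events <- function() {
  if (is.null(.fixture_env$ev)) {
    ds <- generate_ehr(generator_config(n_patients = 3000, seed = 5))
    .fixture_env$ds <- ds
    .fixture_env$ev <- build_index_events(ds$bundle)
  }
  list(ds = .fixture_env$ds, ev = .fixture_env$ev)
}

# brute-force Hamming K-means optimum over all k^n assignments (tiny n):
# for a fixed assignment the majority bit (ties to 0) minimizes inertia
brute_force_kmodes <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    inertia <- 0
    for (j in unique(lab)) {
      Xi <- X[lab == j, , drop = FALSE]
      cj <- as.numeric(colSums(Xi) > nrow(Xi) / 2)
      inertia <- inertia + sum(abs(sweep(Xi, 2, cj)))
    }
    if (inertia < best) best <- inertia
  }
  best
}
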