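## Shared fixtures: hand-built lattice states and small cached datasets.

## Build an evac_state with pedestrians at given (row, col) coordinates.
place_state <- function(L = 8, peds = NULL, exits = "single", exit_sep = 2,
                        epsilon = 0.1) {
  cfg <- sim_config(L = L, alpha = 2, epsilon = epsilon, rho0 = 0,
                    exits = exits, exit_sep = exit_sep, seed = 1)
  st <- init_state(cfg)
  if (!is.null(peds)) {
    peds <- matrix(peds, ncol = 2)
    pos <- (peds[, 2] - 1L) * L + peds[, 1]
    st$occ[pos] <- 1L
    st$ped_pos <- stats::setNames(as.integer(pos), seq_len(nrow(peds)))
    st$N <- nrow(peds)
  }
  st
}

## Memoised heavier fixtures shared across test files.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## A small mixed-density dataset (CI conditions: 5 densities x 50 alpha x
## 8 windows = 2000 samples of 8 x 24 x 24).
ci_mixed_dataset <- function() {
  cached("ci_mixed", function() {
    build_dataset(dataset_manifest(rho0 = seq(0.1, 0.5, by = 0.1),
                                   alpha = alpha_grid(50), windows = 8,
                                   seed = 11))
  })
}

## The reference model trained on it (shared by the pattern and transfer
## checks; the fixed-epoch capacity check trains its own).
ci_mixed_model <- function() {
  cached("ci_mixed_fit", function() {
    evac_cnn(ci_mixed_dataset(), epochs = 25, patience = 6, lr = 2e-3,
             seed = 1)
  })
}

## A tiny dataset for cheap CNN plumbing tests.
tiny_dataset <- function() {
  cached("tiny", function() {
    build_dataset(dataset_manifest(rho0 = 0.3, alpha = c(0.5, 2.5, 4.5),
                                   windows = 10, channels = 2, L = 12,
                                   seed = 5))
  })
}
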