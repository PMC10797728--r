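# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# Tile-level feature matrix for the default four synthetic classes:
# n_per_class generated tiles each, features on the hematoxylin channel.
tile_feature_fixture <- function(n_per_class = 40L) {
  key <- paste0("tiles_", n_per_class)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  params <- default_texture_params()
  X <- NULL; y <- integer(0)
  for (p in params) {
    for (i in seq_len(n_per_class)) {
      tile <- generate_class_tile(p, seed = 1000L * p$class_id + i)
      X <- rbind(X, extract_all(hematoxylin_channel(tile)))
      y <- c(y, p$class_id)
    }
  }
  out <- list(X = X, y = y)
  .fixture_env[[key]] <- out
  out
}

# A default synthetic cohort, shared across tests that only read it.
cohort_fixture <- function(seed = 1L) {
  key <- paste0("cohort_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  coh <- generate_cohort(cohort_config(seed = seed))
  .fixture_env[[key]] <- coh
  coh
}

pair_matrix_fixture <- function(seed = 1L) {
  key <- paste0("pairs_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  # the cohort itself is large and transient; only the pair matrix is kept
  coh <- if (seed == 1L) cohort_fixture(1L)
  else generate_cohort(cohort_config(seed = seed))
  X <- cohort_pair_features(coh, c(0, 1, 5, 10))
  .fixture_env[[key]] <- X
  X
}

# Render an RGB tile from known H and E concentration maps.
render_from_concentrations <- function(cH, cE, M = default_stain_matrix()) {
  od <- cbind(as.vector(cH), as.vector(cE)) %*% t(M)
  array(od_to_rgb(od), dim = c(nrow(cH), ncol(cH), 3))
}
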