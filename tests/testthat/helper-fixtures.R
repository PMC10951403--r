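# Shared small-scale fixtures, generated once per test run.

fixture_env <- new.env()

# Desk-scale image set: 4 families x 6 exemplars at 64 px, with scrambles and
# rotations (96 images), plus PS statistics and the reduced feature space.
small_image_set <- function() {
  if (is.null(fixture_env$iset)) {
    fixture_env$iset <- make_full_image_set(
      n_exemplars = 6, size = 64, rng_seed = 42)
  }
  fixture_env$iset
}

small_ps_stats <- function() {
  if (is.null(fixture_env$stats)) {
    fixture_env$stats <- lapply(small_image_set()$images, compute_ps_statistics)
  }
  fixture_env$stats
}

small_reduced <- function() {
  if (is.null(fixture_env$reduced)) {
    fixture_env$reduced <- suppressWarnings(reduce_statistics(small_ps_stats()))
  }
  fixture_env$reduced
}

small_features <- function() {
  encoding_features(small_reduced(), small_image_set()$manifest)
}

# Desk-scale two-photon schedule matching the small image set.
small_tp_schedule <- function(n_repeats = 6, n_blanks = 24, rng_seed = 5) {
  make_trial_schedule("twophoton", rng_seed = rng_seed,
                      n_exemplars = 6, n_repeats = n_repeats,
                      n_blanks = n_blanks)
}

# Simulated two-photon session on the small feature set.
small_tp_session <- function() {
  if (is.null(fixture_env$tp)) {
    truth <- twophoton_ground_truth(n_cells = 40, rng_seed = 11)
    fixture_env$tp <- simulate_twophoton_session(
      small_features(), small_tp_schedule(), truth, rng_seed = 12)
  }
  fixture_env$tp
}

# Straight-from-formula d' oracles, independent of the package internals.
oracle_dprime_pooled <- function(x, y) {
  (sum(x) / length(x) - sum(y) / length(y)) /
    sqrt(0.5 * (sum((x - mean(x))^2) / (length(x) - 1) +
                  sum((y - mean(y))^2) / (length(y) - 1)))
}

oracle_dprime_stim <- function(stim, blank) {
  (mean(stim) - mean(blank)) /
    (sqrt(sum((stim - mean(stim))^2) / (length(stim) - 1)) +
       sqrt(sum((blank - mean(blank))^2) / (length(blank) - 1)))
}

# Closed-form ridge with intercept via explicit normal equations.
oracle_ridge <- function(X, y, lambda) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  A <- t(Xc) %*% Xc + lambda * diag(ncol(X))
  solve(A) %*% t(Xc) %*% yc
}
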