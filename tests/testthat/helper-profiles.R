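# In-code fixtures shared across test files. All randomness is seeded
# through the package generator, so fixtures are reproducible.

rand_profiles <- function(n, lens = c(20L, 40L), conservation = 0.8,
                          seed = 1L, prefix = "p") {
  generate_synthetic_profiles(n, lens, conservation, seed, prefix)
}

zero_profile <- function(L, id = "zero") new_profile(id, matrix(0, L, 20))

# feature vectors as dense vectors for direct comparison
dense_fv <- function(profile, k, sigma, oracle = FALSE) {
  f <- if (oracle) brute_force_feature_vector(profile, k, sigma)
  else feature_vector(profile, k, sigma)
  dense_features(f)
}

# Gram matrix straight from the brute-force oracle (no trie, no buffer)
oracle_kernel <- function(profiles, k, sigma) {
  F <- vapply(profiles, function(p) dense_fv(p, k, sigma, oracle = TRUE),
              numeric(20^k))
  K <- crossprod(F)
  dimnames(K) <- list(profile_ids(profiles), profile_ids(profiles))
  K
}

expect_same_features <- function(a, b) {
  expect_identical(a$leaf, b$leaf)
  expect_identical(as.integer(a$count), as.integer(b$count))
}

# deterministic stratified train/test split of a labeled task
split_task <- function(task, n_train_per_class) {
  ids <- profile_ids(task$profiles)
  by_class <- split(seq_along(ids), task$labels[ids])
  tr <- unlist(lapply(by_class, function(v) v[seq_len(n_train_per_class)]))
  list(train = task$profiles[tr], test = task$profiles[-tr],
       labels = task$labels)
}

# values-only view: strip kernel metadata attributes, keep dimnames
kernel_values <- function(K) {
  matrix(as.numeric(K), nrow(K), dimnames = dimnames(K))
}
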