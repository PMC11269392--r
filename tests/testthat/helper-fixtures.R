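# Shared fixtures, built once per test run and cached.

.fixtures <- new.env()

# The benchmark cohort: 8 disjoint-signature classes in 3 families,
# 20 samples per class over 5,000 CpGs. By construction the Bayes error is
# essentially zero, so classifier accuracy is attributable to the model.
bench_atlas <- function() {
  if (is.null(.fixtures$atlas)) {
    cfg <- synth_config(
      n_classes = 8, n_families = 3, samples_per_class = 20,
      atlas_size = 5000, signature_size = 300, p_high = 0.9, p_low = 0.1,
      seed = 101
    )
    .fixtures$atlas <- filter_zero_variance(generate_reference_atlas(cfg))
  }
  .fixtures$atlas
}

bench_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_masked_net(bench_atlas(), seed = 11)
  }
  .fixtures$model
}

# A small, fast atlas for feature-level tests.
small_atlas <- function(seed = 5) {
  cfg <- synth_config(
    n_classes = 3, n_families = 2, samples_per_class = 6,
    atlas_size = 300, signature_size = 60, seed = seed
  )
  filter_zero_variance(generate_reference_atlas(cfg))
}

# Independent nearest-centroid oracle: per-class majority-vote binary
# centroid from the reference matrix, Hamming distance on observed features.
nearest_centroid_predict <- function(atlas, values) {
  classes <- sort(unique(atlas$labels$class))
  cent <- vapply(classes, function(cl) {
    as.numeric(colMeans(atlas$matrix[atlas$labels$class == cl, , drop = FALSE]) >= 0.5)
  }, numeric(ncol(atlas$matrix)))
  obs <- !is.na(values)
  d <- colSums(abs(cent[obs, , drop = FALSE] - values[obs]))
  classes[which.min(d)]
}

# Scored cases from the bundled 19-case cohort table.
cohort_scored_cases <- function(score_col = "score_mc") {
  co <- example_cohort()
  tibble::tibble(case_id = co$case_id, score = co[[score_col]],
                 concordant = co$concordant)
}

# Simulate a fresh case from a class model, observe n CpGs, return the
# aligned feature vector and the true class.
simulate_aligned_case <- function(atlas, class, n_obs, seed,
                                  beta_noise_sd = 0) {
  prof <- simulate_case_profile(atlas, class, seed = seed)
  obs <- simulate_sparse_observation(atlas, prof, n_obs,
                                     beta_noise_sd = beta_noise_sd, seed = seed)
  align_to_atlas(binarize(obs), atlas)
}
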