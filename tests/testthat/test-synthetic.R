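test_that("degenerate probabilities force exact signature block structure", {
  cfg <- synth_config(n_classes = 2, samples_per_class = 1, atlas_size = 10,
                      signature_size = 5, p_high = 1, p_low = 0, seed = 1)
  atlas <- generate_reference_atlas(cfg)
  expect_equal(dim(atlas$matrix), c(2, 10))
  expect_equal(as.numeric(atlas$matrix[1, ]), c(rep(1, 5), rep(0, 5)))
  expect_equal(as.numeric(atlas$matrix[2, ]), c(rep(0, 5), rep(1, 5)))
  # two orthogonal profiles
  expect_equal(sum(atlas$matrix[1, ] * atlas$matrix[2, ]), 0)
})

test_that("atlas generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_classes = 8, n_families = 3, samples_per_class = 20,
                      atlas_size = 5000, signature_size = 300, seed = 1)
  a1 <- generate_reference_atlas(cfg)
  a2 <- generate_reference_atlas(cfg)
  expect_identical(a1$matrix, a2$matrix)
  expect_identical(a1$cpg, a2$cpg)
  expect_identical(a1$labels, a2$labels)
})

test_that("within-signature methylation rate matches p_high within exact binomial bounds", {
  cfg <- synth_config(n_classes = 4, samples_per_class = 25, atlas_size = 2000,
                      signature_size = 200, p_high = 0.9, p_low = 0.1, seed = 42)
  atlas <- generate_reference_atlas(cfg)
  for (cl in names(atlas$signatures)) {
    rows <- atlas$labels$class == cl
    block <- atlas$matrix[rows, atlas$signatures[[cl]]]
    n <- length(block)
    # exact binomial 99.9% interval for the number of methylated entries
    lo <- qbinom(5e-4, n, cfg$p_high)
    hi <- qbinom(1 - 5e-4, n, cfg$p_high)
    expect_gte(sum(block), lo)
    expect_lte(sum(block), hi)
  }
})

test_that("invalid configurations are rejected naming the violated invariant", {
  expect_error(
    synth_config(n_classes = 2, n_families = 3, samples_per_class = 2,
                 atlas_size = 100, signature_size = 10),
    "n_families"
  )
  expect_error(
    synth_config(n_classes = 5, samples_per_class = 2, atlas_size = 40,
                 signature_size = 10),
    "atlas_size"
  )
  expect_error(
    synth_config(n_classes = 2, samples_per_class = 2, atlas_size = 100,
                 signature_size = 10, p_high = 0.2, p_low = 0.5),
    "p_low"
  )
})

test_that("noiseless sparse observations reproduce the underlying states", {
  atlas <- small_atlas()
  prof <- simulate_case_profile(atlas, "MC_01", seed = 3)

  # all-methylated profile emits beta exactly 1 at every sampled site
  ones <- rep(1L, ncol(atlas$matrix))
  obs1 <- simulate_sparse_observation(atlas, ones, 50, beta_noise_sd = 0, seed = 4)
  expect_true(all(obs1$beta == 1))
  expect_equal(nrow(obs1), 50)

  # full observation covers every atlas CpG exactly once
  full <- simulate_sparse_observation(atlas, prof, ncol(atlas$matrix), seed = 5)
  expect_equal(nrow(full), ncol(atlas$matrix))
  expect_false(any(duplicated(paste(full$chrom, full$start))))

  # round trip: binarizing the noiseless output recovers the sampled states
  states <- binarize(full, threshold = 0.6)
  fv <- align_to_atlas(states, atlas)
  expect_equal(unname(fv$values), unname(as.numeric(prof)))

  # oversampling is an error
  expect_error(
    simulate_sparse_observation(atlas, prof, ncol(atlas$matrix) + 1),
    "exceeds"
  )
})

test_that("bin-count means follow the purity-dilution formula", {
  genome <- toy_genome()
  # diploid identity: expected count = mean_count regardless of purity
  flat <- simulate_bin_counts(NULL, 0.3, mean_count = 100, bin_size = 1e5, seed = 1)
  se <- sqrt(100 / nrow(flat))
  expect_lt(abs(mean(flat$count) - 100), 3 * se)

  # CN=4 at purity 1 doubles the expected count inside the segment
  seg4 <- tibble::tibble(chrom = "chr1", start = 0, end = 10e6, cn = 4)
  p4 <- simulate_bin_counts(seg4, 1, mean_count = 100, bin_size = 1e5, seed = 2)
  inside <- p4$chrom == "chr1" & p4$start < 10e6
  expect_lt(abs(mean(p4$count[inside]) - 200), 3 * sqrt(200 / sum(inside)))

  # CN=1 over 30% of the genome at purity 0.4: segment/flat ratio 0.8
  seg1 <- tibble::tibble(chrom = "chr1", start = 0, end = 30e6, cn = 1)
  p1 <- simulate_bin_counts(seg1, 0.4, mean_count = 100, bin_size = 1e5, seed = 3)
  inside <- p1$chrom == "chr1" & p1$start < 30e6
  ratio <- mean(p1$count[inside]) / mean(p1$count[!inside])
  # delta-method SE of the ratio over ~1,000 bins
  se_r <- 0.8 * sqrt(1 / (80 * sum(inside)) + 1 / (100 * sum(!inside)))
  expect_lt(abs(ratio - 0.8), 3 * se_r)

  # invalid inputs
  expect_error(simulate_bin_counts(seg1, 0), "purity")
  bad <- tibble::tibble(chrom = "chr9", start = 0, end = 1e6, cn = 3)
  expect_error(simulate_bin_counts(bad, 0.5), "genome model")
  overlap <- tibble::tibble(chrom = c("chr1", "chr1"), start = c(0, 5e6),
                            end = c(10e6, 15e6), cn = c(1, 3))
  expect_error(simulate_bin_counts(overlap, 0.5), "overlap")
})

test_that("negative-binomial dispersion widens counts around the same mean", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 50e6, cn = 2)
  pois <- simulate_bin_counts(seg, 1, mean_count = 100, dispersion = 0,
                              bin_size = 1e5, seed = 7)
  nb <- simulate_bin_counts(seg, 1, mean_count = 100, dispersion = 0.05,
                            bin_size = 1e5, seed = 7)
  expect_lt(abs(mean(nb$count) - mean(pois$count)), 5)
  expect_gt(var(nb$count), var(pois$count))
})

test_that("cohort simulation writes reproducible files with persisted ground truth", {
  cfg <- synth_config(n_classes = 2, samples_per_class = 3, atlas_size = 200,
                      signature_size = 40, seed = 9)
  specs <- tibble::tibble(case_id = c("S1", "S2"), class = c("MC_01", "MC_02"),
                          n_observed = c(100L, 150L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- simulate_cohort(cfg, specs, d1, bin_size = 5e6)
  r2 <- simulate_cohort(cfg, specs, d2, bin_size = 5e6)

  expect_true(file.exists(r1$manifest_path))
  expect_equal(r1$cases$true_class, specs$class)
  expect_equal(r1$cases$observed_cpg_count, specs$n_observed)
  for (f in c("S1_meth.tsv", "S1_bins.tsv", "S2_meth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # manifests agree apart from the directory-specific file paths
  m1 <- readr::read_tsv(r1$manifest_path, col_types = readr::cols())
  m2 <- readr::read_tsv(r2$manifest_path, col_types = readr::cols())
  cols <- setdiff(names(m1), c("methylation_path", "bins_path"))
  expect_identical(m1[, cols], m2[, cols])
  # files parse back through the package readers
  calls <- read_methylation_calls(r1$cases$methylation_path[1])
  expect_equal(nrow(calls), 100)
})
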