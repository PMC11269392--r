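test_that("interval counts land in their midpoint bin and totals are conserved", {
  genome <- toy_genome()
  reads <- tibble::tibble(chrom = "chr1", start = seq(2e6, 2.9e6, 1e5),
                          end = seq(2e6, 2.9e6, 1e5) + 500)
  prof <- bin_counts(reads, genome, bin_size = 1e6)
  expect_equal(prof$count[prof$chrom == "chr1" & prof$start == 2e6], 10)
  expect_equal(sum(prof$count), nrow(reads))

  # brute-force per-read loop oracle on 1,000 random reads
  set.seed(6)
  rnd <- tibble::tibble(
    chrom = sample(genome$chrom, 1000, replace = TRUE),
    start = floor(runif(1000, 0, 49e6))
  )
  rnd$end <- rnd$start + 300
  prof2 <- bin_counts(rnd, genome, bin_size = 1e6)
  brute <- stats::setNames(rep(0, nrow(prof2)),
                           paste(prof2$chrom, prof2$start))
  for (i in seq_len(nrow(rnd))) {
    mid <- (rnd$start[i] + rnd$end[i]) / 2
    key <- paste(rnd$chrom[i], floor(mid / 1e6) * 1e6)
    brute[key] <- brute[key] + 1
  }
  expect_equal(prof2$count, unname(brute))

  expect_error(bin_counts(tibble::tibble(chrom = "chrZ", start = 0, end = 10),
                          genome), "unknown chromosome")
})

test_that("normalization zeroes the median, is scale invariant, and recovers log2 copy ratios", {
  prof <- tibble::tibble(chrom = "chr1", start = seq(0, 99) * 1e6,
                         end = seq(1, 100) * 1e6, count = 50)
  norm <- normalize_bins(prof)
  expect_true(all(norm$log2 == 0))

  set.seed(3)
  prof$count <- rpois(100, 100)
  n1 <- normalize_bins(prof)
  prof2 <- prof
  prof2$count <- prof$count * 2
  n2 <- normalize_bins(prof2)
  expect_equal(n1$log2, n2$log2)

  # CN=4 at purity 1 and high coverage sits at log2 ratio ~ 1
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 10e6, cn = 4)
  raw <- simulate_bin_counts(seg, 1, mean_count = 5000, bin_size = 1e5, seed = 4)
  nn <- normalize_bins(raw)
  inside <- nn$chrom == "chr1" & nn$start < 10e6
  expect_equal(mean(nn$log2[inside]), 1, tolerance = 0.02)

  # masking: low-count bins are excluded and flagged
  prof$count[3] <- 2
  nm <- normalize_bins(prof, min_count = 10)
  expect_true(nm$masked[3])
  expect_true(is.na(nm$log2[3]))
})

test_that("reference subtraction removes shared artifacts and respects masks", {
  set.seed(9)
  prof <- tibble::tibble(chrom = "chr1", start = seq(0, 99) * 1e6,
                         end = seq(1, 100) * 1e6, count = rpois(100, 200))
  norm <- normalize_bins(prof)

  # self-subtraction is exactly zero
  self <- subtract_reference(norm, norm)
  expect_true(all(self$log2[!self$masked] == 0))

  # an all-zero reference is the identity
  flat <- norm
  flat$log2 <- 0
  flat$masked <- FALSE
  expect_equal(subtract_reference(norm, flat)$log2, norm$log2)

  # a planted technical artifact (+0.5 in both tumor and reference) cancels
  tumor <- prof
  tumor$count <- round(tumor$count * ifelse(seq_len(100) == 42, 2^0.5, 1))
  ref <- prof
  ref$count <- round(ref$count * ifelse(seq_len(100) == 42, 2^0.5, 1))
  corrected <- subtract_reference(normalize_bins(tumor), normalize_bins(ref))
  expect_lt(abs(corrected$log2[42]), 0.05)

  # masks propagate; mismatched grids are rejected
  ref2 <- norm
  ref2$masked[7] <- TRUE
  expect_true(subtract_reference(norm, ref2)$masked[7])
  shifted <- norm
  shifted$start <- shifted$start + 1
  expect_error(subtract_reference(norm, shifted), "grid mismatch")
})

test_that("a flat noiseless profile yields a single segment per chromosome", {
  prof <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 50),
    start = rep(seq(0, 49) * 1e6, 2), end = rep(seq(1, 50) * 1e6, 2),
    count = 100
  )
  segs <- segment_profile(normalize_bins(prof), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_bins, c(50L, 50L))
  expect_equal(segs$mean_log2, c(0, 0))
})

test_that("a planted step of +1 is localized within two bins", {
  set.seed(5)
  true_bp <- 100
  x <- c(rnorm(true_bp, 0, 0.1), rnorm(100, 1, 0.1))
  prof <- tibble::tibble(chrom = "chr1", start = seq_along(x) * 1e5 - 1e5,
                         end = seq_along(x) * 1e5, count = 100,
                         log2 = x, masked = FALSE)
  segs <- segment_profile(prof, seed = 2)
  expect_equal(nrow(segs), 2)
  found_bp <- segs$end[1] / 1e5
  expect_lte(abs(found_bp - true_bp), 2)
})

test_that("the first split equals the exhaustive two-segment least-squares fit", {
  set.seed(12)
  for (i in 1:5) {
    n <- sample(40:100, 1)
    k_true <- sample(10:(n - 10), 1)
    x <- c(rnorm(k_true, 0, 0.3), rnorm(n - k_true, 0.8, 0.3))
    # exhaustive SSE minimization over all admissible breakpoints
    min_bins <- 5
    sse <- sapply(min_bins:(n - min_bins), function(k) {
      sum((x[1:k] - mean(x[1:k]))^2) + sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
    })
    k_brute <- (min_bins:(n - min_bins))[which.min(sse)]

    prof <- tibble::tibble(chrom = "chr1", start = seq_along(x) - 1,
                           end = seq_along(x), count = 100, log2 = x,
                           masked = FALSE)
    segs <- segment_profile(prof, alpha = 0.01, min_bins = min_bins, seed = i)
    # the dominant breakpoint must be among segment boundaries and equal the
    # least-squares optimum
    expect_true(k_brute %in% segs$end[-nrow(segs)])
    # segment means are the means of their member bins
    for (j in seq_len(nrow(segs))) {
      expect_equal(segs$mean_log2[j],
                   mean(x[(segs$start[j] + 1):segs$end[j]]))
    }
  }
})

test_that("focal events are called against their flanks with width and annotation", {
  segs <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 20e6, 22e6), end = c(20e6, 22e6, 50e6),
    mean_log2 = c(0.0, 0.3, 0.01), n_bins = c(20L, 2L, 28L)
  )
  braf <- tibble::tibble(chrom = "chr1", start = 20.5e6, end = 21e6,
                         name = "BRAF")
  ev <- detect_focal_events(segs, annotations = braf)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "gain")
  expect_equal(ev$annotation, "BRAF")

  # flat profile: nothing to report
  flat <- tibble::tibble(chrom = "chr1", start = 0, end = 50e6,
                         mean_log2 = 0, n_bins = 50L)
  expect_equal(nrow(detect_focal_events(flat)), 0)

  # a whole-chromosome gain is not focal
  whole <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0, 0),
                          end = c(50e6, 50e6), mean_log2 = c(0.5, 0),
                          n_bins = c(50L, 50L))
  expect_equal(nrow(detect_focal_events(whole)), 0)
})
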