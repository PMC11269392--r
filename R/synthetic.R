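#' Configuration for the synthetic reference cohort generator
#'
#' The generator emulates a binary CpG methylation reference atlas: each tumor
#' class methylates a dedicated block of signature CpGs with high probability
#' (`p_high`) against a low background rate (`p_low`), and classes are grouped
#' into families. Disjoint signature blocks make the Bayes-optimal classifier
#' essentially perfect, so downstream classification accuracy is attributable
#' to the model rather than to ambiguity in the simulated data. An optional
#' `signature_overlap` fraction shifts neighbouring blocks into each other to
#' make the problem harder.
#'
#' @param n_classes Number of methylation classes.
#' @param n_families Number of methylation class families; classes are
#'   partitioned into families as evenly as possible. Must not exceed
#'   `n_classes`.
#' @param samples_per_class Reference samples simulated per class.
#' @param atlas_size Number of CpG sites in the atlas.
#' @param signature_size CpGs per class signature block. The blocks must fit:
#'   `signature_size * n_classes <= atlas_size`.
#' @param p_high Methylation probability at signature CpGs (default 0.9).
#' @param p_low Background methylation probability (default 0.1).
#' @param signature_overlap Fraction in `[0, 1)` of each signature block
#'   shared with the next class's block (default 0, fully disjoint).
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return A list of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(n_classes = 4, n_families = 2, samples_per_class = 10,
#'                     atlas_size = 1000, signature_size = 100, seed = 1)
#' @export
synth_config <- function(n_classes,
                         n_families = n_classes,
                         samples_per_class,
                         atlas_size,
                         signature_size,
                         p_high = 0.9,
                         p_low = 0.1,
                         signature_overlap = 0,
                         seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_families = as.integer(n_families),
    samples_per_class = as.integer(samples_per_class),
    atlas_size = as.integer(atlas_size),
    signature_size = as.integer(signature_size),
    p_high = p_high,
    p_low = p_low,
    signature_overlap = signature_overlap,
    seed = as.integer(seed)
  )
  if (cfg$n_families > cfg$n_classes) {
    abort("invalid config: n_families must be <= n_classes")
  }
  if (cfg$signature_size * cfg$n_classes > cfg$atlas_size) {
    abort("invalid config: signature_size * n_classes must be <= atlas_size")
  }
  if (!(p_low >= 0 && p_low < p_high && p_high <= 1)) {
    abort("invalid config: need 0 <= p_low < p_high <= 1")
  }
  if (signature_overlap < 0 || signature_overlap >= 1) {
    abort("invalid config: signature_overlap must be in [0, 1)")
  }
  structure(cfg, class = "synth_config")
}

# Evaluate code under a given seed without disturbing the caller's RNG stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a labeled binary methylation reference atlas
#'
#' Simulates a reference cohort of binary CpG methylation profiles with
#' class-specific signature blocks (see [synth_config()]). CpG sites are
#' placed at sorted genomic positions on the supplied genome model so that
#' simulated methylation-call files can be aligned back to the atlas by
#' coordinate.
#'
#' @param config A [synth_config()] object.
#' @param genome Genome model tibble (`chrom`, `length`); default
#'   [toy_genome()].
#'
#' @return An object of class `"ref_atlas"`: a list with
#'   \describe{
#'     \item{matrix}{integer 0/1 matrix, samples in rows, CpGs in columns}
#'     \item{cpg}{tibble of CpG coordinates (`chrom`, `start`, `end`), sorted}
#'     \item{labels}{tibble (`sample_id`, `class`)}
#'     \item{hierarchy}{tibble (`class`, `family`)}
#'     \item{signatures}{named list: class -> integer CpG column indices}
#'   }
#' @examples
#' cfg <- synth_config(n_classes = 2, samples_per_class = 3, atlas_size = 50,
#'                     signature_size = 10, seed = 7)
#' atlas <- generate_reference_atlas(cfg)
#' dim(atlas$matrix)
#' @export
generate_reference_atlas <- function(config, genome = toy_genome()) {
  stopifnot(inherits(config, "synth_config"))
  validate_genome(genome)
  with_seed_(config$seed, {
    n_samples <- config$n_classes * config$samples_per_class
    classes <- sprintf("MC_%02d", seq_len(config$n_classes))
    families <- sprintf("MCF_%d", seq_len(config$n_families))
    hierarchy <- tibble(
      class = classes,
      family = families[((seq_len(config$n_classes) - 1L) %% config$n_families) + 1L]
    )

    cpg <- random_cpg_sites(config$atlas_size, genome)

    # Disjoint consecutive signature blocks; optional overlap shifts each
    # block's tail into the next class's block.
    shift <- floor(config$signature_size * config$signature_overlap)
    signatures <- lapply(seq_len(config$n_classes), function(k) {
      start <- (k - 1L) * (config$signature_size - shift) + 1L
      idx <- seq(start, length.out = config$signature_size)
      idx[idx <= config$atlas_size]
    })
    names(signatures) <- classes

    labels <- tibble(
      sample_id = sprintf("REF_%04d", seq_len(n_samples)),
      class = rep(classes, each = config$samples_per_class)
    )
    mat <- matrix(
      rbinom(n_samples * config$atlas_size, 1L, config$p_low),
      nrow = n_samples, ncol = config$atlas_size
    )
    for (k in seq_len(config$n_classes)) {
      rows <- which(labels$class == classes[k])
      idx <- signatures[[k]]
      mat[rows, idx] <- rbinom(length(rows) * length(idx), 1L, config$p_high)
    }
    rownames(mat) <- labels$sample_id
    colnames(mat) <- cpg_key(cpg$chrom, cpg$start)

    new_ref_atlas(mat, cpg, labels, hierarchy,
                  signatures = signatures,
                  p_high = config$p_high, p_low = config$p_low)
  })
}

random_cpg_sites <- function(n, genome) {
  # Allocate sites to chromosomes proportionally to length, then draw sorted
  # unique positions within each chromosome.
  alloc <- floor(n * genome$length / sum(genome$length))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  purrr::map2_dfr(genome$chrom, seq_along(genome$chrom), function(ch, i) {
    pos <- sort(sample.int(genome$length[i] - 1L, alloc[i]))
    tibble(chrom = ch, start = as.numeric(pos), end = as.numeric(pos) + 1)
  }) %>%
    arrange(.data$chrom, .data$start)
}

cpg_key <- function(chrom, start) {
  # element-wise formatting: vectorized format() pads a common number of
  # decimals across the vector, which breaks key identity between calls
  paste0(chrom, ":", vapply(as.numeric(start),
                            function(s) format(s, scientific = FALSE, trim = TRUE),
                            character(1)))
}

#' Draw a fresh case profile from a class's generative model
#'
#' Samples a new binary methylation profile from the same per-class Bernoulli
#' model that generated the reference atlas, for use as the ground-truth state
#' of a simulated case.
#'
#' @param atlas A `ref_atlas` produced by [generate_reference_atlas()].
#' @param class Class label present in the atlas.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of length `ncol(atlas$matrix)`, named by CpG.
#' @export
simulate_case_profile <- function(atlas, class, seed = NULL) {
  stopifnot(inherits(atlas, "ref_atlas"))
  if (!class %in% names(atlas$signatures)) {
    abort(paste0("unknown class: ", class))
  }
  with_seed_(seed, {
    d <- ncol(atlas$matrix)
    p <- rep(atlas$p_low, d)
    p[atlas$signatures[[class]]] <- atlas$p_high
    stats::setNames(rbinom(d, 1L, p), colnames(atlas$matrix))
  })
}

#' Simulate a sparse methylation-call observation of a binary profile
#'
#' Emulates the sparse CpG coverage of low-pass nanopore sequencing: a uniform
#' subset of atlas CpGs is observed, each emitting a beta value equal to the
#' binary methylation state plus truncated Gaussian noise. Unsampled sites are
#' absent from the output, exactly as uncovered CpGs are absent from real
#' methylation-call files.
#'
#' @param atlas A `ref_atlas` (provides CpG coordinates).
#' @param profile Binary 0/1 vector of length `ncol(atlas$matrix)` (e.g. from
#'   [simulate_case_profile()]), or a reference `sample_id` in the atlas.
#' @param n_observed Number of CpG sites observed; must not exceed atlas size.
#' @param beta_noise_sd Standard deviation of Gaussian noise added to the
#'   binary state before clamping to `[0, 1]`. Zero gives exact states.
#' @param mean_calls Mean extra calls per site; per-site call counts are
#'   `1 + Poisson(mean_calls)`.
#' @param seed Optional integer seed.
#'
#' @return A methylation-call tibble (`chrom`, `start`, `end`, `beta`,
#'   `n_calls`), coordinate-sorted.
#' @export
simulate_sparse_observation <- function(atlas, profile, n_observed,
                                        beta_noise_sd = 0, mean_calls = 0.5,
                                        seed = NULL) {
  stopifnot(inherits(atlas, "ref_atlas"))
  if (is.character(profile) && length(profile) == 1) {
    if (!profile %in% rownames(atlas$matrix)) abort("unknown sample_id")
    profile <- atlas$matrix[profile, ]
  }
  d <- ncol(atlas$matrix)
  if (length(profile) != d) abort("profile length must equal atlas size")
  if (n_observed > d) abort("n_observed exceeds atlas size")
  if (beta_noise_sd < 0) abort("beta_noise_sd must be non-negative")
  with_seed_(seed, {
    idx <- sort(sample.int(d, n_observed))
    beta <- pmin(1, pmax(0, profile[idx] + rnorm(n_observed, 0, beta_noise_sd)))
    tibble(
      chrom = atlas$cpg$chrom[idx],
      start = atlas$cpg$start[idx],
      end = atlas$cpg$end[idx],
      beta = as.numeric(beta),
      n_calls = 1L + rpois(n_observed, mean_calls)
    ) %>% arrange(.data$chrom, .data$start)
  })
}

#' Simulate binned read counts with planted copy-number segments
#'
#' Forward model for low-pass WGS copy-number profiling: the genome is tiled
#' into fixed-width bins, each bin's expected count reflects the tumor copy
#' number diluted by tumor purity,
#' `mu = mean_count * (purity * CN + 2 * (1 - purity)) / 2`,
#' and counts are drawn negative-binomially with variance
#' `mu + dispersion * mu^2` (Poisson when `dispersion = 0`).
#'
#' @param true_segments Tibble (`chrom`, `start`, `end`, `cn`) of planted
#'   integer copy-number segments; regions not covered are diploid (CN 2).
#'   Segments must be non-overlapping and inside the genome model.
#' @param true_purity Tumor purity (cellularity) in `(0, 1]`.
#' @param mean_count Expected reads per diploid bin.
#' @param dispersion Negative-binomial dispersion `phi` (variance
#'   `mu + phi * mu^2`); `0` gives Poisson counts.
#' @param bin_size Bin width in base pairs.
#' @param genome Genome model tibble; default [toy_genome()].
#' @param seed Optional integer seed.
#'
#' @return A raw bin-count tibble (`chrom`, `start`, `end`, `count`) tiling
#'   the genome.
#' @export
simulate_bin_counts <- function(true_segments, true_purity,
                                mean_count = 100, dispersion = 0,
                                bin_size = 1e6, genome = toy_genome(),
                                seed = NULL) {
  validate_genome(genome)
  if (!(true_purity > 0 && true_purity <= 1)) abort("purity must be in (0, 1]")
  if (mean_count <= 0) abort("mean_count must be positive")
  segs <- validate_segments_input(true_segments, genome)
  bins <- tile_genome(genome, bin_size)
  cn <- rep(2, nrow(bins))
  if (nrow(segs) > 0) {
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(segs))) {
      hit <- bins$chrom == segs$chrom[i] & mid >= segs$start[i] & mid < segs$end[i]
      cn[hit] <- segs$cn[i]
    }
  }
  mu <- mean_count * (true_purity * cn + 2 * (1 - true_purity)) / 2
  with_seed_(seed, {
    counts <- if (dispersion <= 0) rpois(length(mu), mu)
              else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    bins$count <- as.numeric(counts)
    bins
  })
}

validate_segments_input <- function(segments, genome) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(), cn = numeric()))
  }
  need <- c("chrom", "start", "end", "cn")
  if (!all(need %in% names(segments))) {
    abort("segments need columns chrom, start, end, cn")
  }
  if (any(segments$cn < 0) || any(segments$cn != floor(segments$cn))) {
    abort("copy numbers must be non-negative integers")
  }
  segs <- arrange(segments, .data$chrom, .data$start)
  for (i in seq_len(nrow(segs))) {
    len <- genome$length[match(segs$chrom[i], genome$chrom)]
    if (is.na(len)) abort(paste0("segment chromosome not in genome model: ", segs$chrom[i]))
    if (segs$start[i] < 0 || segs$end[i] > len || segs$start[i] >= segs$end[i]) {
      abort("segment outside genome model or empty")
    }
    if (i > 1 && segs$chrom[i] == segs$chrom[i - 1] && segs$start[i] < segs$end[i - 1]) {
      abort("overlapping segments")
    }
  }
  segs
}

tile_genome <- function(genome, bin_size) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_size)
    tibble(
      chrom = genome$chrom[i],
      start = starts,
      end = pmin(starts + bin_size, genome$length[i])
    )
  })
}

#' Simulate a full cohort to disk
#'
#' Writes per-case methylation-call and bin-count TSVs plus a cohort manifest,
#' and returns the ground truth needed to verify every downstream stage.
#'
#' @param config A [synth_config()].
#' @param case_specs Tibble with one row per case: columns `case_id`, `class`,
#'   `n_observed`, and optionally `beta_noise_sd`, `purity`, `segments`
#'   (list-column of segment tibbles), `mean_count`, `dispersion`.
#' @param dir Output directory (created if needed).
#' @param genome Genome model for the copy-number forward model.
#' @param bin_size Bin width for simulated counts.
#'
#' @return A list with elements `atlas`, `cases` (ground-truth tibble with
#'   file paths), and `manifest_path`.
#' @export
simulate_cohort <- function(config, case_specs, dir,
                            genome = toy_genome(), bin_size = 1e6) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atlas <- generate_reference_atlas(config, genome)
  specs <- as_tibble(case_specs)
  if (!all(c("case_id", "class", "n_observed") %in% names(specs))) {
    abort("case_specs needs columns case_id, class, n_observed")
  }
  if (!"beta_noise_sd" %in% names(specs)) specs$beta_noise_sd <- 0
  if (!"purity" %in% names(specs)) specs$purity <- 1
  if (!"mean_count" %in% names(specs)) specs$mean_count <- 100
  if (!"dispersion" %in% names(specs)) specs$dispersion <- 0
  has_segs <- "segments" %in% names(specs)

  cases <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    seed_i <- config$seed + i
    profile <- simulate_case_profile(atlas, sp$class, seed = seed_i)
    calls <- simulate_sparse_observation(atlas, profile, sp$n_observed,
                                         beta_noise_sd = sp$beta_noise_sd,
                                         seed = seed_i)
    meth_path <- file.path(dir, paste0(sp$case_id, "_meth.tsv"))
    write_methylation_calls(calls, meth_path)
    segs <- if (has_segs) sp$segments[[1]] else NULL
    counts <- simulate_bin_counts(segs, sp$purity,
                                  mean_count = sp$mean_count,
                                  dispersion = sp$dispersion,
                                  bin_size = bin_size, genome = genome,
                                  seed = seed_i)
    bins_path <- file.path(dir, paste0(sp$case_id, "_bins.tsv"))
    readr::write_tsv(counts, bins_path)
    tibble(
      case_id = sp$case_id,
      true_class = sp$class,
      observed_cpg_count = sp$n_observed,
      true_purity = sp$purity,
      true_segments = list(segs),
      methylation_path = meth_path,
      bins_path = bins_path
    )
  })

  manifest <- tibble(
    case_id = cases$case_id,
    age_years = 8L,
    sex = "F",
    location = "simulated",
    reference_diagnosis = cases$true_class,
    lesion_type = "primary",
    pretreatment = "None",
    methylation_path = cases$methylation_path,
    bins_path = cases$bins_path
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  list(atlas = atlas, cases = cases, manifest_path = manifest_path)
}
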