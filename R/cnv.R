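#' Bin interval counts onto a fixed-width genome tiling
#'
#' Tiles each chromosome of the genome model into fixed-width bins (the last
#' bin of a chromosome may be short) and assigns each input interval's count
#' to the bin containing its midpoint. Rows without a `count` column count as
#' one read each, so per-read BED files and pre-aggregated count files are
#' both accepted.
#'
#' @param reads Tibble (`chrom`, `start`, `end`, optionally `count`) or path
#'   to a BED-like TSV with those columns.
#' @param genome Genome model tibble (`chrom`, `length`).
#' @param bin_size Bin width in base pairs; default 1 Mb, matched to ~0.5X
#'   low-pass coverage.
#' @return Raw bin-count tibble (`chrom`, `start`, `end`, `count`).
#' @export
bin_counts <- function(reads, genome = toy_genome(), bin_size = 1e6) {
  validate_genome(genome)
  if (is.character(reads)) {
    reads <- readr::read_tsv(reads, col_types = readr::cols())
  }
  if (!all(c("chrom", "start", "end") %in% names(reads))) {
    abort("reads need columns chrom, start, end")
  }
  if (!"count" %in% names(reads)) reads$count <- 1
  if (any(reads$count < 0)) abort("counts must be non-negative")
  unknown <- setdiff(unique(reads$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("unknown chromosome(s): ", paste(unknown, collapse = ", ")))
  }
  bins <- tile_genome(genome, bin_size)
  mid <- (reads$start + reads$end) / 2
  idx <- floor(mid / bin_size)
  key <- paste0(reads$chrom, ":", idx)
  bin_key <- paste0(bins$chrom, ":", floor(bins$start / bin_size))
  agg <- tapply(reads$count, key, sum)
  bins$count <- as.numeric(agg[bin_key])
  bins$count[is.na(bins$count)] <- 0
  bins
}

#' Normalize a raw bin-count profile to log2 ratios
#'
#' Bins with fewer than `min_count` reads are masked (their log2 ratio is
#' `NA` and they are excluded from all downstream stages). Unmasked autosomal
#' counts are divided by their median and log2-transformed, so the median
#' autosomal log2 ratio is zero by construction and the profile is invariant
#' to total sequencing depth.
#'
#' @param profile Raw bin-count tibble from [bin_counts()] or
#'   [simulate_bin_counts()].
#' @param min_count Minimum reads for a bin to be usable (default 10).
#' @param sex_chroms Chromosomes excluded from the median (default
#'   chrX/chrY; the toy genome has none).
#' @return Tibble (`chrom`, `start`, `end`, `count`, `log2`, `masked`).
#' @export
normalize_bins <- function(profile, min_count = 10, sex_chroms = c("chrX", "chrY")) {
  if (!"count" %in% names(profile)) abort("profile must carry raw counts")
  masked <- profile$count < min_count
  auto <- !masked & !(profile$chrom %in% sex_chroms)
  if (!any(auto)) abort("no usable bins after masking")
  med <- median(profile$count[auto])
  if (med == 0) abort("zero median count; profile cannot be normalized")
  out <- profile
  out$log2 <- ifelse(masked, NA_real_, log2(profile$count / med))
  out$masked <- masked
  out
}

#' Subtract a normal-reference profile from a tumor profile
#'
#' Removes region- and technology-specific artifacts by subtracting the
#' reference's log2 ratio bin-by-bin (subtraction in log space). The two
#' profiles must share an identical bin grid; a bin masked in either profile
#' is masked in the output.
#'
#' @param tumor,reference Normalized bin profiles from [normalize_bins()] on
#'   the same genome tiling.
#' @return Corrected bin profile with the same columns as the inputs.
#' @export
subtract_reference <- function(tumor, reference) {
  for (p in list(tumor, reference)) {
    if (!all(c("log2", "masked") %in% names(p))) abort("profiles must be normalized")
  }
  if (nrow(tumor) != nrow(reference) ||
      !identical(tumor$chrom, reference$chrom) ||
      !identical(tumor$start, reference$start) ||
      !identical(tumor$end, reference$end)) {
    abort("bin grid mismatch between tumor and reference")
  }
  out <- tumor
  out$masked <- tumor$masked | reference$masked
  out$log2 <- ifelse(out$masked, NA_real_, tumor$log2 - reference$log2)
  out
}

#' Segment a bin profile by recursive binary splitting
#'
#' Within each chromosome, the breakpoint maximizing the two-sample
#' t-statistic between left and right bins is proposed and accepted when its
#' permutation p-value falls below `alpha`; accepted splits recurse into both
#' halves. Masked bins are excluded; segment boundaries span from the first
#' to the last member bin. Segment means are plain means of member-bin log2
#' ratios.
#'
#' @param profile Normalized or reference-corrected bin profile.
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param min_bins Minimum bins per segment (default 5).
#' @param n_perm Permutations per split test (default 199).
#' @param seed Seed for the permutation test.
#' @return A tibble of segments (`chrom`, `start`, `end`, `mean_log2`,
#'   `n_bins`) with attribute `residual_sd`, the genome-wide SD of bin
#'   residuals around their segment means.
#' @export
segment_profile <- function(profile, alpha = 0.01, min_bins = 5,
                            n_perm = 199, seed = 1L) {
  if (!"log2" %in% names(profile)) abort("profile must be normalized first")
  if (is.null(profile$masked)) profile$masked <- FALSE
  usable <- profile[!profile$masked & is.finite(profile$log2), , drop = FALSE]
  if (nrow(usable) < 2 * min_bins) abort("too few unmasked bins to segment")
  with_seed_(seed, {
    segs <- purrr::map_dfr(unique(usable$chrom), function(ch) {
      sub <- usable[usable$chrom == ch, , drop = FALSE]
      bounds <- split_recursive(sub$log2, alpha, min_bins, n_perm)
      purrr::map_dfr(bounds, function(b) {
        tibble(
          chrom = ch,
          start = sub$start[b[1]],
          end = sub$end[b[2]],
          mean_log2 = mean(sub$log2[b[1]:b[2]]),
          n_bins = b[2] - b[1] + 1L
        )
      })
    })
    resid <- numeric(0)
    for (i in seq_len(nrow(segs))) {
      v <- usable$log2[usable$chrom == segs$chrom[i] &
                         usable$start >= segs$start[i] &
                         usable$end <= segs$end[i]]
      resid <- c(resid, v - segs$mean_log2[i])
    }
    attr(segs, "residual_sd") <- sd(resid)
    segs
  })
}

# Best single breakpoint of x by two-sample t-statistic, computed for all
# split positions at once from cumulative sums. Returns list(k, stat).
best_split <- function(x, min_bins) {
  n <- length(x)
  ks <- seq(min_bins, n - min_bins)
  if (length(ks) == 0) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  nl <- ks; nr <- n - ks
  sl <- cs[ks]; sr <- cs[n] - sl
  ml <- sl / nl; mr <- sr / nr
  ssl <- cs2[ks] - sl^2 / nl
  ssr <- (cs2[n] - cs2[ks]) - sr^2 / nr
  pooled <- (ssl + ssr) / (n - 2)
  se <- sqrt(pmax(pooled, 1e-12) * (1 / nl + 1 / nr))
  tstat <- abs(ml - mr) / se
  i <- which.max(tstat)
  list(k = ks[i], stat = tstat[i])
}

split_recursive <- function(x, alpha, min_bins, n_perm) {
  n <- length(x)
  if (n < 2 * min_bins) return(list(c(1L, n)))
  obs <- best_split(x, min_bins)
  if (is.null(obs) || !is.finite(obs$stat)) return(list(c(1L, n)))
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    bs <- best_split(sample(x), min_bins)
    if (is.null(bs)) 0 else bs$stat
  }, numeric(1))
  pval <- (1 + sum(perm_stats >= obs$stat)) / (n_perm + 1)
  if (pval >= alpha) return(list(c(1L, n)))
  left <- split_recursive(x[1:obs$k], alpha, min_bins, n_perm)
  right <- split_recursive(x[(obs$k + 1):n], alpha, min_bins, n_perm)
  c(left, lapply(right, function(b) b + obs$k))
}

#' Detect focal copy-number events from a segment table
#'
#' A segment is called focal when it is narrower than `max_width` and its
#' mean log2 ratio deviates from the length-weighted mean of its flanking
#' segments by at least `min_abs_log2`. Events overlapping intervals in an
#' annotation table (BED-like: `chrom`, `start`, `end`, `name`) are labeled
#' with the overlapped locus names.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param min_abs_log2 Minimum absolute log2 deviation from the flanks
#'   (default 0.15, low enough for purity-diluted single-copy gains).
#' @param max_width Maximum focal width in base pairs (default 10 Mb).
#' @param annotations Optional annotation tibble (`chrom`, `start`, `end`,
#'   `name`).
#' @return Tibble of events (`chrom`, `start`, `end`, `direction`,
#'   `mean_log2`, `delta_log2`, `width`, `annotation`); zero rows if none.
#' @export
detect_focal_events <- function(segments, min_abs_log2 = 0.15,
                                max_width = 10e6, annotations = NULL) {
  events <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    width <- seg$end - seg$start
    if (width > max_width) return(NULL)
    flanks <- segments[-i, ] %>% filter(.data$chrom == seg$chrom)
    flanks <- flanks[flanks$end == seg$start | flanks$start == seg$end, , drop = FALSE]
    flank_mean <- if (nrow(flanks) == 0) 0 else {
      sum(flanks$mean_log2 * flanks$n_bins) / sum(flanks$n_bins)
    }
    delta <- seg$mean_log2 - flank_mean
    if (abs(delta) < min_abs_log2) return(NULL)
    tibble(
      chrom = seg$chrom, start = seg$start, end = seg$end,
      direction = if (delta > 0) "gain" else "loss",
      mean_log2 = seg$mean_log2, delta_log2 = delta, width = width
    )
  })
  if (nrow(events) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), mean_log2 = numeric(),
                  delta_log2 = numeric(), width = numeric(),
                  annotation = character()))
  }
  events$annotation <- annotate_events(events, annotations)
  events
}

annotate_events <- function(events, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(rep(NA_character_, nrow(events)))
  }
  ev <- GenomicRanges::GRanges(events$chrom,
                               IRanges::IRanges(events$start + 1, events$end))
  an <- GenomicRanges::GRanges(annotations$chrom,
                               IRanges::IRanges(annotations$start + 1, annotations$end))
  hits <- GenomicRanges::findOverlaps(ev, an)
  out <- rep(NA_character_, nrow(events))
  for (q in unique(S4Vectors::queryHits(hits))) {
    subj <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]
    out[q] <- paste(annotations$name[subj], collapse = ",")
  }
  out
}

#' Genome-wide copy-number profile plot
#'
#' Scatter of per-bin log2 ratios along the genome with optional segment
#' means overlaid, the standard visual summary of a low-pass copy-number
#' profile.
#'
#' @param profile Normalized/corrected bin profile.
#' @param segments Optional segment tibble to overlay.
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profile, segments = NULL) {
  prof <- profile %>% filter(!.data$masked)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                          y = .data$log2)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey70") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "genomic position", y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "firebrick", linewidth = 1, inherit.aes = FALSE
    )
  }
  p
}
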