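#' Read and write methylation-call files
#'
#' Methylation calls use a bedGraph-like TSV dialect with header columns
#' `chrom`, `start`, `end`, `beta`, `n_calls` and 0-based half-open
#' coordinates. Malformed rows (beta outside `[0, 1]`, non-positive
#' intervals, duplicated sites) are rejected with their line numbers so that
#' upstream merge bugs surface immediately instead of being silently
#' resolved.
#'
#' @param path Path to the TSV file.
#' @return A coordinate-sorted tibble of methylation calls.
#' @export
read_methylation_calls <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  calls <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("chrom", "start", "end", "beta", "n_calls")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns in ", path, ": ", paste(missing_cols, collapse = ", ")))
  }
  calls <- dplyr::mutate(
    calls[, need],
    chrom = as.character(.data$chrom),
    dplyr::across(c("start", "end", "beta"), as.numeric),
    n_calls = as.integer(.data$n_calls)
  )
  if (nrow(calls) == 0) abort(paste0("empty methylation-call file: ", path))
  # +1 for the header line when reporting file line numbers
  bad_beta <- which(is.na(calls$beta) | calls$beta < 0 | calls$beta > 1)
  if (length(bad_beta) > 0) {
    abort(paste0("beta outside [0, 1] at line(s) ", paste(bad_beta + 1, collapse = ", ")))
  }
  bad_iv <- which(!(calls$start < calls$end) | calls$start < 0)
  if (length(bad_iv) > 0) {
    abort(paste0("invalid interval at line(s) ", paste(bad_iv + 1, collapse = ", ")))
  }
  dup <- which(duplicated(paste(calls$chrom, calls$start)))
  if (length(dup) > 0) {
    abort(paste0("duplicate CpG site at line(s) ", paste(dup + 1, collapse = ", ")))
  }
  arrange(calls, .data$chrom, .data$start)
}

#' @rdname read_methylation_calls
#' @param calls A methylation-call tibble.
#' @export
write_methylation_calls <- function(calls, path) {
  readr::write_tsv(calls[, c("chrom", "start", "end", "beta", "n_calls")], path)
}

#' Binarize methylation beta values
#'
#' A site is called methylated when `beta >= threshold` (the boundary value
#' itself is methylated). The default threshold of 0.6 is the standard choice
#' for sparse nanopore methylation calls, where per-site beta values are
#' computed from very few reads.
#'
#' @param calls Methylation-call tibble (`chrom`, `start`, ..., `beta`).
#' @param threshold Binarization threshold in `(0, 1)`.
#' @return Tibble (`chrom`, `start`, `state`) with `state` in `{0, 1}`.
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", start = c(0, 10), end = c(1, 11),
#'                         beta = c(0.60, 0.59), n_calls = c(1L, 1L))
#' binarize(calls)$state  # 1, 0
#' @export
binarize <- function(calls, threshold = 0.6) {
  if (!(threshold > 0 && threshold < 1)) abort("threshold must be in (0, 1)")
  tibble(
    chrom = calls$chrom,
    start = calls$start,
    state = as.integer(calls$beta >= threshold)
  )
}

#' Align a binarized site map to the reference atlas feature space
#'
#' Atlas CpGs covered by the case take their observed binary state; atlas
#' CpGs with no observation are `NA` (missing). Sites are matched by
#' `(chrom, start)` identity on 0-based coordinates; case sites outside the
#' atlas are ignored.
#'
#' @param sites Binarized site tibble (`chrom`, `start`, `state`) from
#'   [binarize()].
#' @param atlas A (filtered) `ref_atlas`.
#' @return An object of class `"feature_vector"`: list with `values` (numeric
#'   vector of 0/1/NA aligned to atlas CpG order) and `observed_count`.
#' @export
align_to_atlas <- function(sites, atlas) {
  stopifnot(inherits(atlas, "ref_atlas"))
  values <- rep(NA_real_, ncol(atlas$matrix))
  names(values) <- colnames(atlas$matrix)
  hit <- match(cpg_key(sites$chrom, sites$start), names(values))
  ok <- !is.na(hit)
  values[hit[ok]] <- sites$state[ok]
  structure(
    list(values = values, observed_count = sum(ok)),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d/%d atlas CpGs observed\n",
              x$observed_count, length(x$values)))
  invisible(x)
}

#' Coverage quality-control gate for atlas overlap
#'
#' Classification needs a minimum number of CpG sites overlapping the
#' reference atlas to be meaningful; cases below the gate are flagged for an
#' additional sequencing run but are not dropped — classification is still
#' attempted and reported as low-confidence.
#'
#' @param vector A `feature_vector` from [align_to_atlas()].
#' @param min_cpgs Minimum overlapping CpG count (inclusive); default 1000.
#' @return One-row tibble (`observed_count`, `min_cpgs`, `pass`, `note`).
#' @export
qc_check <- function(vector, min_cpgs = 1000) {
  stopifnot(inherits(vector, "feature_vector"))
  pass <- vector$observed_count >= min_cpgs
  tibble(
    observed_count = vector$observed_count,
    min_cpgs = as.integer(min_cpgs),
    pass = pass,
    note = if (pass) "ok" else "below minimum atlas overlap; additional sequencing run recommended"
  )
}
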