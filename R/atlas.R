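#' Construct a binary methylation reference atlas
#'
#' A `ref_atlas` holds the binary sample-by-CpG reference matrix, the CpG
#' coordinates defining the feature space, per-sample class labels, and the
#' class-to-family hierarchy used for family-level score aggregation.
#'
#' @param matrix Integer/numeric 0/1 matrix, samples in rows, CpGs in columns.
#' @param cpg Tibble of CpG sites (`chrom`, `start`, `end`), 0-based
#'   half-open, one row per matrix column, sorted by (chrom, start).
#' @param labels Tibble (`sample_id`, `class`), one row per matrix row.
#' @param hierarchy Tibble (`class`, `family`); every class maps to exactly
#'   one family.
#' @param signatures Optional named list of per-class signature CpG indices
#'   (kept by the synthetic generator).
#' @param p_high,p_low Optional generative probabilities (synthetic atlases).
#' @param filtered Logical; whether zero-variance filtering has been applied.
#'
#' @return An object of class `"ref_atlas"`.
#' @export
new_ref_atlas <- function(matrix, cpg, labels, hierarchy,
                          signatures = NULL, p_high = NA_real_,
                          p_low = NA_real_, filtered = FALSE) {
  if (!all(matrix %in% c(0, 1))) abort("atlas matrix entries must be 0/1")
  if (nrow(cpg) != ncol(matrix)) abort("cpg table must match matrix columns")
  if (nrow(labels) != nrow(matrix)) abort("labels must match matrix rows")
  if (is.unsorted(order(cpg$chrom, cpg$start))) {
    # order() is always sorted; check actual coordinate sortedness instead
  }
  o <- order(cpg$chrom, cpg$start)
  if (!identical(o, seq_len(nrow(cpg)))) abort("cpg sites must be sorted by (chrom, start)")
  if (anyDuplicated(hierarchy$class) > 0) {
    abort("every class must map to exactly one family")
  }
  missing_cls <- setdiff(unique(labels$class), hierarchy$class)
  if (length(missing_cls) > 0) {
    abort(paste0("classes missing from hierarchy: ", paste(missing_cls, collapse = ", ")))
  }
  structure(
    list(matrix = matrix, cpg = as_tibble(cpg), labels = as_tibble(labels),
         hierarchy = as_tibble(hierarchy), signatures = signatures,
         p_high = p_high, p_low = p_low, filtered = filtered),
    class = "ref_atlas"
  )
}

#' @export
print.ref_atlas <- function(x, ...) {
  cat(sprintf(
    "<ref_atlas> %d samples x %d CpGs, %d classes in %d families%s\n",
    nrow(x$matrix), ncol(x$matrix),
    dplyr::n_distinct(x$labels$class), dplyr::n_distinct(x$hierarchy$family),
    if (x$filtered) " (zero-variance filtered)" else ""
  ))
  invisible(x)
}

#' Remove zero-variance CpG features from a reference atlas
#'
#' CpG columns that are constant across all reference samples carry no
#' class information and are removed before training; the relative order of
#' the remaining columns is preserved. The operation is idempotent.
#'
#' @param atlas A `ref_atlas`.
#' @return The filtered `ref_atlas` (with `filtered = TRUE`).
#' @export
filter_zero_variance <- function(atlas) {
  stopifnot(inherits(atlas, "ref_atlas"))
  if (ncol(atlas$matrix) == 0) abort("atlas has no CpG columns")
  col_min <- apply(atlas$matrix, 2, min)
  col_max <- apply(atlas$matrix, 2, max)
  keep <- col_min != col_max
  if (!any(keep)) abort("degenerate atlas: all CpG columns are constant")
  new_ref_atlas(
    atlas$matrix[, keep, drop = FALSE],
    atlas$cpg[keep, , drop = FALSE],
    atlas$labels, atlas$hierarchy,
    signatures = remap_signatures(atlas$signatures, keep),
    p_high = atlas$p_high, p_low = atlas$p_low, filtered = TRUE
  )
}

remap_signatures <- function(signatures, keep) {
  if (is.null(signatures)) return(NULL)
  new_pos <- cumsum(keep)
  lapply(signatures, function(idx) new_pos[idx[keep[idx]]])
}
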