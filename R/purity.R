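#' Estimate tumor purity by cellularity/ploidy grid search
#'
#' Fits segment log2 ratios to integer absolute copy numbers over a grid of
#' cellularity (tumor purity) values: at cellularity `a` and tumor ploidy
#' `P`, a segment of tumor copy number `n` has expected log2 ratio
#' `log2((a*n + 2*(1-a)) / (a*P + 2*(1-a)))` — the tumor signal diluted by
#' the diploid normal-cell admixture. The fit error is the bin-count-weighted
#' mean squared distance of each segment mean to its nearest integer copy
#' state; the grid argmin is returned with per-segment copy assignments.
#'
#' The fit is intrinsically ambiguous under aliasing (a profile explained by
#' cellularity `a` with copy numbers `{1, 2, 3}` is explained equally well by
#' `a/2` with `{0, 2, 4}`), so a small parsimony penalty proportional to
#' `1 - a` breaks ties in favour of the higher cellularity, i.e. copy states
#' nearest diploid. Purity is only estimable when numerical chromosomal
#' alterations exist: when the genome fraction in clearly aberrant segments
#' (|log2| above `aneuploid_log2`) is below `min_aneuploid_frac`, or the
#' error profile is essentially flat across the grid, the fit is reported as
#' unidentifiable and no cellularity value is returned.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param cellularity_grid Candidate cellularities (default 0.05 to 1.00 in
#'   steps of 0.01).
#' @param ploidy_grid Candidate tumor ploidies (default 2; an extended grid
#'   such as `seq(1.5, 4, 0.1)` can be supplied, with ties broken toward the
#'   lowest ploidy).
#' @param max_cn Largest integer copy number considered (default 8).
#' @param min_aneuploid_frac Minimum genome fraction in aberrant segments for
#'   the estimate to be considered identifiable (default 0.05).
#' @param aneuploid_log2 Absolute log2 ratio above which a segment counts as
#'   aberrant (default 0.1).
#' @param penalty Weight of the `1 - cellularity` parsimony penalty
#'   (default 0.002, small against genuine misfit errors).
#' @param recenter Recenter segment means on their bin-weighted median before
#'   fitting (default `TRUE`). Median normalization of bin counts lets
#'   aberrant segments pull the genome-wide median away from the diploid
#'   level, shifting the whole profile by a constant; recentring pins the
#'   most prevalent copy state to log2 ratio zero, the assumption under
#'   which the expected-ratio formula holds. Requires the modal state to be
#'   the ploidy state, i.e. less than half the genome aberrant.
#'
#' @return An object of class `"purity_fit"`: list with `cellularity`
#'   (`NA` when unidentifiable), `ploidy`, `error`, `identifiable`,
#'   `aneuploid_fraction`, `assignments` (per-segment copy numbers), and the
#'   full `grid` of evaluated fits.
#' @export
estimate_purity <- function(segments,
                            cellularity_grid = seq(0.05, 1, by = 0.01),
                            ploidy_grid = 2,
                            max_cn = 8,
                            min_aneuploid_frac = 0.05,
                            aneuploid_log2 = 0.1,
                            penalty = 0.002,
                            recenter = TRUE) {
  if (is.null(segments) || nrow(segments) == 0) abort("empty segment set")
  w <- segments$n_bins / sum(segments$n_bins)
  r <- segments$mean_log2

  baseline <- if (recenter) weighted_median(r, w) else 0
  r <- r - baseline

  aneuploid_fraction <- sum(w[abs(r) > aneuploid_log2])

  grid <- tidyr::expand_grid(cellularity = cellularity_grid, ploidy = ploidy_grid)
  cns <- 0:max_cn
  fits <- purrr::pmap_dfr(grid, function(cellularity, ploidy) {
    denom <- cellularity * ploidy + 2 * (1 - cellularity)
    levels <- log2(pmax(cellularity * cns + 2 * (1 - cellularity), 2^-10) / denom)
    d <- abs(outer(r, levels, "-"))
    nearest <- max.col(-d, ties.method = "first")
    err <- sum(w * (r - levels[nearest])^2)
    tibble(cellularity = cellularity, ploidy = ploidy, error = err,
           score = err + penalty * (1 - cellularity),
           assignment = list(cns[nearest]))
  })

  flat_error <- (max(fits$error) - min(fits$error)) < 1e-6
  identifiable <- aneuploid_fraction >= min_aneuploid_frac && !flat_error

  best <- fits %>%
    arrange(.data$score, .data$ploidy) %>%
    slice(1)

  structure(
    list(
      cellularity = if (identifiable) best$cellularity else NA_real_,
      ploidy = if (identifiable) best$ploidy else NA_real_,
      error = best$error,
      identifiable = identifiable,
      aneuploid_fraction = aneuploid_fraction,
      baseline = baseline,
      assignments = dplyr::bind_cols(
        segments[, c("chrom", "start", "end", "mean_log2", "n_bins")],
        tibble(cn = if (identifiable) best$assignment[[1]] else rep(NA_integer_, nrow(segments)))
      ),
      grid = select(fits, -"assignment")
    ),
    class = "purity_fit"
  )
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  x[which(cumsum(w) >= 0.5)[1]]
}

#' @export
print.purity_fit <- function(x, ...) {
  if (x$identifiable) {
    cat(sprintf("<purity_fit> cellularity=%.2f ploidy=%.1f error=%.4g (aneuploid fraction %.2f)\n",
                x$cellularity, x$ploidy, x$error, x$aneuploid_fraction))
  } else {
    cat(sprintf("<purity_fit> unidentifiable (aneuploid fraction %.2f below floor or flat error profile)\n",
                x$aneuploid_fraction))
  }
  invisible(x)
}

#' @export
tidy.purity_fit <- function(x, ...) as_tibble(x$assignments)

#' @export
glance.purity_fit <- function(x, ...) {
  tibble(
    cellularity = x$cellularity,
    ploidy = x$ploidy,
    error = x$error,
    identifiable = x$identifiable,
    aneuploid_fraction = x$aneuploid_fraction
  )
}

#' @export
autoplot.purity_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$cellularity, y = .data$error,
                               colour = factor(.data$ploidy))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cellularity", y = "weighted squared error",
                  colour = "ploidy",
                  title = "Purity grid fit") +
    ggplot2::theme_minimal()
}
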