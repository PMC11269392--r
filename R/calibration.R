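#' Confusion accounting at a diagnostic score cutoff
#'
#' A case "passes" when its classification score is strictly greater than the
#' cutoff. Counts follow the diagnostic-calibration convention for
#' methylation classifiers: passing concordant cases are true positives,
#' non-passing concordant cases false negatives, non-passing discordant cases
#' true negatives, and passing discordant cases false positives.
#'
#' Two sensitivity figures are reported. `sensitivity` is the operational
#' definition used in this setting — the fraction of *all* cases that pass
#' the cutoff with a correct classification (`tp / n_total`). The
#' conventional epidemiological definition `tp / (tp + fn)` is reported
#' separately as `sensitivity_conventional`; the two differ whenever
#' discordant cases exist.
#'
#' @param cases Tibble with columns `score` (in `[0, 1]`) and `concordant`
#'   (logical: classification matches the reference diagnosis).
#' @param cutoff Score cutoff in `[0, 1]`; passing is strict (`score > cutoff`).
#' @return One-row tibble with counts (`tp`, `fn`, `tn`, `fp`, `n_total`) and
#'   metrics (`sensitivity`, `sensitivity_conventional`, `specificity`,
#'   `specificity_defined`).
#' @examples
#' cases <- tibble::tibble(score = c(0.9, 0.15, 0.1), concordant = c(TRUE, TRUE, FALSE))
#' confusion_at_cutoff(cases, 0.2)
#' @export
confusion_at_cutoff <- function(cases, cutoff) {
  check_scored_cases(cases)
  if (cutoff < 0 || cutoff > 1) abort("cutoff must be in [0, 1]")
  pass <- cases$score > cutoff
  tp <- sum(pass & cases$concordant)
  fn <- sum(!pass & cases$concordant)
  tn <- sum(!pass & !cases$concordant)
  fp <- sum(pass & !cases$concordant)
  n <- nrow(cases)
  spec_defined <- (tn + fp) > 0
  if (!spec_defined) {
    warn("specificity undefined: no discordant cases")
  }
  tibble(
    cutoff = cutoff, tp = tp, fn = fn, tn = tn, fp = fp, n_total = n,
    sensitivity = tp / n,
    sensitivity_conventional = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (spec_defined) tn / (tn + fp) else NA_real_,
    specificity_defined = spec_defined
  )
}

check_scored_cases <- function(cases) {
  if (!all(c("score", "concordant") %in% names(cases))) {
    abort("cases need columns 'score' and 'concordant'")
  }
  if (any(cases$score < 0 | cases$score > 1)) abort("scores must be in [0, 1]")
  if (any(is.na(cases$concordant))) abort("concordant flags must be non-missing")
  invisible(cases)
}

#' ROC points over all distinct score cutoffs
#'
#' Sweeps every distinct score (plus the endpoints below the minimum and at
#' the maximum) as a strict cutoff and reports the confusion metrics at each,
#' giving the full receiver operating characteristic of the classification
#' score as a predictor of concordant classification.
#'
#' @inheritParams confusion_at_cutoff
#' @return Tibble of [confusion_at_cutoff()] rows, one per candidate cutoff,
#'   in increasing cutoff order.
#' @export
roc_points <- function(cases) {
  check_scored_cases(cases)
  if (all(cases$concordant) || !any(cases$concordant)) {
    abort("ROC undefined: need at least one concordant and one discordant case")
  }
  cutoffs <- sort(unique(c(0, cases$score)))
  # strict cutoff at the lowest value already excludes it; prepend a cutoff
  # below every score so the (sens = max, spec = 0) endpoint is present
  cutoffs <- unique(c(max(0, min(cases$score) - 1e-9), cutoffs))
  purrr::map_dfr(cutoffs, function(cf) confusion_at_cutoff(cases, cf))
}

#' Area under the ROC curve of score vs. concordance
#'
#' Computed either by trapezoidal integration of the ROC points (conventional
#' sensitivity vs. 1 - specificity) or as the normalized Mann-Whitney U
#' rank statistic; the two are mathematically identical.
#'
#' @inheritParams confusion_at_cutoff
#' @param method `"trapezoid"` or `"rank"`.
#' @return AUC as a single number.
#' @export
roc_auc <- function(cases, method = c("trapezoid", "rank")) {
  method <- match.arg(method)
  check_scored_cases(cases)
  pos <- cases$score[cases$concordant]
  neg <- cases$score[!cases$concordant]
  if (length(pos) == 0 || length(neg) == 0) abort("AUC undefined")
  if (method == "rank") {
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    return(mean(cmp))
  }
  pts <- roc_points(cases) %>%
    mutate(fpr = 1 - .data$specificity, tpr = .data$sensitivity_conventional) %>%
    arrange(.data$fpr, .data$tpr)
  x <- c(0, pts$fpr, 1); y <- c(0, pts$tpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Select the diagnostic score cutoff from scored cases
#'
#' Default criterion: among cutoffs achieving 100% specificity (no passing
#' discordant case), take those maximizing the operational sensitivity
#' `tp / n_total`; the optimum is an interval of equivalent cutoffs, whose
#' midpoint is returned along with its endpoints. When full specificity is
#' unachievable the best achievable specificity is used and the result is
#' flagged.
#'
#' @inheritParams confusion_at_cutoff
#' @param criterion Only `"max-sensitivity-at-full-specificity"` currently.
#' @return One-row tibble (`cutoff`, `interval_lo`, `interval_hi`,
#'   `sensitivity`, `specificity`, `achieved_full_specificity`, `degenerate`).
#' @export
select_cutoff <- function(cases, criterion = "max-sensitivity-at-full-specificity") {
  criterion <- match.arg(criterion)
  pts <- roc_points(cases)
  if (length(unique(cases$score)) == 1) {
    warn("degenerate input: all scores equal; no finite optimal cutoff")
    return(tibble(cutoff = NA_real_, interval_lo = NA_real_, interval_hi = NA_real_,
                  sensitivity = NA_real_, specificity = NA_real_,
                  achieved_full_specificity = FALSE, degenerate = TRUE))
  }
  full <- filter(pts, .data$specificity >= 1)
  achieved <- nrow(full) > 0
  if (!achieved) {
    warn("full specificity unachievable; returning best achievable specificity")
    full <- filter(pts, .data$specificity >= max(pts$specificity, na.rm = TRUE))
  }
  best <- filter(full, .data$sensitivity >= max(full$sensitivity))
  # the optimal cutoffs form an interval: from the largest swept cutoff below
  # them (exclusive lower edge) up to the lowest passing concordant score
  lo <- min(best$cutoff)
  scores_above <- sort(unique(cases$score[cases$score > max(best$cutoff)]))
  hi <- if (length(scores_above) > 0) scores_above[1] else lo
  tibble(
    cutoff = (lo + hi) / 2, interval_lo = lo, interval_hi = hi,
    sensitivity = best$sensitivity[1], specificity = best$specificity[1],
    achieved_full_specificity = achieved, degenerate = FALSE
  )
}

#' ROC plot of classification score vs. concordance
#'
#' @inheritParams confusion_at_cutoff
#' @return A ggplot object.
#' @export
plot_roc <- function(cases) {
  pts <- roc_points(cases) %>%
    mutate(fpr = 1 - .data$specificity, tpr = .data$sensitivity_conventional)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity (conventional)",
                  title = "Classification score ROC") +
    ggplot2::theme_minimal()
}
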