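test_that("confusion accounting conserves n and classifies quadrants correctly", {
  cases <- tibble::tibble(score = c(0.9, 0.15, 0.1, 0.6),
                          concordant = c(TRUE, TRUE, FALSE, FALSE))
  cm <- confusion_at_cutoff(cases, 0.2)
  expect_equal(cm$tp, 1)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 1)
  expect_equal(cm$fp, 1)
  expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, cm$n_total)

  # property over random score/concordance draws
  set.seed(2)
  for (i in 1:20) {
    rc <- tibble::tibble(score = runif(15), concordant = runif(15) > 0.4)
    cf <- runif(1)
    m <- confusion_at_cutoff(rc, cf)
    expect_equal(m$tp + m$fn + m$tn + m$fp, 15)
  }
})

test_that("passing is strictly greater than the cutoff", {
  cases <- tibble::tibble(score = c(0.2, 0.2001), concordant = c(TRUE, TRUE))
  cm <- suppressWarnings(confusion_at_cutoff(cases, 0.2))
  expect_equal(cm$tp, 1)  # the exact-0.2 case does not pass
  expect_equal(cm$fn, 1)
})

test_that("raising the cutoff never increases tp or fp", {
  set.seed(4)
  cases <- tibble::tibble(score = runif(30), concordant = runif(30) > 0.3)
  cuts <- seq(0, 1, by = 0.05)
  cms <- purrr::map_dfr(cuts, function(cf) confusion_at_cutoff(cases, cf))
  expect_true(all(diff(cms$tp) <= 0))
  expect_true(all(diff(cms$fp) <= 0))
})

test_that("cutoff 0 with positive scores gives no negatives at all", {
  cases <- tibble::tibble(score = c(0.3, 0.5, 0.9, 0.2),
                          concordant = c(TRUE, TRUE, FALSE, TRUE))
  cm <- confusion_at_cutoff(cases, 0)
  expect_equal(cm$fn, 0)
  expect_equal(cm$tn, 0)
  expect_equal(cm$sensitivity, mean(cases$concordant))
})

test_that("the published cohort reproduces the 15/2/2/0 confusion at cutoff 0.2", {
  cases <- cohort_scored_cases("score_mc")
  cm <- confusion_at_cutoff(cases, 0.2)
  expect_equal(cm$tp, 15)
  expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 2)
  expect_equal(cm$fp, 0)
  expect_equal(round(100 * cm$sensitivity), 79)
  expect_equal(100 * cm$specificity, 100)
  # the conventional definition differs and is reported separately
  expect_equal(cm$sensitivity_conventional, 15 / 17)
})

test_that("ROC needs both concordant and discordant cases", {
  allc <- tibble::tibble(score = c(0.2, 0.8), concordant = c(TRUE, TRUE))
  expect_error(roc_points(allc), "concordant")
})

test_that("perfectly separated scores yield a perfect operating point", {
  cases <- tibble::tibble(score = c(0.9, 0.1), concordant = c(TRUE, FALSE))
  cm <- confusion_at_cutoff(cases, 0.5)
  expect_equal(cm$sensitivity_conventional, 1)
  expect_equal(cm$specificity, 1)
  sel <- select_cutoff(cases)
  expect_gt(sel$cutoff, 0.1)
  expect_lt(sel$cutoff, 0.9)
  expect_true(sel$achieved_full_specificity)
})

test_that("every cutoff between the top discordant and lowest passing concordant score keeps full specificity", {
  cases <- cohort_scored_cases("score_mc")
  for (cf in seq(0.085, 0.235, by = 0.005)) {
    expect_equal(confusion_at_cutoff(cases, cf)$specificity, 1)
  }
  # and the swept ROC grid agrees
  pts <- roc_points(cases)
  in_band <- pts$cutoff > 0.08 & pts$cutoff < 0.24
  expect_true(all(pts$specificity[in_band] == 1))
})

test_that("selected cutoff interval is bounded above by the lowest passing concordant score", {
  cases <- cohort_scored_cases("score_mc")
  sel <- select_cutoff(cases)
  expect_true(sel$achieved_full_specificity)
  expect_equal(sel$specificity, 1)
  expect_lte(sel$interval_hi, 0.24)
  expect_gt(sel$cutoff, sel$interval_lo)
  expect_lt(sel$cutoff, sel$interval_hi)
  # the midpoint itself attains the reported metrics
  cm <- confusion_at_cutoff(cases, sel$cutoff)
  expect_equal(cm$sensitivity, sel$sensitivity)
  expect_equal(cm$specificity, 1)

  # MCF scores give an optimal interval containing the 0.2 cutoff
  sel_f <- select_cutoff(cohort_scored_cases("score_mcf"))
  expect_lt(sel_f$interval_lo, 0.2)
  expect_gt(sel_f$interval_hi, 0.2)
})

test_that("degenerate all-equal scores are flagged with no finite optimum", {
  cases <- tibble::tibble(score = rep(0.5, 4),
                          concordant = c(TRUE, TRUE, FALSE, TRUE))
  expect_warning(sel <- select_cutoff(cases), "degenerate")
  expect_true(sel$degenerate)
  expect_true(is.na(sel$cutoff))
})

test_that("trapezoid and rank-statistic AUC agree with each other and with pROC", {
  set.seed(11)
  for (i in 1:5) {
    cases <- tibble::tibble(score = round(runif(25), 2),
                            concordant = runif(25) > 0.4)
    if (all(cases$concordant) || !any(cases$concordant)) next
    a1 <- roc_auc(cases, "trapezoid")
    a2 <- roc_auc(cases, "rank")
    expect_equal(a1, a2, tolerance = 1e-9)
    a3 <- as.numeric(pROC::auc(pROC::roc(
      response = cases$concordant, predictor = cases$score,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
    expect_equal(a2, a3, tolerance = 1e-9)
  }
})
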