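#' Load a cohort manifest
#'
#' A cohort manifest is a TSV with one row per case and columns `case_id`,
#' `age_years`, `sex`, `location`, `reference_diagnosis`, `lesion_type`,
#' `pretreatment`, plus optional per-case file paths and scoring columns.
#' [example_cohort()] loads the bundled 19-case pediatric CNS tumor cohort
#' with its published per-case methylation class (MC) and class family (MCF)
#' calls, scores, and concordance flags.
#'
#' @param path Path to a manifest TSV.
#' @return A tibble, one row per case.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  manifest <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("case_id", "age_years", "sex", "location", "reference_diagnosis",
            "lesion_type")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(manifest$age_years < 0)) abort("age_years must be non-negative")
  bad <- setdiff(unique(manifest$lesion_type), c("primary", "secondary"))
  if (length(bad) > 0) {
    abort(paste0("lesion_type outside {primary, secondary}: ", paste(bad, collapse = ", ")))
  }
  manifest
}

#' @rdname read_cohort_manifest
#' @export
example_cohort <- function() {
  read_cohort_manifest(
    system.file("extdata", "cohort_table.tsv", package = "methyldx")
  )
}

#' Run the full diagnostic analysis for one case
#'
#' Orchestrates the per-case pipeline: read methylation calls, binarize,
#' align to the atlas, QC the atlas overlap, score classes and families with
#' the classifier, call the top class/family against the diagnostic cutoff,
#' and — when binned counts are available — normalize, subtract the normal
#' reference, segment, detect focal events, and fit tumor purity. A QC
#' failure is recorded and flags the classification as low-confidence, but
#' the case is never silently dropped. Any stage error is captured with its
#' stage name in the report.
#'
#' @param case One-row tibble (or named list) with `case_id` and
#'   `methylation_path`; optionally `bins_path`.
#' @param model A `masked_net` classifier.
#' @param atlas The filtered `ref_atlas` the model was trained on.
#' @param cutoff Diagnostic score cutoff (default 0.2); a call passes when
#'   its score is strictly greater.
#' @param reference_profile Optional normalized normal-reference bin profile
#'   for artifact subtraction.
#' @param genome Genome model for binning (default [toy_genome()]).
#' @param bin_size Bin width in base pairs.
#' @param min_cpgs QC minimum atlas overlap (default 1000).
#' @param annotations Optional focal-event annotation tibble.
#' @param seed Seed for the segmentation permutation test.
#' @return An object of class `"case_report"`.
#' @export
run_case <- function(case, model, atlas, cutoff = 0.2,
                     reference_profile = NULL, genome = toy_genome(),
                     bin_size = 1e6, min_cpgs = 1000, annotations = NULL,
                     seed = 1L) {
  report <- list(
    case_id = case$case_id,
    parameters = list(cutoff = cutoff, bin_size = bin_size,
                      min_cpgs = min_cpgs, seed = seed),
    errors = list()
  )
  class(report) <- "case_report"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  calls <- stage("read_methylation_calls",
                 read_methylation_calls(case$methylation_path))
  if (is.null(calls)) return(report)

  fv <- stage("features", align_to_atlas(binarize(calls), atlas))
  if (is.null(fv)) return(report)
  report$qc <- qc_check(fv, min_cpgs = min_cpgs)

  scores <- stage("classify", predict(model, fv))
  if (!is.null(scores)) {
    fam <- aggregate_families(scores, model$hierarchy)
    top_mc <- top_call(scores)
    top_mcf <- top_call(fam)
    report$class_scores <- scores
    report$family_scores <- fam
    report$classification <- tibble(
      mc = top_mc$label, score_mc = top_mc$score,
      mcf = top_mcf$label, score_mcf = top_mcf$score,
      passes_cutoff = top_mc$score > cutoff,
      low_confidence = !report$qc$pass
    )
  }

  if ("bins_path" %in% names(case) && !is.na(case$bins_path)) {
    cnv <- stage("cnv", {
      raw <- readr::read_tsv(case$bins_path, col_types = readr::cols())
      norm <- normalize_bins(raw)
      corrected <- if (is.null(reference_profile)) norm else
        subtract_reference(norm, reference_profile)
      segs <- segment_profile(corrected, seed = seed)
      list(profile = corrected, segments = segs,
           focal_events = detect_focal_events(segs, annotations = annotations))
    })
    if (!is.null(cnv)) {
      report$segments <- cnv$segments
      report$focal_events <- cnv$focal_events
      report$purity <- stage("purity", glance(estimate_purity(cnv$segments)))
    }
  }
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s\n", x$case_id))
  if (!is.null(x$qc)) {
    cat(sprintf("  QC: %s (%d CpGs overlapping atlas)\n",
                if (x$qc$pass) "pass" else "FAIL", x$qc$observed_count))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  MC:  %s (score %.2f)\n  MCF: %s (score %.2f)\n  %s cutoff%s\n",
                x$classification$mc, x$classification$score_mc,
                x$classification$mcf, x$classification$score_mcf,
                if (x$classification$passes_cutoff) "passes" else "below",
                if (x$classification$low_confidence) " [low confidence]" else ""))
  }
  if (!is.null(x$purity)) {
    cat(sprintf("  purity: %s\n",
                if (isTRUE(x$purity$identifiable))
                  sprintf("%.2f", x$purity$cellularity)
                else "not identifiable"))
  }
  if (length(x$errors) > 0) {
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a cohort: demographics and calibration metrics
#'
#' Computes the standard cohort description (n, median age with range, sex,
#' diagnosis and lesion-type counts) together with the diagnostic calibration
#' metrics at the supplied cutoff whenever per-case scores and concordance
#' flags are available. For even cohort sizes the lower median age is
#' reported.
#'
#' @param manifest Cohort manifest tibble (see [read_cohort_manifest()]).
#' @param score_col Name of the score column used for confusion accounting
#'   (default `"score_mc"`).
#' @param cutoff Diagnostic cutoff (default 0.2).
#' @return A list of class `"cohort_summary"` with elements `n`,
#'   `median_age`, `age_range`, `sex_counts`, `diagnosis_counts`,
#'   `lesion_counts`, and (when scores are present) `calibration` (a
#'   [confusion_at_cutoff()] row) and `string_concordance` (fraction of
#'   cases whose nanopore and microarray classes are string-identical).
#' @export
summarize_cohort <- function(manifest, score_col = "score_mc", cutoff = 0.2) {
  if (nrow(manifest) == 0) abort("empty manifest")
  ages <- sort(manifest$age_years)
  n <- length(ages)
  out <- list(
    n = n,
    median_age = ages[ceiling(n / 2)],
    age_range = c(min(ages), max(ages)),
    sex_counts = count(manifest, .data$sex),
    diagnosis_counts = count(manifest, .data$reference_diagnosis, sort = TRUE),
    lesion_counts = count(manifest, .data$lesion_type)
  )
  if (score_col %in% names(manifest) && "concordant" %in% names(manifest)) {
    scored <- tibble(score = manifest[[score_col]],
                     concordant = manifest$concordant)
    out$calibration <- confusion_at_cutoff(scored, cutoff)
  }
  if (all(c("nanopore_mc", "microarray_mc") %in% names(manifest))) {
    eq <- manifest$nanopore_mc == manifest$microarray_mc
    out$string_concordance <- sum(eq, na.rm = TRUE) / n
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n=%d, median age %s (range %s-%s)\n",
              x$n, x$median_age, x$age_range[1], x$age_range[2]))
  if (!is.null(x$calibration)) {
    cat(sprintf("  at cutoff %.2f: %d/%d passing, sensitivity %.0f%%, specificity %.0f%%\n",
                x$calibration$cutoff, x$calibration$tp, x$calibration$n_total,
                100 * x$calibration$sensitivity, 100 * x$calibration$specificity))
  }
  invisible(x)
}

#' @export
glance.cohort_summary <- function(x, ...) {
  out <- tibble(
    n = x$n, median_age = x$median_age,
    age_min = x$age_range[1], age_max = x$age_range[2]
  )
  if (!is.null(x$calibration)) out <- dplyr::bind_cols(out, x$calibration)
  out
}

#' Write a case report to disk
#'
#' Serializes a [run_case()] report deterministically as JSON (lossless
#' round-trip), TSV (one row mirroring the cohort-table report columns),
#' and/or markdown (human-readable diagnostic summary containing every
#' section present in the JSON).
#'
#' @param report A `case_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv", "markdown")`.
#' @return Invisibly, the named character vector of files written.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv", "markdown")) {
  stopifnot(inherits(report, "case_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  base <- file.path(dir, report$case_id)
  if ("json" %in% formats) {
    paths["json"] <- paste0(base, ".json")
    jsonlite::write_json(unclass(report), paths["json"],
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", pretty = TRUE)
  }
  if ("tsv" %in% formats) {
    paths["tsv"] <- paste0(base, ".tsv")
    row <- tibble(case_id = report$case_id)
    if (!is.null(report$classification)) {
      row <- dplyr::bind_cols(row, report$classification)
    }
    if (!is.null(report$qc)) {
      row$qc_pass <- report$qc$pass
      row$observed_cpgs <- report$qc$observed_count
    }
    readr::write_tsv(row, paths["tsv"])
  }
  if ("markdown" %in% formats) {
    paths["markdown"] <- paste0(base, ".md")
    writeLines(report_markdown(report), paths["markdown"])
  }
  invisible(paths)
}

report_markdown <- function(report) {
  lines <- c(sprintf("# Case report: %s", report$case_id), "")
  if (!is.null(report$qc)) {
    lines <- c(lines, "## QC",
               sprintf("- atlas overlap: %d CpGs (minimum %d): %s",
                       report$qc$observed_count, report$qc$min_cpgs,
                       if (report$qc$pass) "pass" else "FAIL"), "")
  }
  if (!is.null(report$classification)) {
    cl <- report$classification
    lines <- c(lines, "## Classification",
               sprintf("- methylation class: %s (score %.3f)", cl$mc, cl$score_mc),
               sprintf("- methylation class family: %s (score %.3f)", cl$mcf, cl$score_mcf),
               sprintf("- %s the diagnostic cutoff%s",
                       if (cl$passes_cutoff) "passes" else "does not pass",
                       if (cl$low_confidence) " (low confidence: QC failed)" else ""),
               "")
  }
  if (!is.null(report$segments)) {
    lines <- c(lines, "## Copy number",
               sprintf("- %d segments", nrow(report$segments)),
               sprintf("- %d focal event(s)", nrow(report$focal_events)), "")
  }
  if (!is.null(report$purity)) {
    lines <- c(lines, "## Tumor purity",
               if (isTRUE(report$purity$identifiable)) {
                 sprintf("- cellularity %.2f (ploidy %.1f)",
                         report$purity$cellularity, report$purity$ploidy)
               } else {
                 "- not identifiable (no numerical chromosomal alterations)"
               }, "")
  }
  if (length(report$errors) > 0) {
    lines <- c(lines, "## Stage errors",
               sprintf("- %s: %s", names(report$errors), unlist(report$errors)), "")
  }
  lines
}
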