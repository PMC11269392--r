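# methyldx

DNA methylation-based classification and copy-number profiling of CNS tumors
from **sparse, low-pass nanopore whole-genome sequencing**.

Molecular classification of brain tumors by DNA methylation signature is part
of the WHO diagnostic standard, but the routine platform (Illumina EPIC
microarray) needs dedicated tissue, fixed probe sets and days of turnaround.
Low-pass nanopore WGS of otherwise discarded material (for example ultrasonic
aspirator tissue fragments) offers a fast, cheap alternative — at the price
of observing only a small, run-dependent subset of the reference CpG sites:
anywhere from a few thousand to a few hundred thousand of the several hundred
thousand atlas CpGs. `methyldx` implements the full analysis for this regime,
for neuropathology-oriented bioinformaticians who want a tested, scriptable
pipeline rather than a hosted service:

* **Feature stage** — bedGraph-style methylation calls are binarized at
  beta ≥ 0.6, aligned to a binary CpG reference atlas (zero-variance sites
  removed), and gated on a minimum of 1,000 atlas-overlapping CpGs; cases
  below the gate are flagged for an additional sequencing run, not dropped.
* **Classifier** — a neural network trained with *random feature masking*:
  each training sample has a random fraction of its CpGs (default 30–99%)
  replaced by an explicit missing encoding every epoch, so prediction under
  arbitrary sparsity is the regime the network was trained for. Raw outputs
  pass through temperature scaling and a softmax, giving a calibrated
  per-class score; class scores are summed over a class→family hierarchy for
  methylation-class-family (MCF) reporting.
* **Calibration** — ROC analysis of classification scores against reference
  concordance, with confusion accounting in which a case passing the strict
  cutoff (score > 0.2) and correctly classified is a true positive, and
  "sensitivity" is the operational fraction of all cases that pass with a
  correct call (the conventional tp/(tp+fn) is reported alongside).
* **CNV + purity** — binned read counts are median-normalized to log2
  ratios, a matched normal profile is subtracted in log space, segments are
  found by recursive binary splitting with permutation testing, focal events
  are called against their flanking segments, and tumor purity (cellularity
  α) is estimated by grid search: a segment of tumor copy number *n* has
  expected log2 ratio `log2((α·n + 2(1−α)) / (α·P + 2(1−α)))` at ploidy
  *P*, and the fit minimizes the bin-weighted squared distance of segment
  means to their nearest integer copy state. Profiles without numerical
  chromosomal alterations are reported as *unidentifiable*, never given a
  default purity.
* **Synthetic data** — a generator for labeled binary-atlas cohorts with
  class-specific signature blocks, sparse noisy per-case observations, and
  negative-binomial binned counts with planted integer copy segments diluted
  by purity, so every stage is testable against known ground truth.

## Worked example

```r
library(methyldx)

# a synthetic reference cohort: 4 classes in 2 families, 1,000 CpGs
cfg <- synth_config(n_classes = 4, n_families = 2, samples_per_class = 10,
                    atlas_size = 1000, signature_size = 150, seed = 1)
atlas <- filter_zero_variance(generate_reference_atlas(cfg))
model <- train_masked_net(atlas, hidden = 64, epochs = 40, seed = 2)
model
#> <masked_net> 989 CpG features, 4 classes, hidden=64, temperature=0.19, held-out accuracy=1.000

# a sparse case: 300 of 1,000 CpGs observed from a fresh MC_03 tumor profile
profile <- simulate_case_profile(atlas, "MC_03", seed = 5)
calls   <- simulate_sparse_observation(atlas, profile, n_observed = 300, seed = 6)
fv      <- align_to_atlas(binarize(calls, threshold = 0.6), atlas)
fv
#> <feature_vector> 300/989 atlas CpGs observed

scores <- predict(model, fv)
top_call(scores)
#> # A tibble: 1 × 3
#>   label score tie
#>   <chr> <dbl> <lgl>
#> 1 MC_03 1.000 FALSE
top_call(aggregate_families(scores, model$hierarchy))
#> 1 MCF_1 1.000 FALSE
```

The classifier recovers the simulated class from a 30% observation with a
score far above the 0.2 diagnostic cutoff. Copy number and purity from
simulated low-pass counts (true purity 0.4, CN = 1 on 30% of chr1):

```r
truth <- tibble::tibble(chrom = "chr1", start = 0, end = 15e6, cn = 1)
raw   <- simulate_bin_counts(truth, true_purity = 0.4, mean_count = 100,
                             bin_size = 1e5, seed = 7)
segs  <- segment_profile(normalize_bins(raw), seed = 8)
segs
#> # A tibble: 3 × 5
#>   chrom    start      end mean_log2 n_bins
#> 1 chr1         0 15000000   -0.260     150
#> 2 chr1  15000000 50000000    0.0248    350
#> 3 chr2         0 50000000    0.0203    500
estimate_purity(segs)
#> <purity_fit> cellularity=0.36 ploidy=2.0 error=1.182e-05 (aneuploid fraction 0.15)
```

The single-copy loss is segmented at the planted boundary and the estimated
cellularity (0.36) is close to the simulated truth; across the benchmark
grid of simulations (see below) recovery RMSE is about 0.01–0.02.

The published 19-case pediatric cohort bundled with the package reproduces
its headline diagnostics directly:

```r
summarize_cohort(example_cohort())
#> <cohort_summary> n=19, median age 8 (range 1-17)
#>   at cutoff 0.20: 15/19 passing, sensitivity 79%, specificity 100%
```

## Package layout

| Area | Functions |
|---|---|
| synthetic data | `synth_config`, `generate_reference_atlas`, `simulate_case_profile`, `simulate_sparse_observation`, `simulate_bin_counts`, `simulate_cohort` |
| features | `read_methylation_calls`, `binarize`, `filter_zero_variance`, `align_to_atlas`, `qc_check` |
| classifier | `train_masked_net`, `predict`, `aggregate_families`, `top_call`, `tidy`, `glance` |
| calibration | `confusion_at_cutoff`, `roc_points`, `roc_auc`, `select_cutoff`, `plot_roc` |
| CNV / purity | `bin_counts`, `normalize_bins`, `subtract_reference`, `segment_profile`, `detect_focal_events`, `estimate_purity`, `plot_cnv_profile`, `autoplot` |
| pipeline | `run_case`, `summarize_cohort`, `write_report`, `example_cohort`, `read_cohort_manifest` |

See the methods vignette (`vignettes/methods.Rmd`) for the model details,
parameter choices and known limitations.
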