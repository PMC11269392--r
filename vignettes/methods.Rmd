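---
title: "Methods: sparse-CpG methylation classification and copy-number purity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-CpG methylation classification and copy-number purity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldx)
```

# The diagnostic problem

Low-pass nanopore whole-genome sequencing (around 0.5X coverage) of tumor
tissue yields two diagnostic signals at once: per-CpG methylation calls for
methylation-based tumor classification, and genome-wide read depth for
copy-number profiling. Both signals are *sparse and shallow*. A single run
observes a small, essentially random subset of the CpG sites in the
methylation reference atlas — in practice anywhere from under 1% to over
80% of sites — and each observed site is covered by very few reads, so
per-site beta values (methylated fraction) are coarse. `methyldx`
implements an analysis designed for exactly this regime.

# Feature stage

**Binarization.** Beta values are binarized at a threshold of 0.6, with the
boundary value itself called methylated (`beta >= 0.6` → 1). Binarization
discards the unreliable magnitude of few-read beta estimates and keeps only
the state, which is what the reference atlas stores. The threshold is
exposed (`binarize(threshold=)`) but 0.6 is the established choice for
nanopore methylation calls.

**Atlas alignment.** CpG identity is `(chrom, start)` on 0-based half-open
coordinates throughout the package — atlas, methylation calls, bins and
annotations all share the same dialect, and readers validate it at load,
because a silent one-base shift is the classic failure mode when mixing
coordinate conventions. Duplicate sites within a case file are an error,
never resolved last-wins: duplicates indicate an upstream merge bug and
resolving them silently would hide it.

**Zero-variance filter.** Atlas CpG columns constant across all reference
samples carry no class information and are removed before training. The
filter is idempotent and preserves column order; an atlas whose columns are
all constant is rejected as degenerate rather than reduced to an empty
feature space.

**Coverage QC.** A case needs at least 1,000 atlas-overlapping CpGs
(`qc_check(min_cpgs = 1000)`, inclusive at the boundary) for the score to be
meaningful. The gate is a *warning* gate: a failing case is flagged for an
additional sequencing run and its classification is marked low-confidence,
but the analysis still runs — in clinical practice the remediation is to
sequence more, not to discard the case.

# The masked-feature classifier

## Model

The classifier is a single-hidden-layer feed-forward network (default 256
ReLU units) over the binary atlas features. Its defining element is the
*training-time masking*: every epoch, each training sample independently
draws a mask rate uniformly from `mask_range` (default `[0.3, 0.99]`) and
that fraction of its features is replaced by the missing encoding before the
forward pass. The default range spans the sparsity actually seen in
low-pass runs (roughly 0.6%–81% of atlas sites observed). At prediction
time, unobserved CpGs receive *exactly* the same encoding — missingness is
therefore in-distribution, not an afterthought.

**Missing encoding.** A missing feature is encoded as 0 in the value
channel plus a parallel binary observed-indicator channel concatenated to
the input (doubling the input dimension). Plain zero-filling would conflate
"unmethylated" with "unobserved"; the indicator channel keeps the two
distinguishable and lets the network learn how much to trust each feature.

**Score calibration.** Raw outputs are converted to probabilities by a
softmax after temperature scaling. The temperature is fitted after training
by minimizing the negative log-likelihood on the held-out split, evaluated
under several mask rates spanning the training range, so the score is
calibrated in the sparse regime where it will be used. A network trained
with heavy masking also learns the right limiting behaviour: an all-missing
input produces near-uniform scores on a balanced cohort, which the test
suite checks (no class above twice the uniform probability).

**Aggregation and calls.** Family scores are exact sums of member class
scores over the class→family hierarchy, so probability mass is conserved
and a family score is never below its top member's score. The top class
(MC) and top family (MCF) are *independent* calls — the family containing
the top class need not be the top family. Exact ties are broken by
lexicographic label order and flagged, never silently resolved.

## Training choices

Optimization is minibatch Adam (defaults: 60 epochs, batch 32, learning
rate 1e-3, He initialization), full determinism under the `seed` argument
(split, initialization, masking, batch order). A stratified fraction
(default 25%) of samples per class is held out; if held-out accuracy misses
`min_accuracy` (default 0.9) a convergence warning is raised rather than
silently returning a weak model. Non-finite gradients abort with the epoch
number. The architecture is deliberately the smallest adequate one — with
binarized inputs and signature-structured classes the problem is close to
linearly separable, and a deeper network would only slow the fit; width,
epochs and mask range are all exposed for harder atlases.

# Score cutoff calibration

The diagnostic cutoff is calibrated by ROC analysis of classification
scores against concordance with the reference diagnosis. Passing is
*strictly* greater than the cutoff. Two conventions deserve care:

* **Sensitivity** is reported under the operational definition used in this
  diagnostic setting — `tp / n_total`, the fraction of *all* cases passing
  the cutoff with a correct classification — with the conventional
  `tp / (tp + fn)` reported alongside. On the bundled 19-case cohort the
  two differ (15/19 = 79% vs 15/17 = 88%), and hiding either would be
  misleading.
* **Cutoff selection** on a small cohort is non-unique: all cutoffs between
  two adjacent observed scores give identical confusion counts.
  `select_cutoff()` therefore reports the whole optimal *interval* (highest
  operational sensitivity subject to 100% specificity) and returns its
  midpoint, rather than presenting one number as uniquely optimal. A fixed
  cutoff (0.2 is the platform convention) can always be imposed directly in
  `confusion_at_cutoff()` and `run_case()`.

The module accepts either MC or MCF score columns; on the bundled cohort
the MCF-based optimal interval contains 0.2, while the MC-based interval
sits lower — which is one reason the interval, not the point, is the honest
output. Degenerate inputs (all-concordant, all-discordant, all-equal
scores) are rejected or flagged rather than returning an arbitrary number.

# Copy-number profiling and purity

## Binning, normalization, reference subtraction

Reads or intervals are assigned to fixed-width bins by midpoint (default
1 Mb — at ~0.5X coverage a 1 Mb bin collects on the order of a few hundred
reads, enough for a stable ratio). Bins under a count floor (default 10)
are masked from all downstream stages. Counts are divided by the median of
unmasked autosomal bins and log2-transformed; normalization is thus
depth-invariant and centers the *median* bin at zero. A matched normal
reference profile is subtracted bin-wise in log space (log-space subtraction
makes the correction a ratio adjustment, symmetric for gains and losses);
bins masked in either profile stay masked. GC/mappability correction is
deliberately not built in — the simulation has no GC bias and real-data
users can pre-correct counts before binning; the TSV interface is the hook.

## Segmentation

Segmentation is recursive binary splitting: within each chromosome the
breakpoint maximizing the two-sample t-statistic is proposed and accepted
when its permutation p-value (default 199 permutations, fixed seed) is
below `alpha` (default 0.01), then both halves recurse; `min_bins`
(default 5) bounds segment size. Maximizing the t-statistic at a fixed
total sum of squares is equivalent to minimizing the two-segment residual
sum of squares, which gives the method an exact brute-force oracle — the
test suite verifies equality with exhaustive least-squares on small
profiles and ±2-bin breakpoint recovery on planted steps. This is simpler
than full circular binary segmentation but shares its test statistic, is
fully deterministic under seed, and is transparent to verify.

## Focal events

A segment narrower than `max_width` (default 10 Mb) whose mean deviates
from the bin-weighted mean of its flanking segments by at least
`min_abs_log2` (default 0.15) is reported as a focal gain or loss. The 0.15
default is low by design: the clinically interesting focal gains in this
setting (e.g. a *BRAF* tandem duplication in a pilocytic astrocytoma) are
single-copy gains diluted by purity, so their expected log2 ratio can be
well under 0.3. Events are annotated by overlap with a BED-style locus
table via `GenomicRanges`. Whole-chromosome changes are excluded by the
width filter — they belong to the segment table, not the focal report.

## Purity estimation

At cellularity `a` and tumor ploidy `P`, a segment of tumor copy number `n`
has expected log2 ratio

```
E[log2 ratio | n] = log2( (a*n + 2*(1-a)) / (a*P + 2*(1-a)) )
```

— tumor signal diluted by the diploid normal admixture. `estimate_purity()`
evaluates a cellularity grid (0.05–1.00, step 0.01; ploidy grid `{2}` by
default, extensible) and, for each candidate, assigns every segment to its
nearest integer copy state (0 to `max_cn`) and accumulates the bin-weighted
squared distance. Three numerical choices matter:

* **Baseline recentring.** Median normalization pins the median *bin* at
  zero, but aberrant segments drag the genome-wide median away from the
  diploid level, shifting the whole profile by a constant. Before fitting,
  segment means are recentred on their bin-weighted median, pinning the
  most prevalent copy state to zero — the assumption under which the
  formula above holds. This requires the modal state to be the ploidy
  state, i.e. less than half the genome aberrant; the same assumption
  underlies manual recentring of clinical CNV plots.
* **Aliasing and parsimony.** The fit is intrinsically ambiguous: a profile
  explained by cellularity `a` with copies `{1,2,3}` is explained *exactly*
  as well by `a/2` with `{0,2,4}`. A small penalty, `0.002 * (1 - a)`,
  added to the fit error breaks these exact ties toward the higher
  cellularity — equivalently toward copy states nearest diploid, the
  parsimonious reading (the alternative implies homozygous deletion of
  large genome fractions). The penalty is two orders of magnitude below
  typical genuine misfit errors, so it only arbitrates ties; on a grid with
  step 0.01 its bias is below half a grid step. Multi-ploidy grids break
  remaining ties toward the lowest ploidy.
* **Identifiability.** Purity is only estimable when numerical chromosomal
  alterations exist. When the genome fraction in clearly aberrant segments
  (|log2| > 0.1 after recentring) is below `min_aneuploid_frac` (default
  0.05), or the error profile is flat across the grid, the fit returns
  `identifiable = FALSE` with `cellularity = NA` — never a default value.
  The test suite checks the ladder property: shrinking the aberrant
  fraction drives the fit to unidentifiable *before* it returns a wrong
  estimate.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.

* **Reference atlas.** Each of `n_classes` classes methylates a dedicated
  block of `signature_size` CpGs with probability `p_high = 0.9` against a
  background of `p_low = 0.1`; classes partition into `n_families`
  families. Disjoint blocks make the Bayes error essentially zero, so
  classifier accuracy measures the model, not data ambiguity; an optional
  `signature_overlap` fraction makes the problem harder when wanted. The
  benchmark cohort used in tests and the acceptance script is 8 classes in
  3 families, 20 samples per class, 5,000 CpGs with 300-CpG signatures —
  large enough to exercise sparsity over two orders of magnitude, small
  enough to train in well under a minute.
* **Sparse observations.** A uniform random subset of atlas CpGs is
  observed; each emits `beta = clamp(state + N(0, sd), 0, 1)`. Truncated
  Gaussian noise around the binary state is the simplest model that
  exercises the 0.6 binarization boundary from both sides. The generator
  does *not* model the beta distribution of real bisulfite/nanopore data
  (bimodal with intermediate values from subclonality and cell mixture),
  nor non-uniform genomic coverage; passing tests show robustness to
  missingness and boundary noise, not to those real-data features.
* **Binned counts.** Expected count per bin is
  `mean_count * (purity*CN + 2*(1-purity)) / 2` with negative-binomial
  noise parameterized by mean and dispersion φ (variance `mu + phi*mu^2`),
  Poisson at φ = 0 — an explicit, closed-form forward model matching the
  purity fit's inverse model. The default genome is a 2 × 50 Mb toy model
  for desk-scale tests; hg19 chromosome sizes are bundled
  (`hg19_genome()`) for realistically scaled runs. Purity-recovery
  benchmarks plant CN 1 on 30% of chr1 and CN 3 on 40% of chr2 (35% of the
  genome aberrant) over 1,000 bins of 100 kb at mean count 100, at
  cellularities 0.25, 0.40, 0.65.

Seeds thread through every stochastic stage; identical configuration and
seed give byte-identical simulated files.

# Problem sizes and runtime

The test suite trains the benchmark classifier once (~30 s), runs 60
end-to-end purity recoveries (~1 min), and completes in under two minutes
on one CPU. The acceptance script re-simulates everything from its `--seed`
in under a minute. These sizes are the package's validation choices, scaled
so that a full from-scratch reproduction is routine rather than an event.

# Known limitations

* The classifier is validated on synthetic cohorts with block signatures;
  real methylation classes overlap and are class-imbalanced, and a real
  deployment would need a real reference cohort and its own recalibrated
  cutoff (the cutoff here is *platform-specific* by construction).
* Purity estimation assumes the modal copy state is the ploidy state and,
  with the default ploidy grid `{2}`, cannot distinguish genome-doubled
  tumors; the extended ploidy grid is available but underdetermined on
  small toy genomes.
* Reference subtraction assumes tumor and normal were binned on an
  identical grid and corrects only multiplicative (log-additive) artifacts.
* The focal-event caller reports segment-level deviations; it does not
  model breakpoint-level read evidence and will miss events narrower than a
  bin.
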