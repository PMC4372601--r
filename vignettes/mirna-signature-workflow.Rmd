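---
title: "Screening and validating a downregulated miRNA signature from blank-calibrated microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating a downregulated miRNA signature from blank-calibrated microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

## The analysis

mirscreen implements a complete biomarker-discovery workflow for case-control
miRNA expression studies in peripheral blood mononuclear cells (PBMCs), of the
kind used to propose diagnostic signatures for fibromyalgia (FM). The workflow
has four statistical stages over two assay platforms:

1. **Per-array signal processing.** Each microarray carries probe spots (one
   per miRNA species; 1212 on the emulated platform) and a population of
   *blank spots* with no probe, which measure background fluorescence. Per
   array: the blanks are ranked by intensity and the top and bottom 5% are
   discarded (`floor` of the count per tail); a probe is called **present**
   iff its signal strictly exceeds the trimmed blank mean plus twice the
   trimmed blank SD; present probes have the trimmed blank mean subtracted;
   and the background-corrected signals are rescaled so their median equals
   25. Absent probes are stored as 0 (configurable to `NA`) and never enter
   the median.
2. **Fold-change screening.** miRNAs whose control-group or case-group mean
   exceeds 5 are retained. Per miRNA, the screening statistic is the ratio of
   the control group mean to the case group mean ("C/FM"), so downregulation
   in cases gives ratios above 1. A census counts ratios of at least 2
   (inhibition of at least 50%) and at least 4 (at least 75%), and inductions
   beyond 1.5x. The **signature** is the set of miRNAs with a ratio of at
   least 6, sorted by ratio.
3. **qPCR validation.** Independent RT-qPCR measurements are converted to
   relative expression against the U6 reference gene as `2^-(Ct - Ct_U6)`
   (100% amplification efficiency; no calibrator sample, so this is a dCt
   rather than a ddCt design). Groups are compared per miRNA with the
   two-sided Mann-Whitney U test at alpha = 0.05, uncorrected.
4. **Clinical statistics.** Within the case group, validated miRNA levels are
   rank-correlated (Spearman) with the FIQ total severity score (0-100) and
   the five MFI fatigue subscales (0-20 each), with pairwise-complete
   deletion of missing assays. Two descriptive checks complete the analysis:
   a group comparison of per-sample small-RNA fractions (a composition-bias
   control), and a report on the case sample with the lowest mental-fatigue
   score and how its signature levels rank against the control minimum.

Stages are exposed both as composable functions
(`trimmed_blank_stats()`, `call_presence()`, `subtract_background()`,
`global_normalize()`, `normalize_scan()`, `heatmap_filter()`,
`summarize_groups()`, `census()`, `select_signature()`,
`relative_expression()`, `mann_whitney_u()`, `validate_mirnas()`,
`spearman_rho()`, `correlate_clinical()`, `compare_small_rna_fractions()`,
`flag_outlier_patient()`) and as one orchestrated call, `run_all()`. The
numbered scripts under `analysis/` run the same stages as a narrative
workflow writing tables under `results/`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `trim_fraction` | 0.05 | blanks removed per tail of the intensity ranking (floor of the count; below 20 blanks nothing is removed) |
| `sd_multiplier` | 2 | SDs above the trimmed blank mean for the detection threshold |
| `target_median` | 25 | post-normalization median of present signals (fluorescence units) |
| `absent_policy` | `set_zero` | absent probes recorded as 0 and included in group means, or as `NA` |
| `min_group_mean` | 5 | strict lower bound on at least one group mean for a miRNA to be retained |
| `down_thresholds` | 2, 4 | census fold thresholds for downregulation |
| `up_threshold` | 1.5 | case/control ratio counted as induction |
| `min_fold` | 6 | signature membership threshold on the C/FM ratio |
| `alpha` | 0.05 | validation significance level, two-sided, uncorrected |

All defaults reproduce the standard parameterization of this assay family
end to end; every constant is a visible argument, never hard-coded
downstream.

## Numerical and inferential choices

Where the procedure leaves details open, the package makes these choices:

* **Trimming count** is `floor(trim_fraction * n)` per tail — the
  conservative reading of "top and bottom 5%". With fewer than 20 blanks the
  trim removes nothing.
* **SD** is the sample standard deviation (n - 1 denominator); ties in the
  blank ranking are broken by stable sort order; the **median** of an even
  count is the mean of the two central values.
* **Presence is strict**: a signal exactly at the threshold is absent
  ("more than" the threshold). Presence is therefore monotone in intensity,
  and background subtraction of a present probe is always positive.
* **Absent probes are zeros** under the default policy: they keep the matrix
  rectangular and contribute 0 to group means, which is how a strongly
  downregulated miRNA can show a very low case-group average. They are never
  part of the normalization median — including structural zeros would make
  the target unreachable whenever most probes are absent.
* **The screening ratio is a ratio of group means**, not a mean of
  per-sample ratios. A case mean of exactly 0 with a positive control mean
  yields an infinite ratio that counts as downregulated at every threshold;
  a 0/0 ratio is undefined (`NaN`) and excluded from every ratio-based count.
* **Mann-Whitney U** uses midranks; the p-value is exact (full enumeration
  of rank assignments) for pooled samples up to 12 without ties, otherwise a
  normal approximation with tie-corrected variance and continuity
  correction. The two definitions agree with `wilcox.test()` on both paths.
* **Spearman's rho** is the Pearson correlation of midranks; the p-value is
  exact by full permutation for n up to 9 and a t approximation on n - 2
  degrees of freedom above that. The t approximation is only a sanity
  envelope at small n: exhaustively over all rankings, it deviates from the
  exact p by at most 0.027 (n = 7) and 0.048 (n = 6), but by up to 0.077 at
  n = 5 and 0.15 at n = 4 — which is why the exact path exists and is the
  default at those sizes.
* **No multiplicity correction** is applied anywhere by default, matching
  the descriptive character of the screen; Benjamini-Hochberg is available
  via `p_adjust = "BH"` in `validate_mirnas()`.
* **Technical qPCR replicates** are averaged on the Ct scale before dCt.
* **Argmin ties** in the outlier-patient report are broken by sample-id
  order, with a message.

## What the synthetic cohorts emulate

`simulate_cohort()` generates complete cohorts — array scans, sample sheet
with clinical scores and small-RNA fractions, qPCR tables, and a ground-truth
record — so every stage is testable without any external data. The defaults
are the study conditions: 11 cases vs 10 controls; 1212 probes and 100 blank
spots per array; the five signature miRNAs implanted at their published fold
reductions (6.31, 10.39, 11.15, 11.61, 13.47) along with the three assay
controls (3.88, 1.15, 1.36); 20% of probes downregulated 2-4x in cases; 30%
of probes absent; FIQ at 74.11 +/- 13.32 and MFI subscales at their published
case-group means/SDs, truncated to instrument ranges (MFI values are
integers); small-RNA fractions at 14.0 +/- 3.4% (controls) and
16.1 +/- 10.2% (cases); and Ct values generated as
`Ct = Ct_U6 + dCt_base + log2(fold) + noise`.

The generative model is deliberately simple and inspectable:

* **Fluorescence is additive**: spot signal = expression x noise +
  a background draw, with blanks being pure background (log-normal,
  median 30). Background subtraction therefore exactly inverts the model:
  in the zero-noise limit the pipeline recovers every implanted fold to
  floating-point precision, and the test suite asserts this closed form.
* **Baselines are drawn once per cohort** (log-normal, median 1500,
  log-SD 2.2 — spanning the 3+ decades a real miRNA array covers), so arrays
  differ only by a global scale factor (log-SD 0.2; removed exactly by
  normalization, and the pipeline is provably invariant to it) and per-spot
  technical noise (CV 5%, the replicate-spot scale of fluorescence arrays).
* **Absent probes are blank draws**, so a few land just above the detection
  threshold on any given array — the presence caller is exercised on both
  sides of its boundary, as in real data.
* **Broad downregulation lives among abundant probes** (baseline at least
  2.5x the typical level), with each fold capped so the case-group level
  stays above the per-array median. This mirrors the real data — the
  strongly downregulated miRNAs are all high-signal probes — and keeps the
  global median comparable between groups, so median normalization does not
  systematically compress the implanted folds.
* The assayed panel sits at deterministic high baselines (2000 fluorescence
  units per unit fold) so its case-group signal stays well above detection.

What the generator does **not** emulate: biological inter-individual
variability beyond multiplicative noise, probe-sequence effects
(hybridization or primer thermodynamics), PBMC subpopulation composition,
batch or spatial artifacts, induced (upregulated) miRNAs, and
platform-discordant assays (in the real study the ~4-fold microarray change
of one miRNA failed qPCR confirmation; here array and qPCR are generated
from one truth, so such discordance cannot arise). Passing recovery tests
therefore demonstrates correctness of the computation under the stated
model, not robustness to everything real cohorts do.

One behavior worth knowing: the weakest implanted signature member (6.31x)
sits just above the 6-fold selection threshold. With the default 5% spot
noise the recovered ratio has a few percent of sampling error, so across
seeds the screen occasionally reports 4 of 5 members — the same
threshold-proximity fragility a real 6-fold cutoff has. The regression tests
pin seeds where recovery is exact.

## Problem sizes used by the tests and acceptance script

The unit and property tests run on small arrays (tens of probes, 20-40
blanks) where brute-force oracles — straight-line normalization, full
enumeration of rank assignments, full permutation of rankings — are
feasible; the recovery and census checks run one full-size cohort
(21 arrays x 1312 spots). The size of the validation test is estimated on
1000-2000 reduced null cohorts (16 probes, the 4-assay panel), since the
test's operating characteristics depend only on the group sizes. These sizes
were chosen so the whole suite documents the method at interactive speed.

## Known limitations

* The census reports one count per threshold; the source report of this
  assay family gives two inconsistent counts for the same 2-fold threshold
  (16% and 20% of 1212), and the package does not attempt to arbitrate.
* The printed ratio table it reproduces carries one rounding artifact: the
  published 11.62 for one miRNA is not recoverable from its own printed
  means, which give 11.61 at two decimals; exact arithmetic is reported.
* Per-cell clinical correlation values of the original cohort are not
  reproducible without the per-patient raw data; the package validates its
  correlation machinery by oracle equivalence, type-I simulation, and
  implanted-effect recovery instead.
* `read_expression_matrix()` expects the package's own series-matrix-style
  layout; it is not a general GEO SOFT parser.
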