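---
title: "Panel-based HRD scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel-based HRD scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
```

## The problem

Homologous recombination deficiency (HRD) leaves characteristic
copy-number "scars" in a tumor genome. Tumors that cannot repair
double-strand breaks by homologous recombination — most prominently those
with biallelic BRCA1/2 inactivation — respond better to platinum
chemotherapy and PARP inhibitors, so a quantitative HRD readout is a
treatment-selection biomarker. `hrdscar` computes the standard three-part
scar score from allele-specific segment-level copy-number profiles (the
kind produced by PureCN or similar tools from targeted-panel data with a
genome-wide SNP backbone), classifies BRCA1/2 and HRR-pathway gene status
from variant evidence, calibrates the HRD-positive threshold, and runs
the downstream cohort statistics.

The package deliberately starts *after* allele-specific copy-number
estimation: its input is one row per segment with total copy number (tCN)
and minor copy number (mCN). Purity/ploidy inference, segmentation and
variant calling are upstream and out of scope.

## The scar model

For a profile of non-overlapping segments per chromosome, with a genome
build supplying chromosome lengths and centromere intervals:

* **LOH** — the number of segments with `mCN = 0`, `tCN > 0`, length
  ≥ 15 Mb, that do not cover the whole chromosome. "Whole chromosome" is
  operationalised as covering at least 90% of the chromosome length
  (`whole_chrom_fraction`), because covered territory in real profiles
  rarely reaches literal position 1 or the final base.
* **TAI** — the number of segments with allelic imbalance
  (`mCN != tCN - mCN`) that extend to a telomeric end. A segment reaches
  the p (q) telomere iff it is the first (last) segment of its chromosome:
  telomere repeats themselves are never covered, so the terminal segment
  is the standard proxy. Centromere-spanning segments are excluded by
  default (`tai_exclude_centromere_crossing`), following the original TAI
  definition.
* **LST** — the number of copy-number breakpoints between adjacent
  segments that are each ≥ 10 Mb long, separated by ≤ 3 Mb, and differ in
  `(tCN, mCN)`. Before counting, equal-state neighbours are merged (a
  transition between identical states is not a break) and segments shorter
  than 3 Mb are iteratively smoothed away with re-merging of newly
  adjacent equal states, following the original LST definition. Breaks are
  counted within chromosome arms (`lst_per_arm`); pairs straddling the
  centromere are never counted in that mode.

The **HRD score** is the sum `LOH + TAI + LST`; a sample is HRD-positive
when the total is **≥ 38** (inclusive). All three components are
restricted to autosomes by default (`autosomes_only`): allele-specific
copy number on X/Y depends on sex and is ill-defined for males.

```{r}
build <- hg19_build()
profile <- segment_profile("demo", data.frame(
  chrom = "chr2",
  start = c(1, 30e6 + 1),
  end   = c(30e6, 243199373),
  tCN = c(1, 2), mCN = c(0, 1)), build)
hrd_score(profile)
```

(The 30 Mb deletion both qualifies as LOH and, being terminal and
imbalanced, as TAI — the components are counts of segment properties, not
disjoint event labels.)

### Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `loh_min_len_bp` | 15e6 | bp | minimum LOH segment length |
| `whole_chrom_fraction` | 0.90 | fraction | whole-chromosome exclusion for LOH |
| `lst_min_seg_bp` | 10e6 | bp | minimum flank length of an LST break |
| `lst_max_gap_bp` | 3e6 | bp | maximum inter-segment gap of a break, and the merge gap |
| `lst_smooth_bp` | 3e6 | bp | sliver-removal scale (0 disables smoothing) |
| `lst_per_arm` | TRUE | — | count breaks within arms only |
| `tai_exclude_centromere_crossing` | TRUE | — | drop centromere-spanning TAI segments |
| `tai_min_len_bp` | 0 | bp | optional TAI length floor |
| `autosomes_only` | TRUE | — | restrict scoring to autosomes |

The published pipeline description fixes 15 Mb / 10 Mb / 3 Mb; whether it
counted LST per arm and applied sliver smoothing is not stated, so both
follow the original LST reference and are exposed as flags. The "distance
not larger than 3 Mb" clause is implemented both as the inter-segment gap
test and as the smoothing scale, which is how the primary LST definition
uses it.

### Numerical and degenerate-input conventions

Coordinates are 1-based inclusive (SEG convention); the reader converts
0-based half-open input via `zero_based = TRUE` and remaps column names
via `dialect`. Unknown chromosomes, overlapping segments and `mCN >
tCN - mCN` are hard errors with row locations — silent drops would corrupt
scores. Empty profiles score 0 on all components. Scores are invariant to
input row order and to splitting any segment into abutting equal-state
pieces, because profiles are canonicalised (equal-state merge) before
counting; gaps between covered segments are allowed and treated as
uncovered territory.

## BRCA and HRR classification

A variant is **pathogenic** when its effect is nonsense or frameshift, or
its curated classification is pathogenic/likely pathogenic. Gene-level
copy-number calls use the panel log2-ratio cutoffs: ≥ +1 amplification,
≤ −1 deletion, ≤ −2 homozygous deletion (the homozygous threshold is a
package choice — the source pipeline prints only the ±1 cutoff — and is
configurable).

Per sample, BRCA1/2 status is three-way:

* **deficient** — two distinct pathogenic alleles in one gene (panel data
  carry no phase, so two distinct alterations are assumed biallelic), one
  pathogenic allele plus a deletion call in that gene, a homozygous
  deletion, or a large-rearrangement flag;
* **monoallelic_pathogenic** — pathogenic alteration present, no second
  hit;
* **intact** — no pathogenic alteration at all.

Distinct alteration identity is resolved by `allele_id`: a germline
variant re-detected in the tumor counts once. `hrr_deficiency()` applies
the same deficient logic to every non-BRCA gene of a 25-gene HRR panel;
the bundled list is provisional (clinical panels differ) and overridable.

## Threshold calibration

`sensitivity_at_cutoff()` is the fraction of BRCA-deficient samples at or
above a cutoff. Because sensitivity is non-increasing in the cutoff,
*every* cutoff below a qualifying one also qualifies; a "candidates =
everything above the floor" rule therefore always returns an interval
anchored at the bottom of the search range, which is not how the
published threshold was derived. `candidate_cutoffs()` with the default
`search_range = NULL` instead returns the **minimal qualifying
sensitivity plateau**: the cutoffs achieving the smallest sensitivity
still ≥ the floor. On score distributions with a gap (as in the source
cohort: 61/64 deficient samples at ≥ 41, one miss at 35) this plateau is
exactly the set of interchangeable thresholds, and `select_cutoff()`
picks its **lower median** — the convention forced by a six-element
candidate set 36..41 selecting 38. An explicit `search_range` restores
the literal "every qualifying integer in range" semantics.

The plateau rule is sensitive to how many deficient samples fall below
the threshold: if more than `1 - min_sensitivity` of them miss, the
plateau truncates into the miss cluster and the selected threshold drops
toward it. This is a property of the sensitivity rule itself (visible in
simulated cohorts near the 5% budget), not of the implementation.

`cox_cutoff_scan()` validates a threshold against outcome data: for each
integer cutoff (default 35..45) it fits a univariate Cox model of PFS on
`score >= cutoff` with Efron tie handling (day-granularity PFS has ties)
and reports the full hazard-ratio table plus the smallest-p cutoff. Ties
in p across cutoffs (which occur whenever no sample scores inside the
scanned window) resolve to the smallest cutoff.

## Cohort statistics

Group score comparisons use the two-sided Wilcoxon rank-sum test with
medians; survival uses Kaplan-Meier medians (reported `NA` when a curve
never crosses 0.5) with the log-rank test, and multivariable Cox models
with reference levels HRD-negative / stage III / R0. Concurrent-alteration
enrichment uses the two-sided Fisher exact test per alteration column
(mutation, copy loss and amplification of a gene are distinct columns),
filtered to overall frequency > 5%, with raw p ≤ 0.05 by default —
matching the original analyses, which report unadjusted p; a
Benjamini-Hochberg option exists but is off by default. Cross-method
agreement is Pearson correlation for scores and unweighted Cohen's kappa
for binary calls.

## What the simulator emulates — and what it does not

`simulate_profile()` starts from a balanced diploid genome (one 2/1
segment per autosome) and plants exactly `n_loh_events` interstitial
15-20 Mb 1/0 segments, `n_tai_events` terminal 5-14 Mb imbalanced
segments (3/1 or 2/0, never centromere-spanning, at most one per
chromosome end), and `n_lst_breaks` breakpoints as runs of adjacent
10 Mb alternating-state segments within single arms. Events are packed
best-fit-decreasing into arm interiors with isolation gaps larger than
the 3 Mb LST bound, so planted events cannot interact: with zero noise
**every component score equals its planted count exactly**, which is what
the recovery tests assert. Noise events are sub-threshold by
construction — LOH below 15 Mb, interior allelic imbalance, transition
pairs with sub-10 Mb flanks — and provably never change a score.

`simulate_cohort()` layers study-level structure on top: BRCA status
(deficient / monoallelic / intact), an HRD-high phenotype drawn with
probability 0.95 for deficient samples and 0.37 otherwise, planted totals
at least 10 points above (high) or below (low) the threshold 38 so truth
is unambiguous, exponential PFS with a 343-day HRD-negative median and a
multiplicative hazard ratio (default 0.47) for HRD-positive samples,
independent uniform censoring calibrated to a target censoring fraction,
a platinum-sensitivity Bernoulli link (0.82 positive / 0.63 negative),
BRCA and HRR variant/copy-number evidence consistent with the assigned
status, and an alteration matrix with planted enrichments (a TP53-like
alteration at 98.3% vs 81.5%, an amplification exclusive to positives,
one alteration enriched in negatives, and neutral columns). Deficient
samples that miss the threshold are modelled as near-misses just below
the low margin, mirroring the observed discontinuity in real cohorts.
Exponential survival keeps closed-form medians available as test oracles.

Deliberately **not** modelled: purity/ploidy estimation error, subclonal
copy number, noisy tCN/mCN calls, segmentation artifacts, correlated
scars, and non-proportional hazards. Passing tests therefore demonstrate
correctness of the counting rules, the calibration logic and the
statistical wiring — not robustness to upstream estimation noise.

Problem sizes used by the test-suite studies: 200 random profiles per
scar-score oracle comparison, 500 parameter draws for planted-truth
recovery (the last 100 with noise), a 500-sample cohort for hazard-ratio
recovery and 200 replicates of 100 samples for null calibration of the
log-rank p — sizes at which the checks are sharp while the suite stays
fast.

## Known limitations

* The first/last-segment proxy for "reaches the telomere" makes TAI
  sensitive to how much terminal territory the upstream segmentation
  covers; profiles truncated far from the telomeres will overcount
  interior imbalance as telomeric.
* The bundled HRR gene list is provisional; supply the assay's own list
  for real analyses.
* `hrd_cli()`'s provenance header records the resolved options and seed,
  but reproducibility across package versions is only guaranteed for
  identical versions (the simulator's RNG stream is an implementation
  detail).
* The threshold-selection plateau behaves discontinuously near the
  sensitivity budget, as discussed above.
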