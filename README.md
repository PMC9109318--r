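# hrdscar

Panel-based **homologous recombination deficiency (HRD)** scoring and
cohort analysis in R.

Tumors that cannot repair DNA double-strand breaks by homologous
recombination — classically those with biallelic *BRCA1/2* inactivation —
accumulate quantifiable copy-number "scars" and respond better to platinum
chemotherapy and PARP inhibitors. `hrdscar` turns allele-specific
segment-level copy-number profiles (one row per segment with total copy
number *tCN* and minor copy number *mCN*, as produced by PureCN-style
pipelines from targeted panels with a genome-wide SNP backbone) into the
standard three-component scar score and runs the downstream biomarker
analyses. It is aimed at bioinformaticians evaluating HRD assays and at
methodologists who need a fully simulatable test bed for HRD pipelines.

## The score

For a segment profile with a genome build (chromosome lengths +
centromere intervals; hg19 bundled):

* **LOH** — count of segments with mCN = 0, tCN > 0, length ≥ 15 Mb, not
  covering the whole chromosome;
* **TAI** — count of allelically imbalanced segments (mCN ≠ tCN − mCN)
  extending to a telomeric end, excluding centromere-spanning segments;
* **LST** — count of breakpoints between adjacent ≥ 10 Mb segments
  ≤ 3 Mb apart that differ in (tCN, mCN), after equal-state merging and
  3 Mb sliver smoothing, counted within chromosome arms;

**HRD score = LOH + TAI + LST**, HRD-positive iff the total ≥ 38
(threshold calibrated so that ≥ 95% of BRCA-deficient samples test
positive, taking the lower median of the interchangeable candidate
cutoffs).

Alongside scoring, the package classifies per-sample BRCA1/2 status
(deficient / intact / monoallelic pathogenic) and HRR-pathway gene
deficiency from variant and gene-level copy-number evidence, calibrates
the threshold (sensitivity plateau + Cox cutoff scan over 35–45), and
provides the cohort statistics: Wilcoxon score comparisons, Kaplan–Meier /
log-rank PFS, multivariable Cox, Fisher enrichment of concurrent
alterations, and Pearson / Cohen's-kappa concordance. A seeded simulator
generates profiles with *planted* scar counts and cohorts with an
HRD-linked proportional-hazards survival signal, so every stage is
testable without patient data.

## Worked example

Simulate an 85-sample platinum-treated ovarian cohort, score its segment
profiles, and run the survival and enrichment analyses:

```r
library(hrdscar)
build <- hg19_build()
sim <- simulate_cohort(cohort_params(n_samples = 85, seed = 2026), build)

scores <- hrd_score_table(sim$profiles)
head(scores, 4)
#>   sample loh tai lst hrd_score hrd_status
#> 1   S001  12   5  10        27   negative
#> 2   S002   9  11   8        28   negative
#> 3   S003   9   8  11        28   negative
#> 4   S004  35  16  22        73   positive

co <- sim$cohort
co$hrd_positive <- scores$hrd_score[match(co$sample_id, scores$sample)] >= 38

km <- km_logrank(co, "hrd_positive")
km$medians; km$p_value
#> FALSE  TRUE
#>   446   829
#> [1] 0.003156648

fit <- cox_multivariate(co)   # covariates: HRD status, stage, residual tumor
subset(fit, term == "hrd_positivepositive")
#>                   term hazard_ratio    ci_low   ci_high     p_value
#> 1 hrd_positivepositive    0.4684495 0.2738522 0.8013263 0.005629815

enrichment_scan(sim$alterations, co$hrd_positive)[, c(1, 4:6)]
#>           alteration   freq_pos  freq_neg      p_value
#> 1 PTK2_amplification 0.31372549 0.0000000 0.0001149707
#> 2    ARID1A_mutation 0.07843137 0.4117647 0.0003459190
#> 3      KRAS_mutation 0.07843137 0.3235294 0.0073014012
#> 4      TP53_mutation 0.98039216 0.8235294 0.0149862253
#> 5    NCOR1_copy_loss 0.31372549 0.1176471 0.0410246902
```

Reading: the scored table reproduces each sample's planted scar counts;
HRD-positive patients progress later (median PFS 829 vs 446 days,
log-rank p = 0.003) with a multivariate hazard ratio of 0.47 — the
generative value — while stage and residual tumor, simulated independently
of outcome, stay near HR 1. The enrichment scan recovers the planted
alteration structure, including the amplification exclusive to
HRD-positive samples.

The same pipeline is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/hrdscar.R", package = "hrdscar"))')
Rscript "$CLI" simulate --n-samples 85 --seed 2026 -o simdir
Rscript "$CLI" score --segments simdir/segments.tsv -o scores.tsv
Rscript "$CLI" cox-scan --scores scores.tsv --clinical simdir/clinical.tsv -o scan.tsv
```

Every output table starts with comment lines recording the package
version, a hash of the resolved options, and the seed.

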