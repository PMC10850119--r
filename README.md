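# methpanel

Discovery and evaluation of cancer-specific DNA methylation biomarker
panels from probe-level beta-value matrices.

## The problem

Adenocarcinomas and their liver metastases can be hard to tell apart by
histology, and in carcinoma of unknown primary the tissue of origin must be
read off the tumor itself. CpG hypermethylation is a good substrate for
this: it appears early in tumorigenesis, is conserved from primary tumor to
metastasis, and is detectable in cell-free DNA (cfDNA) from plasma.
`methpanel` is for bioinformaticians who want to mine array-style
methylomes (beta values β ∈ [0, 1] per CpG probe) for small panels of
probes that are hypermethylated in one cancer type and unmethylated
everywhere else, and then to quantify how well those panels diagnose and
differentiate.

## What it does

For sample groups *g* (a cancer's tumors, its adjacent normals, or a
methylation cluster MC within a cancer), the pipeline:

1. filters probes (sex chromosomes, any missing value, duplicated ids) and
   excludes FFPE samples;
2. optionally clusters each cancer's tumors with a recursively partitioned
   beta-mixture model on the 5000 most variable probes (fanny fuzzy
   initialization, method-of-moments EM for per-probe beta shapes, a
   level-weighted BIC split decision), labelling clusters MC1 (most
   methylated) … MCn;
3. tests every probe in every group pair: delta = mean β(g1) − mean β(g2),
   two-sided Wilcoxon rank-sum p, Benjamini–Hochberg adjustment;
   significant ⇔ |delta| ≥ 0.2 and adjusted p ≤ 0.05;
4. intersects the significant hypermethylated probes across all
   cancer-vs-cancer comparisons and keeps those with, for every comparator,
   delta > 0.3 and comparator mean < 0.1 (strict tier; a relaxed 0.2 / 0.15
   tier backstops cancers with few strict hits), then annotates each
   candidate by its paired-normal behaviour;
5. greedily assembles a per-cancer panel (fewest probes, highest
   sensitivity under specificity constraints) and evaluates it with the
   max-beta call rule — a sample is positive iff max β over the panel
   probes exceeds 0.3 — reporting sensitivity, cancer specificity,
   tumor-samples specificity, all-samples specificity and diagnostic
   accuracy, on identification and verification cohorts, on metastases and
   on cfDNA.

A synthetic multi-project cohort generator with planted ground truth
(methylation subtypes, marker probes, tumor-and-normal shared probes,
metastases, tumor/leukocyte cfDNA mixtures) makes the whole pipeline
testable without external data.

## Worked example

```r
library(methpanel)

cfg <- cohort_config(projects = default_projects()[c(1, 4, 6), ],  # BRCA, LIHC, PAAD
                     n_background_probes = 400L, n_cluster_probes = 60L,
                     seed = 7L)
cohort <- simulate_cohort(cfg)
run <- run_nonclustered(cohort$beta, cohort$sheet, cohort$annotation,
                        pipeline_config(seed = 7L))
run
#> <meth_run> non-clustered approach: 15 comparisons, 3 cancers with panels
#> # A tibble: 3 × 7
#>   target n_probes sensitivity cancer_specificity ts_specificity
#>   <chr>     <int>       <dbl>              <dbl>          <dbl>
#> 1 BRCA          1         100                100            100
#> 2 LIHC          1         100                100            100
#> 3 PAAD          1         100                100            100
#> # ℹ 2 more variables: all_samples_specificity <dbl>, accuracy <dbl>

run$panels$LIHC
#> <meth_panel> LIHC (non-clustered approach), cutoff 0.30
#>   1 probes: symklihc00032
```

Each row is one cancer's panel evaluated on the identification cohort: the
panel's probes, the fraction of that cancer's tumors called hypermethylated
(sensitivity), and how often everything else stays negative (the three
specificities and the accuracy). On this small synthetic cohort a single
planted marker per cancer suffices, so every panel is one probe with
perfect separation; `tidy(run)` lists the full candidate table and
`autoplot(run$evaluations$LIHC)` draws the max-beta boxplots.

The count-to-statistic step is exposed directly and reproduces published
confusion-table rows exactly, e.g. a 6-probe liver-cancer panel called on
2853 samples:

```r
metrics_from_counts(list(
  target_pos = 344, target_n = 377, paired_normal_neg = 50,
  paired_normal_n = 50, other_ts_neg = 2116, other_ts_n = 2232,
  other_all_neg = 2357, other_all_n = 2476, total_n = 2853))[, 10:14]
#>   sensitivity cancer_specificity ts_specificity all_samples_specificity accuracy
#> 1        91.2                100           94.8                    95.2     94.7
```

That is: 91.2% of the target tumors are detected, all 50 paired normals
stay negative, 94.8% of other tumors and 95.2% of all other samples stay
negative, for 94.7% diagnostic accuracy.

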