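---
title: "Methods: methylation biomarker panel discovery with methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation biomarker panel discovery with methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adenocarcinomas that metastasize to the liver — colorectal, pancreatic,
breast, lung and stomach cancers, next to the primary liver tumors
(hepatocellular carcinoma and cholangiocarcinoma) — can be difficult to tell
apart by histology, and in carcinoma of unknown primary the tissue of origin
must be inferred from the tumor itself. CpG hypermethylation is an
attractive basis for such differentiation: it arises early in tumorigenesis,
is largely conserved from primary tumor to metastasis, and is measurable in
tissue and in cell-free DNA (cfDNA) from plasma.

`methpanel` implements a complete discovery-and-evaluation workflow on
array-style beta values (per-CpG methylation fractions in [0, 1]):

1. **Data preparation** — probe filtering (sex chromosomes, missing data,
   duplicated probe ids), FFPE sample exclusion, project pooling
   (e.g. colon + rectum as colorectal cancer).
2. **Optional subtype discovery** — recursively partitioned beta-mixture
   clustering of each cancer's tumor samples into methylation clusters
   (MCs), labelled MC1 (most methylated) downwards.
3. **Differential methylation** — all pairwise group comparisons with
   per-probe mean differences, Wilcoxon rank-sum p-values and
   Benjamini–Hochberg adjustment.
4. **Candidate selection** — intersection of significant hypermethylated
   probes across all cancer-vs-cancer comparisons, then strict/relaxed
   effect-size cutoffs and verification in normal tissue.
5. **Panel design and evaluation** — greedy assembly of a small probe panel
   per cancer, max-beta calling at a 0.3 cutoff, and five summary
   statistics on identification and independent verification cohorts,
   metastases, and cfDNA.

Because the original cohorts (thousands of TCGA/GEO methylomes) cannot be
bundled, the package ships a synthetic cohort generator with planted ground
truth; every stage is tested against that truth.

## Sample groups and statistics

For a panel targeting cancer *T* with call rule
`max(beta over panel probes) > 0.3` (strictly greater; 0.3 itself is
negative), the five statistics are

* **sensitivity** — fraction of *T* tumor samples called positive;
* **cancer specificity** — fraction of *T*'s adjacent-normal samples called
  negative;
* **tumor-samples specificity** — fraction of all non-*T* tumor samples
  called negative;
* **all-samples specificity** — fraction of all non-*T* samples (tumors and
  normals, including *T*'s normals) called negative;
* **diagnostic accuracy** — (target positives + non-target negatives) /
  all samples.

All percentages are rounded half-up to one decimal (`round()`'s banker's
rounding would disagree on exact halves). The metastasis variant replaces
the paired-normal block with the other cancers' metastases and counts all
primaries plus other metastases in the tumor-samples block.

`metrics_from_counts()` exposes the count-to-statistic step directly. The
package bundles 31 confusion-count rows transcribed from published panel
evaluations of this design (`panel_count_examples()`); the test suite
recomputes every percentage from the counts. Sixteen of the 155 printed
cells are arithmetically inconsistent with their own printed counts (no
rounding convention reproduces them — mostly small denominator slips in the
source tables); these are excluded by an explicit list in
`tests/testthat/test-acceptance.R` and the remaining 139 reproduce exactly.

## The beta-mixture clustering model

Tumor methylomes within one cancer type form methylation subtypes. The
clustering model treats each sample's betas over the `k` most variable
probes (default `k = 5000`, clamped to the probe universe; variance computed
within the tumor group, ties broken by probe id) as independent beta
variables within a class:

* **Initialization** — fanny fuzzy clustering (Euclidean distance,
  fuzzifier 2), with a deterministic median-split fallback when fanny fails
  or returns uniform memberships.
* **EM fit** (`fit_beta_node()`) — two-class mixture; the M-step estimates
  each probe's shape pair by weighted method of moments,
  `a = mu (mu(1-mu)/v - 1)`, `b = (1-mu)(mu(1-mu)/v - 1)`, with the
  weighted variance floored at `1e-6` and capped below `mu(1-mu)` so shapes
  stay positive; the E-step recomputes responsibilities from joint beta
  log-densities. Betas are clamped to `[1e-4, 1-1e-4]` before density
  evaluation because the beta log-density diverges at the boundary.
  Method-of-moments M-steps are a standard, stable approximation to maximum
  likelihood but are not an exact ascent step: the log-likelihood trace can
  decrease by ~1e-2 on traces of magnitude ~1e3, so the monotonicity test
  allows a 0.05 absolute tolerance.
* **Split decision** (`level_weighted_bic()`) — `BIC = -2 logL + p log(n)`
  with `p` = two shape parameters per probe per class, plus one mixing
  weight for the split. The level weight `2^(-depth)` attaches to the node
  being split; since both the one-class and two-class alternatives are
  scored at that node, the weight scales both sides equally and each local
  decision reduces to a plain BIC comparison. (The weighting convention is
  isolated in one function so a different reading can be swapped in.) A
  split is also rejected when either child would have fewer than
  `min_cluster_size = 5` samples.
* **Recursion** — binary splits to `max_depth = 3` (at most 8 leaves,
  matching the 4–7 subtypes typically reported per cancer). Leaves are
  relabelled by mean beta over the clustering probes: MC1 = most
  methylated; ties break by leaf size, then original leaf index. Normal
  samples are never clustered.

A practical note on `k`: 5000 probes against a 450k-probe array is ~1% of
the universe and is strongly enriched for informative probes. On a small
synthetic universe (a few thousand probes) `k = 5000` clamps to *all*
probes, and the BIC penalty of the uninformative majority (two parameters
per probe per class) can mask real splits at small n. The clustered-pipeline
tests therefore pass `k` proportional to the synthetic universe (~300 of a
~1,400-probe universe), the same ratio choice an analyst makes on a real
array. Relatedly, recovering subtypes is inherently n-limited: with 40
tumors per project the split penalty `(2p+1) log n` exceeds the attainable
likelihood gain for the deeper splits, so subtype-recovery tests use
projects with 120–200 tumors.

## Differential methylation and selection

`dmr_compare()` computes, per probe, the two group means, their difference
(delta), a two-sided Wilcoxon rank-sum p-value and its BH adjustment across
all probes of that comparison (the adjustment family is one pairwise
comparison, not the pooled set of comparisons). A probe is significant iff
`|delta| >= 0.2` **and** adjusted p `<= 0.05`. The p-value policy: the exact
enumeration distribution when both groups have at most 12 observations and
no ties are present, otherwise the normal approximation with tie and
continuity correction; an all-tied comparison is defined as p = 1. The
vectorized per-probe path implements the identical formulas as
`stats::wilcox.test` and is tested for exact agreement against it and
against a brute-force enumeration oracle.

The comparison plan: in the **non-clustered** approach each project's tumor
samples and each project's normal samples are independent groups and all
unordered pairs are compared; in the **clustered** approach every MC is a
group and all pairs are compared *except* MCs of the same cancer. Each
unordered pair is computed once and reused in both directions (the p-value
is symmetric; delta changes sign).

Selection per target group: probes significant **with positive delta** in
*every* comparison against the other cancers' groups are intersected, then
tiered —

* **strict**: for every comparator, delta `> 0.3` and comparator mean
  `< 0.1`;
* **relaxed** (used when a cancer yields fewer than 3 strict candidates):
  delta `> 0.2` and comparator mean `< 0.15`. Both conditions are required
  by default; `relaxed_mode = "or"` switches to the disjunctive reading.

Candidates are then **verified in normal tissue**: annotated
`normal_discriminating` when the paired-normal mean beta is below the 0.3
call cutoff, else `shared_with_normal` — the pancreatic-cancer-like case
where a probe is hypermethylated in the tumor *and* its tissue of origin.
No candidate is removed at this step; a panel built solely from
`shared_with_normal` probes is allowed and its cancer specificity is
reported rather than enforced. In the clustered approach a cancer's
candidates are merged across its MCs, recording `n_target_mcs`, the number
of that cancer's clusters in which the probe was selected; probes found in
many clusters are preferred by the panel builder because they detect more
of the cancer's samples.

## Panel construction

`build_panel()` is a greedy forward selection over the candidate ranking
(`n_target_mcs` descending, target mean descending, probe id): at each step
it adds the feasible candidate that maximizes sensitivity on the
identification scope, where feasible means cancer specificity stays at or
above `min_cancer_specificity = 90` (waived when the pool is entirely
`shared_with_normal`) and the all-samples specificity does not fall more
than `spec_slack = 2` points below the current panel's value (the empty
panel imposes no slack constraint). Growth stops when the best addition
newly detects fewer than `min_gain = 1` target samples, and the result is
trimmed to the smallest prefix achieving the final sensitivity — the
"fewest probes, highest sensitivity and specificity" preference. An
exhaustive mode enumerates all subsets for pools of at most 12 candidates;
on candidate-like pools the greedy result matches it, and the test suite
asserts it stays within 5 sensitivity points under identical constraints.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws every value from a beta distribution
parameterized by mean and concentration `phi` (shape pair
`(mu*phi, (1-mu)*phi)`); `phi = 30` gives a within-group standard deviation
near 0.08, comparable to the spread of per-probe beta distributions in
tumor cohorts. The probe universe contains:

* **marker probes** per cancer — mean 0.70 in the target tumors (optionally
  only in configured subtypes), 0.05 everywhere else (delta 0.65);
* **shared probes** — additionally at 0.70 in the target cancer's normals
  (the tumor-and-tissue-of-origin case);
* **cluster-informative probes** per project — tumor mean equal to the
  subtype's level, evenly spaced 0.25–0.65 with ±0.03 per-probe jitter, and
  0.1 elsewhere, making subtypes separable and orderable by mean
  methylation;
* **background probes** — bimodal means (modes near 0.1 and 0.8, the
  genome-wide bimodality of CpG methylation), identical across all sample
  groups, so variance-based probe selection has something to discard;
* sex-chromosome probes, duplicated probe ids and sporadic missing values,
  exercising the filtering rules.

The probe model is derived from the config seed alone, so identification
and verification cohorts share planted truth while their samples are
independent draws. Metastases copy a source tumor column, perturb each
probe's mean by ±0.05 (uniform) and redraw — the conservation of
cancer-associated hypermethylation from primary to metastasis. cfDNA
columns mix a tumor profile (the project's mean tumor methylome) with a
leukocyte-like background (markers unmethylated at 0.05, background probes
at their bimodal means) at tumor fraction `f` and redraw.

The generator does **not** emulate copy-number or purity variation,
array-chemistry artefacts (type I/II probe bias), batch effects,
cell-composition heterogeneity in normals, or read-level cfDNA sampling.
Passing tests on this cohort therefore demonstrate that the pipeline's
logic is correct and self-consistent — not that the discovered probes or
printed sensitivities would transfer to real arrays.

Default desk-scale roster: seven cancers, 40 tumors + 10 normals each, 4–7
subtypes, 50 markers per cancer, 10 shared probes for the
pancreatic-like project, 2,000 background probes. A full non-clustered run
on this roster takes ~15 s on one core; the whole test suite, including two
roster runs, subtype recovery at n = 200 and an exhaustive-search
comparison, runs in about a minute.

## Numerical choices and edge cases

* Beta values are validated into [0, 1] at read time with errors naming the
  probe and sample; readers never coerce silently.
* Probe filtering drops a probe if it has *any* missing value anywhere in
  the loaded matrix (the strictest reading of "probes with missing data
  were removed"), and drops *all* copies of a duplicated probe id, since
  there is no principled way to prefer one measurement.
* A sample whose max panel beta is exactly 0.3 is called negative.
* Zero denominators yield `NA` statistics ("not applicable"), never 0 or
  Inf.
* Degenerate EM classes (effective size below `min_cluster_size`) return a
  collapse flag and the split is rejected; they do not raise.
* All randomness flows through explicit integer seeds; repeated runs are
  byte-identical, and the run manifest stores the configuration and input
  hashes so a result can be traced to its inputs.

## Limitations

* The level-weighting formula of the split criterion is not uniquely
  determined by its name; the package's reading (weight attached to the
  node under consideration, hence locally a plain BIC test) is isolated in
  `level_weighted_bic()` for replacement.
* Method-of-moments beta estimation is an approximation to maximum
  likelihood; it is stable and closed-form but slightly less efficient.
* The greedy panel builder formalizes a preference ordering the original
  design states informally; different constraint settings can produce
  different (equally defensible) panels.
* Per-probe analysis only: no merging of adjacent CpGs into regions, no
  covariate adjustment, no cell-composition correction, no tumor-fraction
  estimation from cfDNA.
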