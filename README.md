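# zftfscreen

Combinatorial zinc-finger transcription-factor (ZF-TF) libraries are a
functional-genomics tool for *inducing* phenotypes rather than observing
them: modular ~30-aa zinc-finger domains, each recognising a ~3-bp DNA
"subsite", are mixed and matched into multi-finger arrays fused to a
transcriptional activation domain, and the resulting library — `m^L` members
for `m` catalogued fingers and `L` positions — is screened for members that
confer a phenotype such as anti-endocrine drug resistance in breast cancer
cells.  `zftfscreen` implements, as a tested R package, both sides of such a
study's computational work:

* **Library design** — finger-catalog parsing and validation, streaming
  enumeration of the `25^4 = 390,625`-member four-finger library, degenerate
  (IUPAC) target-site prediction for any array, exact site scanning of FASTA
  sequences with BED output, and clone deduplication.
* **Resistance-signature analysis** — the expression pipeline that turns
  array intensities from screen-derived cell lines into a shared resistance
  signature and a prognostic test:
  trimmed-mean scaling (2% trimmed mean of every sample set to 100) →
  per-gene mean-shift batch correction → top-2,500-SD variance filter →
  Tukey median polish → row standardisation → average-linkage clustering
  with distance `1 − r` → direction-labelled module extraction (including
  the "common-down" cluster: genes down-regulated in *every* ZF-TF
  condition) → hypergeometric over-representation tests with one Holm
  family per cluster → metagene scoring, median-split stratification,
  Kaplan–Meier curves and a one-sided log-rank test of the pre-specified
  hypothesis that the resistant-metagene stratum fares worse.
* **Synthetic data with ground truth** — a generator for expression
  experiments with planted direction-coherent gene modules and batch
  effects, gene-set databases with known-enriched and decoy sets, and
  survival cohorts whose hazard tracks a planted signature metagene; every
  pipeline stage is validated against this ground truth and against
  independent brute-force oracles.

The statistical core in one line each: enrichment p-values are upper
hypergeometric tails `P(X ≥ k)` for an `n`-gene cluster overlapping an
`S`-gene set by `k` in an `N`-gene universe, Holm-adjusted per cluster; the
survival test is the standard log-rank `z = (O_w − E_w)/√V` with the
one-sided p-value `P(Z ≥ z)` for the hypothesised-worse stratum (patients
below the median metagene, the 72-gene signature being down-regulated in
resistance).

## Worked example

```r
library(zftfscreen)

## library combinatorics and site prediction
cat25 <- load_catalog()                       # packaged 25-finger catalog
enumerate_library(cat25, 4)
#> Combinatorial ZF-TF library: 25 fingers ^ 4 positions = 390,625 arrays
clone7 <- load_resistance_clones(cat25)[["7"]]
predict_sites(clone7)
#> Predicted sites for array '7' (F1-3prime): 12 bp
#>   degenerate site(s): RTCNGGVGAGCW | RTCNGGGAAGCW
#>   64 distinct concrete sites

## synthetic resistance screen: control + six ZF-TF conditions,
## two infections in four batches, five planted modules
preset <- resistance_screen_preset()
sim <- generate_expression_experiment(preset$design, preset$modules, seed = 1)
pm  <- preprocess_pipeline(sim$experiment)    # scale, batch-correct, filter,
                                              # median polish, row-scale
hc  <- average_linkage_cluster(correlation_distance_matrix(pm))
res <- cut_and_label(hc, pm)
res
#> Cluster result: 2500 genes in 1178 clusters (5 labelled)
#>  cluster size                           tag
#>        1  231       shared-up:ZF7+ZF19+ZF70
#>        2  225                         mixed
#>        3  134                         mixed
#>        5  126 shared-up:ZF7+ZF64+ZF83+ZF115
#>        6   73                   common-down

## the common-down cluster is the shared resistance signature
signature <- cluster_genes(res, "common-down")
db  <- generate_gene_set_db(sim$truth, n_decoy_sets = 50, seed = 2)
tab <- run_enrichment(signature, db, rownames(pm$matrix),
                      cluster_id = "common-down")
head(tab[, c("set", "N", "S", "n", "k", "p_raw", "p_holm")], 3)
#>         set    N  S  n  k        p_raw       p_holm
#> 1   true_m5 2500 72 73 58 1.517662e-89 8.347144e-88
#> 2 decoy_016 2500 42 73  4 3.242611e-02 1.000000e+00
#> 3 decoy_017 2500 54 73  4 7.067267e-02 1.000000e+00

## prognostic value of the signature metagene in a survival cohort
coh <- generate_survival_cohort(300, signature, hazard_ratio = 3, seed = 3)
run_prognosis(coh$matrix, coh$clinical, signature)
#> Prognosis (endpoint: generic, 73 signature genes)
#> fulvestrant-resistant fulvestrant-sensitive
#>                   150                   150
#> One-sided log-rank ('fulvestrant-resistant' hypothesised worse)
#>   z = 7.1186, one-sided p = 5.451e-13, two-sided p = 1.09e-12
#>                         n observed  expected
#> fulvestrant-resistant 150      117  70.74482
#> fulvestrant-sensitive 150       86 132.25518
```

Reading the output: the labelled clusters recover the five planted modules —
one up-module shared by ZF-TF 7/19/70, single-condition modules (partially
relabelled "mixed" because the mean-shift batch correction leaks a fraction
of a one-condition effect into conditions profiled in the same batch — see
the vignette), and exactly one 73-gene **common-down** cluster matching the
planted 72-gene signature.  That cluster's enrichment table puts the planted
set first at Holm-adjusted `p ≈ 8e-88` while all decoys stay at 1, and in a
hazard-ratio-3 cohort the low-metagene ("fulvestrant-resistant") stratum
shows far more events than expected (117 vs 70.7; one-sided `p ≈ 5e-13`).

A thin command-line wrapper over the same functions ships in
`inst/scripts/zftf.R` (`simulate`, `preprocess`, `cluster`, `enrich`,
`prognose`, `enumerate`, `predict`, `scan`).

The methods vignette (`vignettes/zftf-pipeline.Rmd`) documents the models,
parameter defaults and their rationale, numerical conventions, and what the
synthetic benchmark does and does not demonstrate.

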