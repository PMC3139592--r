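---
title: "From a combinatorial zinc-finger library to a resistance signature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a combinatorial zinc-finger library to a resistance signature: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zftfscreen)
```

`zftfscreen` models the computational side of a combinatorial zinc-finger
transcription-factor (ZF-TF) resistance screen: the library combinatorics and
target-site prediction up front, and, downstream of the screen, the
expression-profiling pipeline that extracts a shared drug-resistance gene
signature and evaluates its prognostic value in survival cohorts.  This
vignette explains the models and conventions the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## 1. The combinatorial library model

Individual zinc-finger domains bind roughly 3 bp of DNA.  Linking `L` fingers
in series yields a protein that recognises a composite `3L`-bp site, and a
catalog of `m` characterised fingers therefore spans an `m^L`-member
combinatorial library.  The packaged catalog has 25 fingers, so the default
four-finger library has `25^4 = 390,625` members:

```{r}
cat25 <- load_catalog()
lib <- enumerate_library(cat25, 4)
lib
```

Enumeration is streaming: the size is computed arithmetically and arrays are
materialised one at a time (`lib$next_array()`), so the full library never
needs to reside in memory.

**Orientation convention.** Zinc-finger arrays bind DNA antiparallel to the
protein chain, so by default finger F1 contacts the *3'-most* triplet and the
predicted site read 5'→3' is `subsite(FL)…subsite(F1)`.  Because a site is a
double-stranded entity, the only meaningful alternative is reporting it from
the other strand; `predict_sites(..., orientation = "F1-5prime")` does exactly
that and yields the reverse complement of the default site set.  Every output
records the convention used.

**Degeneracy.** Subsites are IUPAC triplets (standard map; N = ACGT, V = ACG,
…).  Fingers with alternative subsites (e.g. LZF23: VGA or GAA) contribute one
degenerate site per subsite combination; concrete sites are produced by IUPAC
expansion and de-duplicated.  Clone 83 (NGG, NNN, AAG, VGA|GAA) expands to
`4 x 64 x 1 x 4 = 1,024` distinct 12-mers, which is why a single ZF-TF can
plausibly perturb dozens to hundreds of genes — a 12-bp degenerate family has
many chance occurrences in a genome.  `scan_sequence()` reports exact
occurrences (0-based, half-open, both strands; `N` in the subject never
matches) and writes BED.

## 2. Expression preprocessing

The pipeline starts from a linear-scale (non-log) gene-by-sample intensity
matrix, as produced by probe-level summarisation, plus a sample sheet
(condition, replicate, batch).  The stages, in order:

1. **Trimmed-mean scaling** — each sample is rescaled so its 2% trimmed mean
   equals 100.  "2% trimmed" is interpreted as 1% of values removed from each
   tail, `floor(n * 0.01)` values per tail; both the fraction and the target
   are arguments.
2. **Batch correction** — per gene, every batch other than the first is
   shifted by (mean in first batch − mean in that batch).  This equalises
   per-gene batch means exactly and leaves within-batch contrasts untouched.
   The "first" batch is the batch of the first sample in the sample sheet.
3. **Variance filter** — the 2,500 rows with the largest sample standard
   deviation are retained (`k` configurable); ties at the boundary break by
   row-id lexicographic order so the result is platform-independent.
4. **Median polish** — Tukey's alternating row/column median sweeps
   (`stats::medpolish`), run until the sum of absolute residuals changes by
   less than `tol = 1e-6` (relative) or 20 iterations; the matrix is replaced
   by the residuals and the effects are kept.
5. **Row scaling** — each row to mean 0 and standard deviation 1 with the
   population (divide-by-n) convention.  Constant rows are an error by
   default, or dropped with a warning.

Two conventions deserve comment.  The stages run on *linear-scale* values in
exactly this order, with no log transform; an optional `log2` flag exists but
defaults off, because the published order of operations never inserts one.
And the variance filter uses the *sample* SD (divide by n−1); the row scaling
uses the *population* SD — the latter choice is recorded in the transform log,
and neither affects which rows are selected beyond ties.

Every stage appends its name and parameters to a `transform_log`, and
`replay_transforms()` re-executes a log bit-identically — the pipeline's
reproducibility contract, enforced in the test suite.

**A caveat the pipeline inherits from its method.**  When conditions are not
balanced across batches, the per-gene mean-shift correction removes part of a
real condition effect along with the batch effect: a gene up-regulated in one
condition only will, after correction, appear slightly *down* in the other
conditions sharing its batch.  With two replicate infections spread over four
batches this confounding is unavoidable; it attenuates single-condition
effects but cannot erase a module that moves in *every* treatment condition,
which is the pattern the analysis ultimately relies on.

## 3. Clustering and direction-labelled modules

Genes are clustered with average-linkage (UPGMA) agglomerative clustering on
the distance `1 − Pearson correlation` (range 0–2).  The package delegates
the linkage to `stats::hclust(method = "average")` and verifies it in the
test suite against a naive cubic re-averaging implementation.

The published analysis identified gene modules as visually boxed regions of
the clustered heatmap.  The package formalises this with two parameters:

* **Cut rule** — by default the dendrogram is cut at height 0.16, i.e. a
  cluster's genes correlate at about 0.84 or better on average; this default
  was calibrated on the synthetic benchmark (below) so that planted
  modules of the study's scale are recovered as single clusters, and it can
  be replaced by an explicit `n_clusters` or any other `height`.
* **Direction calls** — for each cluster of at least `min_size = 20` genes,
  the mean scaled expression per treatment condition minus the control mean
  is thresholded at `tau = 0.5` scaled units: above is "up", below −`tau` is
  "down", otherwise "none".  A cluster down in every treatment condition is
  tagged `common-down` — the shared resistance signature; single- and
  multi-condition up-patterns get `unique-up:<cond>` and `shared-up:<…>`
  tags.  Clusters smaller than `min_size` are tagged `small` and not called,
  which keeps singleton noise genes from masquerading as modules.

`project_external()` reproduces the external-cohort comparison: the external
matrix is restricted to the reference gene panel, *independently* median
polished and row scaled, and reordered to the reference dendrogram's leaf
order (missing genes stay as masked rows).  Per labelled cluster it reports a
direction-agreement score: the fraction of cluster genes whose
treated-minus-control contrast in the external data matches the cluster's
reference direction.  Self-projection gives 1; unrelated data gives about
0.5.

## 4. Hypergeometric enrichment with Holm control

For a cluster of `n` genes tested against a database set that has `S` members
inside the universe of `N` assayable genes, with `k` shared genes, the raw
p-value is the upper hypergeometric tail `P(X ≥ k)` (over-representation
only, computed by `stats::phyper` in a numerically stable way).  Within each
cluster, the p-values of all sets tested form one Holm family
(`stats::p.adjust(method = "holm")`) — one family *per cluster*, matching the
published procedure.  Sets are intersected with the universe before `S` is
counted; sets emptied by the intersection are reported with p = 1 and
flagged.  The universe defaults to the genes of the processed matrix; when
several probe-level rows map to one gene, `collapse_probes()` keeps the
highest-SD row per gene.  `augment_database()` concatenates a base collection
with study-specific signatures, refusing silent name collisions.

## 5. Metagene prognosis

A signature's *metagene* is the unweighted mean expression of its member
genes, per sample.  Patients strictly below the median metagene form the
"fulvestrant-resistant" stratum — the signature genes are *down*-regulated in
resistance, so low expression marks the resistant-like state; patients at or
above the median are "fulvestrant-sensitive" (ties to the median land in the
sensitive group, per the strict "below the median" rule).  Kaplan-Meier
curves come from `survival::survfit`, and the pre-specified directional
hypothesis — resistant fares worse — is tested with a one-sided log-rank
test: `z = (O_w − E_w)/sqrt(V)` from the standard observed/expected table
(`survival::survdiff`, ties handled by the multi-event hypergeometric
variance), with the one-sided p the upper normal tail of `z`, so p < 0.5
exactly when the observed direction matches the hypothesis.  When a clinical
table carries both endpoints, distant-metastasis-free survival is preferred
over death-from-relapse-free survival; an explicit `endpoint` argument
overrides.

## 6. The synthetic-data generator

Real inputs to the original analysis (cell lines, arrays, public cohorts) are
not reproducible at desk scale, so the package generates every input with
known ground truth:

* **Expression experiments** (`generate_expression_experiment`) — log2-scale
  baseline `N(7, 1.2)` per gene, plus planted module effects of ±1.5 log2
  units per affected condition, plus `N(0, 0.15)` log2 noise, exponentiated
  to the linear scale (log-normal multiplicative noise, guaranteeing
  positivity), after which a constant per-(gene, batch) offset `N(0, 2)` is
  added on the linear scale — exactly the additive artefact the mean-shift
  correction removes.  The `resistance_screen_preset()` encodes the study
  structure: control + six ZF-TF conditions, two replicate infections in
  four batches, and five modules of sizes 230/225/135/123/72 — one up in
  three conditions, three up in exactly one condition each, and the 72-gene
  module down in all six.  The preset generates 2,500 genes, the working
  dimension of the clustering analysis (the variance-filter panel size):
  simulating the tens of thousands of additional array probes would only add
  rows destined for removal, and planting modules below an intensity-driven
  variance filter would make the ground truth unrecoverable by any analysis
  — a benchmark defect rather than added realism.
* **Gene-set databases** (`generate_gene_set_db`) — one "true" set per
  planted module drawing 80% of its members from the module, plus uniform
  decoy sets; serialisable to GMT.
* **Survival cohorts** (`generate_survival_cohort`) — bimodal (default) or
  continuous signature expression; exponential event times with the hazard
  multiplied by `hazard_ratio` for the low-metagene half; independent uniform
  censoring with the cap calibrated so the expected censored fraction equals
  `censoring_rate`.

One master seed is fanned out into named substreams (baseline, noise, batch,
…), so the same seed always reproduces the identical dataset and adding a
downstream component never perturbs upstream draws.

**Parameter rationale.**  The study reports no effect sizes or noise levels,
so the defaults are calibration choices, not estimates: 1.5 log2 units is a
strong but not degenerate perturbation for a stably transduced ZF-TF;
0.15 log2 replicate noise corresponds to high-quality technical replicates;
the additive batch offset (sd 2 on a scale where samples are normalised to a
trimmed mean of 100) is visible but subordinate to biological signal.  These
defaults make the planted structure *recoverable yet non-trivial*: with only
14 arrays, sample correlations of pure-noise genes with any fixed pattern
have an sd of about `1/sqrt(13) ≈ 0.28`, so a recovered module inevitably
gains a few correlated noise genes and loses an occasional noisy member.
The test suite quantifies this: over 20 generator seeds the pipeline reports
exactly one common-down cluster per seed with median Jaccard ≥ 0.9 against
the planted 72-gene module and a median size within a few genes of 72 —
exact integer recovery of a stochastic cluster size is not a property the
noise model (or real data) supports.

**What the generator does not emulate.**  Probe-level effects (no MAS5/CEL
simulation), intensity-dependent noise structure, correlated noise between
genes outside planted modules, probe-set redundancy per gene, and real
gene-set topology (decoys are uniform draws).  Passing the synthetic suite
therefore demonstrates correctness of the *procedures* under a clean
generative model, not performance on arbitrary real microarray data.

## 7. Numerical choices and degenerate inputs

* Hypergeometric tails come from `phyper(k−1, S, N−S, n, lower.tail=FALSE)`;
  `k = 0` short-circuits to 1.
* Correlation distances are clipped at 0 from below (perfect correlations
  can produce −1e−16) and symmetrised; constant rows are an error because
  their correlation is undefined.
* Median polish convergence is relative (`1e-6`) with a 20-iteration cap —
  typical Tukey settings.  Residuals are exactly invariant to shifting a
  whole input row (the row sweep absorbs it in one step) and invariant up to
  a small path-dependence for column shifts; the tests assert both at their
  honest tolerances.
* Average-linkage ties are resolved by `stats::hclust`'s deterministic
  internal rule; merge heights (the quantity with scientific meaning) are
  verified against a naive re-averaging oracle.
* Median split ties go to the "sensitive" stratum (strictly-below rule);
  an all-equal metagene is a reported error, not a silent 0/n split.
* The survival censoring cap is solved with `uniroot` from the closed-form
  censored fraction of a uniform-censoring exponential model.

## 8. Known limitations

* The cut height, `tau`, and `min_size` defaults formalise a visual
  judgement; on data with substantially different noise they should be
  re-examined (all are arguments and all are logged in the result).
* The batch correction is the published mean shift, deliberately not an
  empirical-Bayes method; its condition/batch confounding behaviour is
  described above.
* Enrichment is over-representation only (upper tail); depletion is not
  tested, matching the published procedure.
* No Cox regression or multivariable adjustment; the prognosis module
  implements exactly the metagene → median split → one-sided log-rank chain.
* Cross-platform gene-id mapping for external cohorts is the caller's
  responsibility; the projection and metagene functions log and tolerate
  missing genes but do not translate identifiers.
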