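---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
the numerical conventions, and what the synthetic-data tests do and do not
establish about real data.

## The analytical setting

The pipeline targets comparative single-cell RNA-seq designs in which
cells from several patient groups (here the four-way cross of
MPLC/SPLC with tumour/normal tissue) arrive already clustered, and the
scientific questions are: which clusters prefer which group, which cells
are malignant and how are their copy-number clones related, which
programs and interactions distinguish the groups, and whether a cluster's
signature carries prognostic information in bulk cohorts. Upstream steps
(alignment, HVG selection, PCA, graph clustering, batch correction) are
deliberately out of scope: cluster labels are inputs.

## Quality control and normalisation

A cell is kept iff `min_genes ≤ n_genes ≤ max_genes`, `n_umi ≤ max_umi`
and `pct_mito ≤ max_pct_mito`, with defaults 200, 5000, 30 000 UMIs and
30%. The verbal rules behind these bounds ("fewer than 200", "more than
5000", "exceeding 30 000", "over 30%") are read literally as strict
violations, so cells sitting exactly on a bound are kept; this is a
documented interpretation, since inclusive variants differ only on
boundary cells. Mitochondrial genes are recognised by a configurable
symbol prefix (`"MT-"`).

Normalisation is the standard library-size log transform
`ln(1 + s·x/N)` with scale factor `s = 10 000` (counts per ten thousand);
it is invariant to rescaling a cell's library, which the tests exercise.
Cell-cycle (or any nuisance) correction is implemented as least-squares
regression of per-gene expression on per-cell covariates — e.g. S/G2M
module scores from `module_score()` — with gene means restored. Regressing
scores rather than deleting gene lists is a choice: the underlying verbal
prescription ("regress out cell cycle genes") is ambiguous, and score
regression is the reproducible variant. Rank-deficient covariate matrices
are an error naming the collinear columns, not a silent drop.

## Marker statistics

For two disjoint cell sets the per-gene statistic is the Mann–Whitney U
with average ranks, reported as AUC = U/(n₁n₂) (ties count half). The
two-sided p value uses the tie-corrected normal approximation without
continuity correction, switching to exact enumeration over all
`choose(n₁+n₂, n₁)` group assignments when the pooled size is ≤ 12 (the
enumeration is valid under ties because U remains symmetric about
n₁n₂/2 across assignments). The fold change is
`log2((mean(exp(x_in)−1)+1) / (mean(exp(x_out)−1)+1))` — back-transformed
means with a +1 pseudocount, matching the convention of the standard
single-cell toolchain; this is documented here because the verbal methods
do not define the formula. "Detected" always means raw count > 0.

Marker discovery runs one-vs-rest per cluster, Bonferroni-adjusts over
the genes tested within that cluster, and retains genes with
`pct_in ≥ 0.25`, adjusted `p < 0.05` and `log2FC > 0.25`. Clusters with
fewer than 3 cells are skipped with a warning. Annotation scores each
(cluster, type) pair as the mean normalised expression of the type's
reference markers over the cluster's cells and assigns the argmax; a
cluster whose top two scores differ by less than 10% of the top score is
flagged ambiguous. This scoring rule is a stated surrogate for manual
annotation from DEGs and literature markers, which is not an algorithm;
it makes the assignment reproducible and testable.

Ten-gene signatures are the top markers by log2FC, ties broken by smaller
p and then gene id — every tie-break in the package is stated explicitly
so results are permutation-independent.

## Cluster-by-group odds ratios

For cluster *i* and group *j* the 2×2 table counts cells in/out of the
cluster crossed with in/out of the group. The odds ratio is the sample
cross-product ratio (ad)/(bc); when any cell is zero, 0.5 is added to
every cell (Haldane–Anscombe) — conditional, so non-degenerate tables are
unperturbed. The conditional-MLE odds ratio that `fisher.test()` reports
is deliberately not used as the point estimate. The two-sided Fisher p
sums hypergeometric probabilities of all tables, with fixed margins, whose
probability does not exceed the observed one, using a 1e-7 relative
tolerance for probability ties. BH correction is applied jointly across
all cluster×group combinations in one batch (the alternative, per-group
families, is not used; with a joint family the adjusted p values are
comparable across the whole preference matrix). Labels follow
OR > 1.5 with adjusted p < 0.01 (*enriched*) and OR < 0.5 (*depleted*).

Cells are the counting unit, as in the composition tables this procedure
accompanies; `by = "samples"` collapses to per-sample pseudo-units for
users worried about pseudo-replication, but is not the default and not
what the planted-recovery tests exercise.

## CNV scores, malignancy and clonal structure

`estimate_cnv_residuals()` is a transparent smoothing stand-in for
HMM-based CNV callers, not a re-implementation of one: per gene,
expression is centred on the reference-cell mean and clipped at ±3
reference SDs (falling back to the overall SD for constant reference
genes); genes are averaged in consecutive genomic blocks of
`window_size_genes` (default 10) — the windows are disjoint, so profile
columns are genomic intervals; each cell is then re-centred at its median
window value. The residual scale is "departure from copy-neutral", so the
per-cell CNV score Σ r² is a departure-from-diploid energy; whether such
scores should run over genes or windows is not externally specified, and
windows are used here (permutation-invariance over windows is tested).

Malignancy is called above the reference mean + 2 sample SDs (n−1
denominator), strictly; a zero-variance reference degrades to the mean
with a warning. The intended reference population is T/NK cells from
para-tumour tissue (3000 cells in the motivating design); the functions
take any reference subset.

Each window belongs to the chromosome arm containing the majority of its
span. An arm is called gained/lost per cell when its mean residual
exceeds +0.3 / falls below −0.3; these cutoffs are configurable defaults
chosen at roughly a third of a single-copy effect on log-scale residuals,
since no external values are specified. Cells with identical arm-event
sets collapse into subclones with exact fractions. Tree topology follows
strict event-set inclusion: each subclone's parent is the subclone whose
event set is the largest proper subset of its own (ties: larger fraction,
then lexicographically smallest event key); incomparable clones attach to
the diploid root. This reconstructs the input an evolutionary-tree
renderer consumes; only the rendering tool, not the topology rule, is
named in the motivating methods. Newick output labels nodes with
'|'-joined events ("5q+", "7p-") and uses cell fractions as branch
lengths, rounded to 4 decimals.

## Preranked GSEA

Genes are ranked by AUC − 0.5 (signed, descending; ties by log2FC then
gene id). The enrichment score is the classic weighted
Kolmogorov–Smirnov running sum with weight p = 1: hits add
`|metric|^p` normalised over hits, misses subtract `1/(N − N_hits)`; the
ES is the extremum of the walk, and the leading edge contains the hits up
to the extremum (from it onward for negative ES). If all hit metrics are
zero the hit weights fall back to uniform.

Because the input is a preranked list, the null permutes gene sets, not
phenotypes: for each set, `n_perm` random same-size sets from the ranked
universe. NES divides ES by the mean |null ES| of matching sign; p is the
matching-sign exceedance with add-one smoothing `(1+k)/(1+m)` so a
finite-permutation p is never exactly zero; FDR is the standard per-sign
ratio-of-tails estimator on the pooled normalised null, capped at 1. The
NES/FDR estimators are named conventions, not externally specified
formulas, and are documented as such. Degenerate nulls (no same-sign
permutation scores) are an error rather than a silent 0.

## Ligand–receptor interactions

The communication score is a documented simplified surrogate (the tools
used in practice do not publish a closed-form score): L is the
25%-trimmed mean of ligand expression over senders, R the geometric mean
over receptor subunits of their trimmed means over receivers (a zero
subunit zeroes R), and the probability is the Hill saturation
`LR/(0.5 + LR)`. The significance machinery shuffles cluster labels
among the union of sender and receiver cells, with
`p = (1 + #{null ≥ obs})/(1 + n_perm)` and BH across pairs. The retention
filter is applied verbatim: ligand and receptor detected in **more than**
10% of sender and receiver cells respectively, ligand log2FC (sender vs
all other cells, marker-engine formula) **> 0.1**, adjusted **p < 0.05**.
The filter, not the score, is the externally specified component.

## Module scores, correlation, survival

Module scores follow the control-matched convention: genes are binned
into 24 expression bins by average-expression rank; each set gene draws
100 controls from the non-set genes of its bin (with replacement when the
bin is small; set genes re-enter the pool only if a bin holds nothing
else — excluding them makes the control a clean non-set baseline); the
score is mean(set) − mean(controls) per cell. The only randomness is the
control draw, governed by an exposed seed.

Spearman correlation is the Pearson correlation of average ranks with an
exact permutation p for n ≤ 8 and a t approximation above.

Bulk signature scores are per-gene z-scores (sample SD) of
log2(x + 1) — the +1 pseudocount is a zero-safety choice where the verbal
methods say only "log2-transformed" — averaged over the signature genes.
Cohorts split at the median, with scores equal to the median assigned to
the *low* group (the tie side is unspecified externally; low is the
conservative choice and is stated). Kaplan–Meier, the two-group log-rank
test and the univariate Cox model are delegated to the `survival`
package, with Breslow tie handling for Cox (the simplest consistent
choice), CI = exp(β ± 1.96·SE) and a Wald p. The primary covariate is the
binary high/low split, matching the stratified design; the continuous
score is available as an option. Monotone likelihoods (complete
separation) and non-convergence raise errors with diagnostics instead of
returning unstable estimates. Tests cross-check the Cox estimate against
a two-stage grid search of the Breslow partial likelihood (1e-5 grid) and
the log-rank statistic against direct O/E/V tabulation.

## The synthetic-data generators

`generate_dataset()` draws counts from a negative binomial with per-gene
means log-normal (sdlog 0.5) around `nb_mean` (default 1 count/cell,
typical of shallow UMI data) and dispersion 0.5; cluster marker genes are
multiplied by `2^marker_log2_shift` (default shift 2, i.e. 4×);
per-sample cluster counts are multinomial from the group's composition
row. The default composition plants the motivating structure — a
macrophage-like cluster at 30% of cells in MPLC tumours versus 10%
elsewhere (odds ratio ≈ 3.9) with 2000 cells per group (2 samples ×
1000 cells) — so the odds-ratio stage has a known answer. Mitochondrial
content is simulated by scaling five `MT-` genes so each cell's expected
mito share is uniform on `mito_fraction_range` (default 2–8%, a healthy
range below the 30% QC cutoff).

`generate_cnv_profiles()` plants Gaussian window noise (SD 0.1) plus
±1.0 arm shifts for subclones on a four-chromosome toy genome (50 Mb p
arms, 70 Mb q arms, 1 Mb windows); the default clones are 5q+ (35%) and
5q+/7p− (25%) with the remainder diploid, mirroring the nested-gain
pattern such analyses report. `generate_survival_cohort()` draws
exponential event times with hazard `baseline × HR^z` (baseline 0.05 per
month, planted HR 1.5), z a latent Bernoulli(½) risk group that also
shifts the 10 signature genes by +2 log2 units over unit-variance noise;
censoring is an independent Bernoulli (default 20%) with censor times
uniform before the event.

All generators are pure functions of their config (seed included, RNG
state restored afterwards) and return ground truth beside — never inside —
the data. What they deliberately do **not** emulate: gene–gene
correlation, doublets, ambient RNA, batch effects, non-exponential
hazards. Passing recovery tests therefore demonstrates that each stage
inverts its own generative assumptions at realistic effect sizes, not
that those assumptions hold in any particular tissue.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: 8000-cell cohorts over
50–100 seeds for odds-ratio recovery; 600-cell, 480-window profiles over
20 seeds for CNV classification; n = 1000 patients over 50 seeds for
hazard-ratio recovery; exhaustive sweeps where they are cheap (all 2×2
tables with total ≤ 40 against enumeration; all ≤ 12-subject rank-sum
enumerations; the 28-set exhaustive GSEA null on an 8-gene universe).
These sizes give the planted effects comfortable power while keeping the
default suite quick on a laptop.

Conventions used throughout: genomic coordinates are 0-based half-open;
genes are identified by case-sensitive symbol strings; matrices are
cells-as-rows; group labels form a closed validated vocabulary; readers
reject invariant violations rather than repairing them; Newton/eigen
tolerances and every tie-break are fixed and documented at the function
level.

## Known limitations

- The CNV residual estimator is a moving-average smoother; it has no
  state model, no posterior probabilities, and underestimates effects at
  window boundaries and in short arms. Its clipping also caps planted
  effects larger than 3 reference SDs.
- Odds-ratio preference on cells ignores patient-level correlation;
  `by = "samples"` is a blunt remedy, not a mixed model.
- The interaction score is a surrogate; only the retention filter should
  be compared against published interaction lists.
- Annotation presumes the reference markers are expressed in the data;
  clusters from lineages absent from the panel will be assigned the
  nearest available type (flagged by low margins).
- The exact rank-sum p is limited to pooled n ≤ 12; beyond that, the
  tie-corrected normal approximation is used without continuity
  correction.
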