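---
title: "Methods: clonotype expansion calling and single-cell companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype expansion calling and single-cell companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(festsc)
```

This vignette is the package's own account of the statistics it
implements: the models, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data generators do and do
not emulate.

## Clonotype expansion testing (FEST)

A FEST-style assay cultures T cells with individual peptides (or pools)
and with no peptide, sequences the TCR-β repertoire of each culture, and
asks which clonotypes expanded *because of* a peptide. The unit datum is
a 2×2 table: clone reads vs all other reads, culture vs reference.

**Preprocessing.** Non-productive rearrangements are dropped; CDR3 amino
acid sequences are uppercased and must begin with C, end with F or W, and
have length ≥ 7 — the canonical junction grammar; duplicates within a
well are summed. Cultures with fewer than 1,000 productive reads are
excluded, since depth that low cannot support frequency comparisons.

**The test.** Expansion is directional, so the Fisher exact test is
one-sided (greater in the culture): `p = P(X ≥ a)` for hypergeometric `X`
with the table's margins, computed via the upper tail of the
hypergeometric distribution. The odds ratio is the cross-product ratio;
when any cell is zero, 0.5 is added to every cell (Haldane–Anscombe) so
criterion 3 always compares a finite number. The correction is applied
only in the zero-cell case; the convention is recorded in the caller's
config object.

**Decision rule.** A clonotype with condition reads at or above the
provider read floor (default 300 for short-read core assays; 30 for
survey-level platforms, matching their depth difference) is called when
it is (1) expanded vs the no-peptide control at BH FDR < α = 0.05, (2)
expanded vs every other culture at FDR < α — except cultures whose
peptides derive from the same mutation, which are expected to share
reactive clones and are exempted in both directions — (3) has odds ratio
strictly > 5 vs control, and (4) appears in at least 10 % of the
condition's wells. BH adjustment is applied *per comparison family*
(condition-vs-control; condition-vs-each-other-condition) across the
clonotypes eligible in that condition: each family corresponds to one
sequencing comparison, which keeps the adjustment interpretable when
conditions differ in eligible-clone counts. Verdicts are computed on
alphabetically ordered condition names, so input order cannot change
results.

**Triplicate mode.** Assays testing few peptides are typically run in
triplicate; there the rule is FDR < α vs control in ≥ 2 of 3 replicates
and no significant expansion in any replicate of any other condition.
This is a config flag, not auto-detected — explicit is better than
guessing the design from table counts.

## Single-cell QC and CD8 gating

Cell filters: detected genes (count > 0) must be ≥ 250 and ≤ median +
3×MAD of all cells; mitochondrial fraction ≤ 10 % and ribosomal fraction
≥ 10 % (both strict at the boundary in the removing direction). The MAD
is the raw median absolute deviation (constant = 1, no 1.4826
normal-consistency factor); the convention is written into the QC report.
Gene filters remove `MT-` genes, `RP`-prefixed poorly supported models,
TR segment genes (TRAV/TRBV/TRBD/TRBJ/TRAC/TRBC/TRD*/TRG* — kept in the
data they would simply echo clonotype identity), configured exclusion
lists, and genes detected in < 5 cells. Cells are filtered before genes;
because removing cells can push a gene below the 5-cell floor, the full
QC is a fixed point after at most two passes, which the tests assert.

The CD8 gate fits a Gaussian-kernel density (Silverman's `bw.nrd0`
bandwidth, 512-point grid spanning the data range ± 3 bandwidths) to
per-cell log2 CD8A expression and places the cut-off at the *first*
trough — the first grid point where the first derivative crosses from
negative to positive. If no interior trough exists the gate raises an
explicit "unimodal" error rather than guessing. The gate accepts any
per-cell expression vector; the pipeline default is
log2(library-size-normalized count + 1), and an imputation step can be
plugged in upstream — on raw counts, integer discreteness can itself
create a trough between the zero and one-read populations, which for a
marker that is truly absent in the negative population is exactly the
boundary wanted.

Clonotype linking is exact amino-acid string matching of each cell's TRB
CDR3 against verdict-true calls; a CDR3 called for two different antigen
classes flags its cells "ambiguous" rather than silently picking one.
Cells without a VDJ assembly stay unlabelled but are retained.

## Pseudobulk PCA and the canonical-correlation permutation test

Counts are summed per (cluster, sample) and each profile is scaled to a
common library size (1e6 by default; the constant cancels in the later
standardization). A (cluster, sample) pair with no cells is *missing*,
not zero; clusters missing in any sample are dropped from the feature
set, because PCA needs complete columns, and clusters seen in fewer than
two samples are excluded with a warning. A per-batch centering/scaling
stand-in (with a hook for any external batch-correction function) is
available for multi-batch designs.

Highly variable genes are selected per cluster by fitting a LOESS
regression (span 0.3, degree 2) of per-gene SD on log1p per-gene mean
across samples and keeping genes with positive residuals; the span is
fixed and recorded since nothing in the data chooses it. With fewer than
10 genes of nonzero mean the fit is skipped in favour of the top half by
SD, with a warning.

The per-cluster HVG blocks are concatenated into one sample × feature
table, each feature standardized to mean 0/variance 1 (zero-variance
features dropped), and samples embedded with PCA. The association of
(PC1, PC2) with a covariate is the first canonical correlation, with
categorical covariates dummy-coded (one reference column dropped); this
reduces to the multiple correlation for a binary covariate but also
handles > 2 levels. Significance comes from permuting the sample labels
(default 10,000), optionally within strata; the default is global
permutation. The p-value uses the add-one estimator
`(1 + #{null ≥ observed}) / (1 + n_perm)`, so it is never exactly zero.
A caution for small designs: with a binary 6-vs-6 covariate only
`choose(12,6) = 924` label patterns exist and the identity/complement
patterns reproduce the observed correlation, so the smallest attainable
p is about 2/924 ≈ 0.002 regardless of `n_perm`.

Clusters enriched for a labelled subset — subset frequency at least
`fold` (default 2) times the background frequency — can be merged into
one combined pseudo-cluster before this analysis.

## Composition ratio test

For a labelled subset (e.g. MANA-specific cells) observed at two
timepoints, `m_ct` is the subset proportion of cell type `c` at time `t`
and `p_ct` the background proportion; `R_ct = m_ct / p_ct` measures
relative abundance, and `S = Σ_c (R_c,T1 − R_c,T2)²` measures change.
Under the null the ratio is common across timepoints; it is estimated by
pooling both timepoints' subset and background cells,
`R_c = (pooled subset proportion) / (pooled background proportion)`, and
each Monte-Carlo replicate redraws the subset counts at time `t` from
`Multinomial(n_t, p_ct R_c / Σ_c' p_c't R_c')` with the observed subset
total `n_t` held fixed. Types with zero background at a timepoint are
excluded from S and from ratio estimation (and reported); subset cells
in a type with zero background are an input inconsistency and error.
The companion Fisher 2×C homogeneity test on the subset counts runs the
exact conditional computation for totals ≤ 200 and a seeded Monte-Carlo
version (default 1e5 draws) beyond that, with the method recorded —
exact multivariate enumeration grows exponentially with the table.

## Module scores, markers, dose–response

The module score bins all genes by average expression into 24 equal-size
rank bins and, for each set gene, samples 100 control genes with
replacement from the *non-set* genes of its bin (the whole bin if the
set fills it); the per-cell score is mean(set) − mean(control pool).
Subtracting bin-matched controls removes depth and global-shift effects:
adding a constant to every gene leaves the score unchanged to 1e-6,
which is asserted. Excluding the set from its own control pools matters
only when the gene universe is small relative to `bins` — with genome-
scale universes the overlap is negligible, but in that regime
self-contamination would cancel a genuine set signal. The checkpoint
score fixes the set to CTLA4, PDCD1, LAG3, HAVCR2, TIGIT, ENTPD1; the
exhaustion score reads a user-replaceable list, and the packaged default
(`exhaustion_genes.synthetic.txt`) is an explicitly synthetic stand-in of
canonical exhaustion-program genes, not a published list.

Marker calling is a one-vs-rest two-sided Wilcoxon rank-sum per gene,
Bonferroni-corrected over the genes tested in each group's comparison.
Significant markers must further pass log2FC > 0.25 and detection in
≥ 25 % of either compared population. The fold-change convention is
`log2((mean(expm1 x) + 1) / (mean(expm1 y) + 1))` on log-normalized
input — stated in the output because several inequivalent conventions
are in circulation. Score-correlated gene ranking is plain Pearson
correlation over candidate genes (HVGs minus the score's own members),
with constant genes assigned 0 and flagged, and optional per-group
coefficients and differences. Dose–response summaries report mean ± SEM
per (group, dose) — SEM undefined below 2 cells, flagged — and a
Spearman trend of score against log dose per group.

## Pseudotime dynamics

Genes with normalized expression ≥ 0.01 in ≥ 1 % of cells are retained.
Expression along pseudotime is fitted per sample by least squares on a
cubic B-spline basis with interior knots at pseudotime quantiles; the
default df = 7 (intercept + 6 basis columns, i.e. 3 interior knots) is a
fixed, configurable choice — flexible enough for rising/falling/transient
shapes, small enough to fit in a few hundred cells. The likelihood is
Gaussian with the per-model MLE variance, giving
`LR = n·log(RSS0/RSS1) ≥ 0` against the intercept-only null; per-sample
LRs are summed, matching permutations that shuffle pseudotime *within
each sample* (shuffling pseudotime against expression is implemented as
the equivalent within-sample shuffle of expression against a fixed,
pre-factorized basis, which makes 1,000 permutations over hundreds of
genes a matrix product). The p-value is the add-one-guarded fraction of
permuted LRs exceeding the observed one; BH across genes; dynamic ⇔
FDR < 0.05. Samples with fewer than df + 2 cells are skipped with a
warning. Exact fits (RSS ≈ 0) are guarded by a relative epsilon so
noise-free fixtures do not produce infinite LRs. Mean temporal curves
average the per-sample spline predictions on a common 100-point grid,
with per-sample extrapolation clamped to that sample's pseudotime range;
k-means (fixed seed, 10 restarts) clusters the curves after per-curve
standardization, so patterns — not amplitudes — define the groups. Any
top-percentile outlier trimming is a plotting concern only and never
enters the test.

## Synthetic data: what it emulates, what it does not

The repertoire generator draws baseline clone frequencies once from a
symmetric Dirichlet (concentration 0.5 — a skewed repertoire), multiplies
spiked clones' frequencies by their fold in the target condition,
renormalizes, and draws reads multinomially per well. Spiking at fold
`f` therefore changes *frequencies*, not raw counts, exactly the signal
the Fisher test sees. CDR3 strings follow the C…F/W grammar so generated
tables pass preprocessing losslessly. The single-cell generator uses a
Poisson-lognormal count model around cluster/covariate/batch-shifted
gene means, a truncated power-law clone-size distribution, bimodal CD8A
(high in CD8+ cells, near-zero ambient otherwise), and places labelled
clonotype cells into designated clusters at a designated enrichment. The
pseudotime generator adds Gaussian noise to template shapes on uniform
per-sample pseudotimes.

None of this claims biological fidelity: no UMI saturation, ambient RNA,
doublets, batch-by-cluster interactions, TCR rearrangement biology, or
transcriptional kinetics. Passing tests therefore demonstrate that the
statistics behave as designed under their own assumptions (calibration
under the null, power against planted effects, determinism), not that
they are robust to every artefact of real data.

## Problem sizes and numerical choices in the test suite

The statistical acceptance checks use: all 2×2 tables with margins ≤ 60
against an independent enumeration oracle; 500 null repertoire
simulations (1,000 clones, depth 1e5, 10 wells) plus 60 spiked runs of 5
clones at 20-fold; 500 null composition repetitions at 1,000 Monte-Carlo
draws; 200 null and 100 power repetitions of the CC permutation test at
500 permutations; a 5,000-cell Gaussian mixture for the gate; 240 genes
× 300 cells × 1,000 permutations for pseudotime; exact rank-sum
enumeration up to size-8 groups; a 1,000-gene × 2,000-cell module-score
fixture. These sizes were chosen to put each check's Monte-Carlo error
well inside its decision margin while keeping the whole suite fast
enough to run routinely. Permutation and Monte-Carlo p-values use
add-one estimators throughout; all randomness flows from explicit seeds,
and every seeded operation is bit-reproducible.

## Known limitations

- The caller tests clonotypes per condition with wells used only for the
  presence criterion; a well-level random-effect model is out of scope.
- The BH family choice (per comparison) is a convention; a global family
  across conditions would be marginally more conservative.
- ComBat-style empirical-Bayes batch correction is not implemented; the
  per-batch standardization stand-in removes location/scale effects
  only.
- The composition test supports exactly two timepoints.
- Trajectory inference is upstream: pseudotime is consumed, not
  estimated.
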