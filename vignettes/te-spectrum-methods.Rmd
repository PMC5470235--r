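---
title: "Methods: TE activation, chimeric transcripts and methylation across a pluripotent spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE activation, chimeric transcripts and methylation across a pluripotent spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices behind
them: what each stage computes, which knobs matter, what the synthetic data
emulate (and what they do not), and where the design was genuinely open.

## Coordinates and annotation model

All internal coordinates are 0-based half-open. GTF and RepeatMasker input
(1-based inclusive) is converted at the I/O boundary; BED passes through
unchanged. A gene is summarized over the union of its transcripts: exons
are merged, the *first annotated exon* is the 5′-most exon in gene
orientation (minimum-start exon on `+`, maximum-end exon on `-`), the TSS
is its 5′ base, and the *acceptor sites* are the first base (in gene
orientation) of every non-first exon — the genomic start on `+`, the
genomic end − 1 on `-`. Working at the gene level rather than per
transcript reflects that chimeric transcription is described relative to
genes; it also makes the caller insensitive to incomplete isoform
annotation. Overlap queries run through a per-chromosome nested containment
list (IRanges) behind `build_interval_index()`, and are property-tested
against a linear scan.

## Splice junctions and the chimeric-transcript rule

Junctions are extracted by walking CIGAR strings of primary alignments: each
`N` operation contributes one intron `[first skipped base, end)`; a read
with *k* `N`s contributes *k* junctions; strand comes from the `XS:A` tag
when present. Records with an `N` at a read edge are malformed for this
purpose and are skipped with a warning. Only primary alignments add support,
so multimapping reads are never double-counted.

A junction is called chimeric for gene *g* when, in gene orientation:

1. its **donor** (intron start − 1 on `+`, intron end on `-`) lies inside a
   TE instance;
2. the donor is strictly upstream of *g*'s first annotated exon;
3. the TE's gene-proximal edge is within `W` of the first exon's 5′ edge,
   with distance ≥ 0 (the TE itself is fully upstream);
4. the **acceptor** equals an annotated acceptor site of *g* exactly
   (`acceptor_tolerance` exists but defaults to 0 — simulated and real
   splice acceptors are base-precise);
5. at least `min_samples` samples carry ≥ `min_support` reads.

Parameter defaults and why:

* `W = 10000` bp. No distance bound is inherent to the biology; 10 kb
  covers the scale at which LTR promoters drive downstream genes in genome
  browser views of such events, and the bound is explicit and tunable
  rather than hidden in the rule. The generator plants adversarial TEs at
  `W` + 1.5–2.5 kb that the caller must never call.
* `min_support = 2`, `min_samples = 1`: two junction reads suppress
  single-read alignment artifacts without costing sensitivity at typical
  bulk depth.
* `require_gene_strand_match = TRUE`: a junction with a known transcript
  strand must match the gene. `require_te_strand_match = FALSE`: LTR
  promoters fire antisense to their element, as for MT2/MERVL-driven
  transcripts, so the TE's own strand is not constrained.
* The donor must fall **inside the TE**, not merely upstream of the gene:
  the junction read is the observable; inferring a TSS inside the TE from
  coverage is out of scope.

Per-condition activity re-applies the support thresholds within each
condition's replicates; the specificity classes are `single-condition`,
`restricted` (> 1 but not all) and `ubiquitous`.

## TE family quantification and the multimapper policy

Reads are assigned to the family of the TE instance their aligned blocks
overlap most (summed bp across the instances of a family; an exact tie
between families is ambiguous and the read is discarded and logged). Two
policies are exposed because TE-derived reads multimap heavily and no
single convention is neutral:

* `unique` (default): only NH = 1 primary alignments count. Conservative;
  undercounts young, high-copy families.
* `fractional`: every reported record (primary and secondary) adds 1/NH.
  Spreads evidence across reported loci; requires NH tags and errors
  otherwise with an instruction to use `unique`.

Family-level (not instance-level) counts are the unit of testing because
differential activity is a family phenomenon; instance-level diagnostics
come from the chimera module instead. EM-style reassignment
(TEtranscripts-like) is deliberately out of scope.

## The differential-expression engine

The engine is implemented in-package from formulas so that its exact
behavior is specified and testable.

**Normalization.** Median-of-ratios size factors with a leave-one-out
reference: sample *j*'s factor is the median over everywhere-positive
features of its count divided by the geometric mean of the *other*
samples. This keeps the two properties the package tests: identical
samples get identical factors, and multiplying one sample's counts by *c*
multiplies exactly its factor by *c* (with the classic all-samples
reference the scaled sample contaminates its own reference and the second
property fails). When TE families are tested, size factors are computed
from the gene counts, so global TE activation cannot masquerade as library
depth.

**Dispersion.** Per feature, a method-of-moments estimate on normalized
counts pooled across the two groups (`(s² − μ·ξ)/μ²` with ξ the mean
reciprocal size factor, weighted by group df), floored at 0, then shrunk
50/50 toward a trended fit `a₀ + a₁/μ` obtained from binned medians
(falling back to the overall median when degenerate). With fewer than two
replicates in a group the engine warns and falls back to a common value.

**Test.** Wald statistic on `log2(mean_A / mean_B)` with the delta-method
standard error from `Var(K) = μ + αμ²`. The statistic is referenced to a
*t* distribution with 4× the residual degrees of freedom rather than a
normal: the 50/50 shrinkage quarters the sampling variance of the plug-in
dispersion, and moment-matching the shrunk dispersion to a scaled
chi-square yields exactly that moderated df. Monte-Carlo calibration (the
package's acceptance suite) shows the normal reference is anti-conservative
at n = 3 vs 3 (type-I ≈ 0.08 at nominal 0.05) while the moderated *t* sits
at 0.04–0.06, with planted 8-fold changes still recovered completely at
adjusted p < 0.01. Reported fold changes use no pseudocount (infinite
log-ratios are legitimate for on/off features); only the test statistic
moderates exact zeros with +0.5 to keep its SE finite. Features with both
means zero get `log2fc = 0`, `p = 1`.

**Multiplicity.** BH within each pairwise contrast, matching an
"adjusted p per comparison" reading; the robust differential set is the
union of per-pair significant features. Whether a global correction across
all pairs is preferable is not decidable from the substance the package
mirrors; union-per-contrast is the documented default
(`differential_genes()` + `de_union()`). Defaults `alpha = 0.01`,
`lfc_threshold = 2` follow the conventional "|log2 FC| > 2, adjusted
p < 0.01" thresholds for this kind of analysis.

## PCA spectrum ordering

Counts are transformed to log2(CPM + 1); the top `k_var_genes = 2000` genes
by variance (clamped with a warning when fewer exist) are gene-centered and
decomposed by SVD with samples as observations. Loadings are unit-norm and
explained-variance fractions non-increasing; reconstruction
`scores · loadingsᵀ` must reproduce the centered matrix to numerical
precision, which the tests assert at 1e−8. Because an SVD sign is
arbitrary, PC1 is anchored so the user-named `reference_condition` (the
most naive state) has a negative mean score; remaining components fix their
sign by making the largest-magnitude loading positive, so results are
reproducible across BLAS implementations and sample orders. The spectrum
order is the conditions sorted by mean PC1 score; `top_loadings()` names
the genes that drive the separation.

`classify_te_origin()` flags features whose TSS lies inside a TE instance
(half-open: a TSS exactly at the element's end is outside) or within a
configurable downstream window of one; the default window is 0.

## Methylation summaries

The level of any CpG set is the **weighted** (read-pooled) level ΣM/ΣT,
not the mean of per-CpG fractions: at shallow coverage a once-seen CpG
contributes one read of evidence rather than a hard 0 or 1, which keeps the
estimator consistent as coverage grows (tested at coverages 1, 5 and 20).
Regions with pooled depth below `min_depth = 10` report a missing level —
never a silent zero. Region sets are summarized by the median over their
member regions. Imprint status cuts are working definitions around the
expected 50% of a normal imprint: `erased` < 0.15, `atrophied` < 0.35,
`maintained` ≤ 0.65, `hyper` above; they are configurable and exist to make
the imprint table machine-readable, not as biological claims.

## The synthetic dataset

The generator writes a complete miniature study — FASTA genome, GTF gene
models, BED TE instances and region sets, a design table, per-sample
spliced SAM and per-CpG reports — with the truth recorded alongside. Its
defaults *are* the study conditions the rest of the package is tested
under, chosen once:

* Six conditions ordered 2i/L → 2i/L_K → 2i → Pd/L → Ch/L → S/L_F with two
  replicates each; global 5-mC levels 0.28, 0.33, 0.42, 0.57, 0.72, 0.80
  (a monotone gradient, lowest in 2i/L, spanning the hypo-to-hyper range
  such studies report); imprints at 0.50 everywhere except 0.25 (atrophy)
  in 2i/L and 0.05 (erasure) in the KSR condition.
* A 2 Mb genome on two chromosomes, 100 genes of 2–3 exons laid out in
  non-overlapping slots whose upstream corridors hold the planted TEs; 120
  background TE copies from a catalog of real mouse family names with
  their classes; 30 planted chimeras within the caller window, 3
  adversarial ones beyond it, and 300 decoy junctions (annotated gene
  introns plus random intergenic junctions whose acceptors are verified
  not to coincide with any annotated acceptor site).
* Negative-binomial counts (dispersion 0.05; dispersion 0 gives the
  Poisson limit) with 8-fold (log2 FC = 3) planted effects: 30 *driver*
  genes follow the condition gradient and carry PC1, and 30 *jump* genes
  activate in a single mid-gradient condition — placed mid-gradient so the
  single-condition programs (as 2C-like activation is) stay orthogonal to
  the spectrum axis. TE families receive graded activity mirroring the
  biology being modeled: IAPEy-int/RLTR45 high at the naive end,
  MER50B/L1M6B at the primed end, MT2_Mm/MERVL-int jumping in 2i, LTRIS2
  repressed in Pd/L.
* 20000 gene reads and 4000 TE reads per sample, 20% of TE reads written
  as NH = 2 multimappers (primary + secondary record, same name), 80 bp
  reads, 40 bp junction flanks, 5 junction reads per active
  chimera-sample; CpG depth Poisson(2) — shallow, but ≥ 10⁴ covered CpGs
  so pooled levels concentrate within ±0.02.

Everything derives from one seed; two runs are byte-identical. What the
generator does **not** emulate: sequencing error and quality, bisulfite
reads (methylation is simulated at the CpG-call level), paired-end
geometry, isoform structure beyond one transcript per gene, mapping
ambiguity beyond the NH = 2 two-copy model, and background effects between
genetic lines. Passing on these data therefore demonstrates the
correctness of the *computations* — rule logic, estimators, orderings —
not robustness to alignment artifacts of real libraries.

## Numerical and degenerate-input conventions

Ties in TE assignment are discarded, not split; ties in TE choice for a
chimeric call break by distance then instance id; hierarchical-clustering
leaves are deterministic because samples are processed in `sample_id`
order; a constant count matrix yields an all-zero PCA rather than an
error; an empty GTF yields an empty gene table; a CpG report with
methylated > total is rejected naming the record; zero-coverage CpGs are
retained but never contribute to a level.

## Problem sizes used by the checks

The test and acceptance suites run the full default simulation (2 Mb, 12
samples, ~300 k alignments) once for the chimera criterion, a 600 kb
variant everywhere a whole dataset is needed repeatedly, 1000-feature
count matrices over 20 seeds for DE calibration, and 400-gene gradients
for the PCA checks — sizes at which every stage's behavior is asserted
exactly while the whole suite stays desk-scale. These sizes are package
choices; all of them are parameters of `simulation_config()`.

## Known limitations

With only two replicates per condition the full pipeline's PC1 ordering
can swap adjacent mid-gradient conditions (Spearman 0.83–0.94 against the
planted order across seeds, versus exactly 1.0 on the dedicated gradient
fixture): the single-condition jump programs add variance that is not
aligned with the spectrum axis, just as sub-state activation does in real
data. The chimera caller requires annotated acceptor sites, so fully novel
genes cannot be recovered; junction support is the only abundance measure for
chimeric isoforms; the DE engine fits two-group contrasts only (no
covariates, no background term — the design table records `background` but
the miniature study keeps it constant); fractional TE counting does not
re-estimate assignment probabilities; and the methylation module performs
no differential testing, only summarization and classification.
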