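---
title: "Classifying developmental expression divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying developmental expression divergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures in `heterochron`, the
assumptions behind them, the choices that were genuinely open and how they
were resolved, and what the synthetic benchmarks do and do not demonstrate.

## Data model and normalization

The unit of analysis is the gene (transcript-level estimates are assumed to
have been summarized upstream). Counts are modelled as negative binomial
(NB): `Var(Y) = mu + alpha * mu^2`, with a per-sample library-size factor
entering through the mean. Size factors are median-of-ratios: for sample
*j*, the median over reference genes (those with no zero count) of
`count[g, j] / geomean_g`, rescaled so the factors have geometric mean 1.
The median is taken on the plain ratios, which the rescaling then anchors;
when no gene is expressed in every sample the estimator falls back to a
positive-counts-only variant with a warning. Quality control drops samples
under two million reads (metadata `total_reads` when available, else the
column sum; whether the cut refers to raw or mapped reads is not observable
from a count matrix, so column totals are the fallback semantics).

Dispersion is estimated per gene by method of moments within replicate
groups (genotype × stage), `alpha = (s^2 - m_pois) / m^2` with the Poisson
term corrected for size factors, pooled across groups by degrees of freedom,
then shrunk toward a parametric mean–dispersion trend `a0 + a1/mu` with a
weight that grows with replicate degrees of freedom (prior strength 8), and
floored at `1e-8`. This is a deliberately transparent stand-in for the
heavier empirical-Bayes machinery of the established DE packages: with 4–6
replicates per cell the moment estimator is informative, and the trend
shrinkage stabilises low-count genes. Independent filtering, fold-change
shrinkage and outlier refitting are intentionally omitted.

## Differential expression

Each stage is a two-group contrast. Group means are fitted by maximum
likelihood on the log scale with size-factor offsets and fixed per-gene
dispersion (Fisher scoring; the reported standard error is the inverse
Fisher information of the log-mean), and the group log-ratio is tested with
a Wald statistic. A gene is DE at a stage when the BH-adjusted `q <= alpha`
(default 0.05) **and** `|log2FC| >= lfc_min` (default 1, the twofold rule).
The reported `log2FC` uses a display pseudocount of 0.5 normalized counts;
the test itself uses none, and the twofold rule is applied to this raw
(unshrunken) fold change. Genes enter the FDR denominator only if their mean
normalized count reaches 1 in at least one genotype × stage cell; genes with
all-zero counts in both groups are never tested. A group with all-zero
counts is floored at half a count for the point estimate so that the Wald
statistic stays finite; such calls are driven by the nonzero group.

## Profile clustering

Stage profiles are per-stage means of `log2(normalized + 1)` across
replicates. Rows with standard deviation below `min_sd = 0.1` log2 units are
set aside as unclusterable *before* standardization (filter-then-standardize;
the alternative order would rescue flat genes by construction), and the rest
are z-scored per gene. Fuzzy c-means with Euclidean distance is fitted on
the planktotroph (reference) profiles by alternating optimization:
membership update from centroid distances with exponent `2/(m-1)`, centroid
update as `u^m`-weighted means; 10 seeded random restarts, convergence when
no centroid coordinate moves more than `1e-8`. Zero distances receive a hard
membership on the nearest centroid, ties broken toward the lowest cluster
index and flagged.

The fuzzifier `m` is estimated from the data dimensions (N profiles, D = 6
stages) by the published size-based relation and clamped to [1.05, 3]; it
decreases toward hard clustering as N grows. The cluster number scans
`k = 2, 3, ...` ascending and keeps the largest `k` before the first `k`
whose fitted centroids contain a pair with Pearson `r >= 0.85` — the
stop-at-first-violation reading of "the highest number of clusters" keeps
the scan monotone and reproducible. The lecithotroph profiles are
standardized by their own row statistics (each morph's shape is judged on
its own scale) and mapped onto the *fixed* centroids with the model's `m`;
centroids are never refit on the second morph. Cluster labels are arbitrary,
so reports order clusters by the stage at which each centroid peaks
(early to late), with peak ties broken by the centroid's center of mass.

## Gene classification

Categories are assigned with the precedence **morph-specific >
heterochronic > heteromorphic > conserved**, which makes the partition
mutually exclusive; the precedence itself is forced by the definitions (a
gene off in one morph has no second profile to compare). Heterochrony
requires three conditions: DE at ≥1 stage, different hard cluster
assignments in the two morphs, and Pearson correlation of the
unstandardized log-scale stage-mean profiles below `r_max = 0.85` — the
correlation filter removes cluster switches that are artifacts of
discretizing similar shapes. A gene with an undefined correlation (constant
profile) is judged by the cluster switch alone and flagged. Genes
unclusterable in either morph fall back to heteromorphic-if-DE, flagged.

The morph-specific rule uses per-sample adaptive thresholds: within a
sample, nonzero `log2(normalized + 1)` values are fitted with a
two-component Gaussian mixture (unequal variances, via `mclust`), honoring
the assumption that robust expression is normally distributed while spurious
expression piles up near zero; the threshold is where the posterior
probability of the high component crosses 0.5, guaranteed to lie between the
component means. If the components collapse (means closer than 1 log2 unit)
or no crossing exists, the fallback is the 15th percentile of nonzero
values, flagged. The gene-level rule is then: above threshold in ≥3
replicates at some stage in one morph (stages left with fewer than three
replicates after QC require `ceiling(0.6 * n)`), and at most **one**
above-threshold sample in the other morph *across all stages combined* —
the single-mismatched-replicate allowance is read as one incidence per morph
over the whole time course, not per stage. By default morph-specific calls
additionally require DE at ≥1 stage (`require_de_for_morph_specific`),
consistent with counting them inside the DE-differentiated total; the flag
exposes the alternative.

## F1 analyses

Genes DE between the reciprocal F1s (PL vs LP) at any tested stage are
excluded from inheritance calling, since a parent-of-origin effect
invalidates the pooled-F1 comparison. Inheritance at a stage uses three
pairwise NB Wald tests (F1 vs each parent, parents vs each other) at the FDR
cut **without** the twofold rule: the additive expectation sits ~1.6-fold
from each parent when the parents differ fourfold, so a fold-change gate
would make additivity undetectable by construction; the established
criteria this classification follows are test-based. Conserved = nothing
significant; additive = F1 differs from both parents with mean strictly
inside the parental interval; dominant = indistinguishable from one parent,
different from the other; over-/under-dominant (misexpressed) = different
from both with mean outside the interval. Reciprocal F1s are pooled by
default (`pool_reciprocal_f1`), trading a parent-of-origin blind spot
(handled by the exclusion rule) for power.

Allele-specific contrasts use only assignable reads: per gene and stage, a
paired NB GLM with one blocking coefficient per F1 sample and one allele
coefficient, dispersion estimated from Poisson-fit residual moments shrunk
toward the across-gene median. Genes with fewer than `min_assignable = 10`
summed assignable reads are untestable and leave the FDR denominator. The
interaction contrast compares the parental and allelic log-ratios with
`z = (L_A - L_B) / sqrt(SE_A^2 + SE_B^2)`. The three significance flags and
the two ratio signs then map deterministically onto
cis / trans / cis+trans / cis×trans / compensatory / conserved, with every
remaining pattern (including any untestable side) labelled ambiguous.
Stage-wise calls are reported per stage; the gene-level summary is the modal
informative call.

Parent-of-origin effects are PL-vs-LP contrasts (with the full DE rule) at
the stages where both reciprocals exist — 16-cell, gastrula and swimming
under the default design, where LP samples are limited to those three
stages. Significant genes that are also DE between the parents at that stage
are labelled maternal- or paternal-matching by sign agreement; others stay
unassigned.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
read-level reality: NB counts (global dispersion 0.05 by default — pooled
embryos from full-sib lab crosses average out much embryo-level variance,
so replicate dispersions sit at the low end of the bulk RNA-seq range),
log-normal library factors (sd 0.15) with an emulated sequencing depth of
~30M reads recorded in the metadata, five replicates per genotype × stage,
and LP samples only at 16-cell/gastrula/swimming, mirroring the study
design it follows. Six canonical stage profiles are Gaussian bumps peaking
at each stage (width 0.8 stages, floored at 5% of peak); the stage-1 bump
is a monotone maternal-decay shape and the stage-6 bump a post-gastrula
rise, and all pairwise log-scale correlations stay below 0.85.

Per category: conserved genes share one profile; heteromorphic genes scale
the whole profile by `2^2` in one morph (amount-not-timing is the category's
definition; scaling a stage subset would manufacture shape changes that
belong to heterochrony); heterochronic genes move two shapes along the shift
map (default +2), and the generator refuses pairs correlating at ≥0.85
unless `enforce_shape_divergence = FALSE` (used to benchmark the
correlation filter on borderline cases); morph-specific genes sit at an
ambient NB mean of 0.5 in the off morph — not a structural zero, so the
adaptive threshold is exercised. F1 totals follow the inheritance mode
(additive = arithmetic midpoint, chosen over the log-scale midpoint because
the DE machinery operates on count means; dominant = the matching parent;
misexpressed = fourfold outside the parental range, a free parameter with
no empirical anchor); allelic log2 ratios follow the regulatory mode
(cis = parental ratio exactly, trans = 0, cis+trans = half the parental
ratio, cis×trans = minus half, compensatory = 2 with equal parents).
Assignable reads are a binomial split of 30% of each F1 count — the
assignable fraction is a free parameter reflecting how few genes carry
morph-differentiating SNPs in an intraspecific cross. Parent-of-origin
genes (50 by default) multiply PL by `2^(+1)` and LP by `2^(-1)` at 16-cell
and blastula only, oriented by the maternal morph's parental expression.

What the benchmarks do **not** show: robustness to trended or gene-specific
dispersion misspecification, to profile shapes outside the bump family, to
unbalanced replication, or to mapping bias in allele assignment. One
composition caveat surfaced during design and is worth stating: when a
large fraction of genes is divergent between two sample groups,
median-of-ratios factors absorb part of the shift (the median gene is no
longer null). The category benchmark tolerates this because the
PP-vs-LL layout is symmetric, but the F1 benchmark uses a realistic
mostly-conserved composition (`f1_benchmark_config`: 60% conserved) so
that normalization stays anchored — as it is in real transcriptomes, where
only a few percent of genes diverge.

## Problem sizes and numerical choices

The shipped benchmarks are desk-scale: 600 genes (150/150/150/75/75 across
categories) for category recovery, 2,000 null genes at dispersion 0.1 for
error control, and 750 genes for the F1 benchmark (~200 assignable reads
per gene per sample, parental ratio 2 log2 units). Convergence tolerances:
FCM centroid movement `1e-8` (tests tighten to `1e-14` when comparing
fixed points across implementations), IRLS/Fisher scoring step `1e-10`,
linear-predictor clamps at ±20/30 to keep degenerate blocks finite.
All randomness flows from explicit seeds through restorable RNG state, so
identical configurations produce byte-identical outputs.

Known limitations: the Wald tests share the usual small-count
anticonservativeness that LRT or exact tests would avoid; the fuzzifier
relation is an extrapolated heuristic outside its calibration range (hence
the clamp); cluster-number selection inherits FCM's restart stochasticity
(mitigated, not eliminated, by seeding and 10 restarts); and the
inheritance taxonomy leaves genuinely intermediate patterns in "ambiguous"
rather than forcing a call.
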