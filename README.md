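# heterochron

Classification of developmental gene-expression divergence between two
intraspecific larval morphs, from stage-resolved bulk RNA-seq counts.

## The problem

Two developmental morphs of one species — a feeding *planktotrophic* (PP) and
a non-feeding *lecithotrophic* (LL) larva — proceed through the same embryonic
stages (16-cell, blastula, gastrula, trochophore, swimming larva, 1-week
larva) while diverging in life history. Given a gene × sample count matrix
covering both morphs (and, optionally, reciprocal F1 crosses PL and LP, mother
listed first), the package asks, gene by gene:

* **Is expression divergent at all?** Per-stage negative-binomial Wald tests
  with Benjamini–Hochberg FDR control; a gene is differentially expressed (DE)
  at a stage when `q <= 0.05` and the fold change exceeds twofold.
* **Is the divergence a change of amount or of timing?** Standardized 6-stage
  expression profiles of the reference morph are clustered by fuzzy c-means
  (fuzzifier `m` estimated from data size; cluster number `k` chosen as the
  largest `k` whose centroids all correlate below `r = 0.85`); the other
  morph is mapped onto the fixed centroids. A DE gene that keeps its cluster
  is **heteromorphic** (amount); one that switches clusters with inter-morph
  profile correlation `r < 0.85` is **heterochronic** (timing).
* **Is a gene simply off in one morph?** A per-sample adaptive expression
  threshold (two-component Gaussian mixture on `log2` normalized expression;
  robust expression is the normally distributed high component) flags each
  gene × sample; a gene above threshold in ≥3 replicates at some stage in one
  morph and in ≤1 sample of the other morph across all stages is
  **morph-specific**.
* **What drives the divergence?** With reciprocal F1s: inheritance mode
  (conserved / additive / dominant / over- or under-dominant) from pairwise
  F1-vs-parent tests; parent-of-origin effects from PL-vs-LP contrasts; and —
  with allele-resolved F1 counts — the regulatory architecture per stage from
  three contrasts (parental A, allelic B, interaction C):
  `A·B·¬C = cis`, `A·¬B·C = trans`, `A·B·C` same sign `= cis+trans`,
  opposite sign `= cis×trans`, `¬A·B·C = compensatory`.

A seeded synthetic-data generator produces complete experiments (parental +
reciprocal F1 counts, allele counts, metadata) with per-gene ground truth for
every layer, so the whole pipeline is benchmarkable offline.

## Worked example

```r
library(heterochron)

ds  <- simulate_experiment(sim_config(seed = 7))   # 600 genes, known truth
cfg <- pipeline_config(counts = ds$counts, samples = ds$samples,
                       allele_counts = ds$allele_counts,
                       out_dir = "example_out", seed = 7)
rep <- run_pipeline(cfg)
print(rep)
```

```
divergence classification report
  genes: 600 total, 600 tested
  clusters: k = 6 (fuzzifier m = 1.813)
  categories:
    conserved       150
    heteromorphic   149
    heterochronic   152
    P-specific      74
    L-specific      75
    unclassifiable  0
  percent DE by stage:
    16-cell       67.8% (407 genes)
    blastula      66.2% (397 genes)
    ...
```

The generator planted 150/150/150/75/75 genes across the five categories; the
report recovers them almost exactly. `k = 6` is selected because a seventh
centroid would correlate above 0.85 with an existing one; `m = 1.813` is the
data-size-based fuzzifier estimate for 600 six-stage profiles. Per-gene detail
lives in `rep$classification`:

```
gene_id      category cluster_P cluster_L pearson_r de_stages                    direction
g0301  heterochronic          2         4    -0.009 16-cell,gastrula,trochophore earlier-in-P
g0303  heterochronic          6         1    -0.590 16-cell,...,1-week           earlier-in-L
```

Gene `g0301` peaks in cluster 2 (early) in PP but cluster 4 (late) in LL with
near-zero profile correlation — a timing shift, expressed earlier in the
planktotroph. Result files (`classification.tsv`, per-stage `de_<stage>.tsv`,
`regulatory.tsv`, `inheritance.tsv`, `parental_effects.tsv`,
`cluster_model.json`, `report.json`, `MANIFEST.tsv`) are written to
`out_dir`; identical configs give byte-identical outputs.

A thin shell wrapper is installed at
`system.file("scripts", "divergence-pipeline.R", package = "heterochron")`
with `simulate` and `run` subcommands.

## Scope

The pipeline starts from count matrices: read trimming, mapping,
quantification, SNP discovery and read-parentage assignment are upstream of
this package, and GO enrichment is downstream.
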