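# circanet

Multi-evidence expansion of circadian gene regulatory networks.

The mammalian circadian clock is driven by a ~14-gene core oscillator (the
PER, CRY, BMAL, CLOCK/NPAS2, ROR and REV-ERB families), but the set of
genes it regulates downstream is much less settled. `circanet` implements a
pipeline for systems biologists who want to expand a curated clock seed
network into a network of putatively clock-regulated genes, requiring
agreement between two independent evidence streams and annotating the
result with orthogonal validation data:

1. **Co-expression prediction** — Pearson correlation ρ and mutual rank
   `MR(a,b) = sqrt(rank_a(b) · rank_b(a))` over an expression compendium;
   the top-K pairs between seed genes and the rest of the genome are
   selected by |ρ| and filtered by *tightness* (the number of distinct seed
   partners per candidate, threshold ≥ 2).
2. **Literature mining** — text-mined interaction tables are aggregated
   into gene pairs; the 50 most frequent partners per seed gene form the
   second prediction stream.
3. **Consensus and assembly** — the intersection of both streams extends the
   seed into a three-layer network (core clock ⊆ curated extension ⊆
   predicted extension) with per-edge provenance
   (`known` / `coexpression` / `textmining` / `both`), exported as GraphML
   or SIF.
4. **Validation layers** — hypergeometric term overrepresentation with BH
   FDR (`P(X ≥ Significant)` drawing the query from the namespace
   universe); ChIP-seq target calling by nearest-TSS peak assignment with
   summed signal scores `S_g` and a `log2(S_g) ≥ 3` threshold; and a
   JTK-style rhythmicity scan (Kendall's τ against cosine references over a
   20–28 h period grid, with a Monte-Carlo-calibrated p-value for the
   max-τ statistic).

A synthetic-data generator plants known truth in every input format the
pipeline reads (expression TSV, evidence TSV, GMT, narrowPeak, BED, time
course TSV), so the whole pipeline runs and is tested without any external
download.

## Worked example

Run the full pipeline on the default synthetic study (200 unsynchronised
samples, a 43-gene seed network, 40 planted targets with tightness 2, 1000
background genes, 10% literature false positives), selecting the reference
1.18% fraction of seed × universe pairs:

```r
library(circanet)
cfg <- pipeline_config(synthetic = synthetic_config(rng_seed = 11),
                       K = fraction_K(43, 1083), rng_seed = 11)
res <- run_pipeline(cfg)
#> intersect_evidence: 43 coexpression, 49 textmining -> 40 consensus
#> classify_edges: 80 both, 448 coexpression-specific, 0 textmining-specific

res
#> <pipeline_result: 43 predicted coexpression genes, 49 textmining genes,
#>  40 consensus; network 83 nodes>
attr(res$predicted$pairs, "report")
#> <selection_report: K=550 over 43 seed x 1083 universe genes = 1.18%;
#>  cutoff 0.2409 (2.9 sd)>

evaluate_recovery(res)$chip
#>      tf recall false_call_rate
#> 1 NR1D1      1               0
#> 2 NR1D2      1               0
#> 3 ARNTL      1               0
```

Reading the output: 43 genes survived the co-expression tightness filter
and 49 genes came from the text-mining stream; their intersection — the 40
consensus genes — is exactly the planted target set (precision and recall
1.00 on this seed), and extends the 43-gene seed into an 83-node layered
network. The selection report shows the implied |ρ| cutoff (0.24, i.e. 2.9
background standard deviations) behind the 1.18% selection fraction. All
three simulated transcription-factor peak sets recover their planted
targets at the default log2 threshold with no false calls.
`res$report` lists each consensus gene with its validation flags
(per-TF target, circadian, RNAi phenotype class, disease), and
`run_pipeline(cfg, out_dir = "out")` writes every stage artifact plus a
reproducibility manifest — same config and seed, byte-identical files.

Individual stages are plain functions (`pearson_matrix()`, `mutual_rank()`,
`select_top_pairs()`, `compute_tightness()`, `overrepresentation()`,
`top_partners()`, `closest_gene_scores()`, `jtk_scan()`,
`assemble_ncrg()`, ...) and can be used on real data files independently of
the orchestrator.

## Package data

`inst/extdata/` ships small plain-text fixtures: the 43-gene two-layer seed
network (core-clock gene names are canonical; extension membership is a
synthetic stand-in, hence the `_synthetic` suffix), a published consensus
annotation table and GO enrichment reference encoded as TSV, and a 10-gene
clock-similarity list. The methods vignette
(`vignettes/circanet-methods.Rmd`) documents the models, defaults, and the
design decisions behind them.
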