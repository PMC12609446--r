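# asconserve

Comparative analysis of alternative splicing (AS) across related plant
genomes, including allopolyploids. `asconserve` is aimed at comparative
transcriptomics work in which per-species gene models, junction/element
read counts and orthogroup tables already exist (from an assembly +
orthology pipeline) and the questions are: which AS events exist, how do
they differ between tissues and species, and which individual events are
conserved across species and subgenomes deeply enough to suggest
function?

## What it computes

* **Event detection** — the four primitive AS types are enumerated by
  pairwise comparison of each gene's transcript isoforms: intron
  retention (IR: an intron of one isoform spanned exactly by an exon of
  another), exon skipping (ES: an internal exon bypassed by a direct
  neighbour junction), and alternative donor/acceptor (A5/A3: introns
  sharing one boundary, differing at the other, with overlapping variant
  exons). Events are kept only when the variable element is supported by
  strictly more than 3 pooled reads in a sample.
* **PSI and differential splicing** — percent spliced in,
  `PSI = inc/(inc + exc)`; events *present* at `0 < PSI < 1`; between two
  tissues, `ΔPSI = |PSI₂ − PSI₁|` with an exact two-sided binomial test of
  the condition-2 counts against the condition-1 PSI. Significant events
  (`ΔPSI > 0.2`, `p < 0.05`) are classified as **gain** (near-constitutive
  in tissue 1, intermediate in tissue 2), **loss** (the mirror image) or
  **DAS** (the remainder). Distribution-level shifts are compared with
  two-sample Kolmogorov–Smirnov tests.
* **Sequence features** — GC content and length of skipped exons and
  retained introns versus the genome-wide background (exons/introns never
  involved in the respective event type), compared by Wilcoxon rank-sum
  tests.
* **Exon homology and conservation** — within single-copy orthogroups
  (single copy per genome unit: a diploid genome, or one subgenome of an
  allotetraploid), exon sequences are aligned all-vs-all
  (Smith–Waterman, match +2 / mismatch −3 / gap 5+2L, Karlin–Altschul
  e-values) and reciprocal best hits with `e ≤ 1e-5` and ≥60% coverage on
  both sides form the exon homology reference set. IR/ES events of two
  species are conserved when their skipped exon (ES) and
  transcription-order flanks map through RBH pairs; conserved pairs are
  merged into multi-species clusters by connected components, summarized
  by species-sharing level and by subgenome combination.
* **Synthetic cohort generator** — a five-species cohort (two diploid,
  three allotetraploid with A/B subgenomes) with planted events, planted
  conservation structure, planted PSI and binomially simulated replicate
  counts, plus exact truth tables, so the entire pipeline is testable
  end to end.

## Worked example

```r
library(asconserve)

co  <- generate_cohort(cohort_config(n_orthogroups = 40L, seed = 42L))
res <- run_pipeline(cohort = co)

res$summaries$conservation$leaf$by_type
#> # A tibble: 2 x 5
#>   event_type n_clusters n_events n_genes share_pct
#> 1 ES                  8       24      21      22.2
#> 2 IR                 28       88      84      77.8

res$summaries$decline$leaf
#>   species_level n_clusters_at_least
#> 1             2                  36
#> 2             3                  24
#> 3             4                  11
#> 4             5                   5

res$feature_tests$leaf
#>    as_class     measure median_as median_background  p_value
#> 1   ES_exon gc_fraction     0.337             0.403  4.3e-09
#> 3 IR_intron gc_fraction     0.538             0.420  1.3e-42
#> 4 IR_intron   length_bp    87                133     2.0e-31
```

Reading: of the 36 conserved AS clusters called in leaf tissue, 77.8% are
intron retentions; the number of clusters falls monotonically with the
number of species sharing them (36 at ≥2 species down to 5 shared by all
five); and retained introns are markedly GC-richer (median 0.54 vs 0.42)
and shorter (87 vs 133 bp) than background introns, while skipped exons
are GC-poorer — the planted biases recovered through the full detection
and filtering stack.

`run_pipeline(..., out_dir = "out/")` additionally writes each stage's
TSV (events, support, PSI, differential events, RBH pairs, per-tissue
clusters) and a JSON run manifest with the configuration, seed, row
counts and file checksums; rerunning the same seed reproduces identical
files.

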