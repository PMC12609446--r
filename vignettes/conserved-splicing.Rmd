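---
title: "Detecting and comparing conserved alternative splicing across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing conserved alternative splicing across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparative surveys of alternative splicing (AS) ask two linked questions:
how does the splicing landscape of a clade change as genomes diverge and
polyploidize, and which individual splicing events are conserved across
species deeply enough to suggest function? `asconserve` implements the
post-alignment half of such a survey for a cohort of related plant species
that includes both diploids and allotetraploids. The package consumes gene
models (GTF), genome sequences (FASTA), junction/element read counts and
orthogroup membership tables; upstream read processing, transcript
assembly and orthology inference are out of scope and are consumed as
inputs.

## Event model

Events are defined from annotation alone, by pairwise comparison of the
transcript isoforms of each gene, and read support is applied afterwards
as a filter — the same order of operations as annotation-driven event
generators. Four primitive types are enumerated, with all coordinates held
0-based half-open internally (GTF conversion happens only at the I/O
boundary):

* **IR** — transcript 1 splices an intron between two exons; transcript 2
  carries a single exon with exactly the same outer boundaries.
* **ES** — an internal exon of transcript 1 is absent from transcript 2,
  whose junction joins the two neighbouring exons directly.
* **A5 / A3** — two transcripts use introns sharing one boundary and
  differing at the other, with the requirement that the two variant-side
  exons overlap; the *donor* is the 5' splice site in transcription
  orientation, so the genomic side of an A5/A3 label depends on strand.

The overlap requirement on A5/A3 variant exons matters: without it, every
exon-skipping junction would also masquerade as an alternative-acceptor
pair with the canonical intron. Complex patterns (mutually exclusive
exons, multi-exon skips) are reported only insofar as they satisfy one of
the four primitive definitions.

Each event's identifier is a pure function of the gene, the type and the
defining coordinates, so duplicates found from different transcript pairs
collapse deterministically (first occurrence supplies auxiliary flank
fields). Two feature keys link each event to the count table: the *body*
of the variable element (retained intron, skipped exon, extended segment)
evidences the inclusion form, and the *junction* of the spliced form
evidences exclusion. "Reads containing the specific element" is read
literally: the support filter keeps an event in a sample only when its
variable element has strictly more than `min_reads` (default 3) pooled
reads, so four reads pass and three fail.

## PSI and differential splicing

PSI is the read-based inclusion fraction `inc / (inc + exc)` on pooled
replicate counts, undefined at zero depth. An event is *present* in a
sample when `0 < PSI < 1` (strict). Between the two tissues of a species,
the package computes `ΔPSI = |PSI_root − PSI_leaf|` and an exact two-sided
binomial test of the root counts under the null that the inclusion
probability equals the leaf PSI (clipped to `[1e-6, 1 − 1e-6]`). Events
with `ΔPSI > 0.2` and `p < 0.05` (strict on both) are significant and are
partitioned into exactly one of three classes:

* **gain** — leaf PSI above 0.95 or below 0.05 while root PSI is
  intermediate;
* **loss** — the mirror image;
* **DAS** — every other significant event.

These tissue-anchored definitions are kept verbatim even though "gain
with extreme PSI in the leaf" can read counterintuitively; swapping the
tissue labels maps gain to loss and leaves DAS fixed, which the property
suite asserts. No multiple-testing correction is applied by default so
that the raw `p < 0.05` rule is preserved; distribution-level comparisons
between species or tissues use the two-sample Kolmogorov–Smirnov test on
the PSI values of present events.

## Sequence features

GC content is `(G+C)/(A+C+G+T)` counted case-insensitively, with
ambiguous bases excluded from both numerator and denominator. The
contrasts compare skipped exons against exons never skipped anywhere in
the annotation, and retained introns against introns never retained —
"background" is genome-wide, not per-gene, and each unique interval
contributes a single observation however many transcripts reuse it.
Group differences use the two-sided Wilcoxon rank-sum test, exact for
tie-free combined samples of at most 20 and normally approximated (with
tie correction) otherwise.

## Exon homology and conservation calling

Within each single-copy orthogroup — single copy evaluated per *genome
unit*, i.e. one unit per diploid genome and one per allotetraploid
subgenome, so a tetraploid may contribute one gene in A and one in B —
the reference exons of every gene pair are aligned all-versus-all.
Alignment is exact Smith–Waterman (match +2, mismatch −3, gap open 5, gap
extend 2) through `Biostrings::pairwiseAlignment()`; an exact DP pass was
preferred over a seeded heuristic because the exon sequences are short,
it removes any micro-exon special case, and a two-pass strategy
(score-only everywhere, full alignments only for best-hit candidates)
keeps the cohort-level cost low. Expectation values use the
Karlin–Altschul formula with λ solved from the scoring scheme under
uniform base composition and K fixed at 0.35; the effective search space
is the query length times the total exon length of the partner gene. The
calibration differs from any particular external aligner, but the
conservation logic depends only on pass/fail at `e ≤ 1e-5` and ≥60%
aligned coverage of **both** sequences, which is insensitive to the
constant over the divergence range tested. Coverage is the aligned span
over the sequence length; best-hit ties break deterministically by higher
identity, then lower opposite exon rank.

A pair of same-type events from different species is *conserved* when
they lie in the same orthogroup and their anatomy maps through reciprocal
best hits: for ES the skipped exons must be an RBH pair and each
transcription-order flank must match its counterpart (upstream with
upstream, downstream with downstream); when a flank is absent on both
sides — a terminal skipped exon — the requirement applies only to the
single available flank. For IR both flanks must match, which enforces
"the same pair of flanking exons" without accepting any stray RBH within
the gene. Calls are per tissue; an event must already have passed the
read-support and presence filters to participate.

Conserved pairwise calls become edges of a graph whose connected
components are the conserved clusters (transitive merging across the
orthogroup, matching organization by family and exon-number identifiers);
a strict-clique mode exists for sensitivity analysis. A cluster's
*species level* counts distinct species — the two subgenomes of one
tetraploid never raise it, though subgenome-resolved sharing is tabulated
separately for the allotetraploid units.

## The synthetic cohort and what it does (not) show

The generator emulates the study design end to end so that every stage
has exact ground truth: five species (two diploid, three allotetraploid
with subgenomes A and B) share 200 single-copy orthogroups of 4–8-exon
genes; each unit's sequence diverges from the ancestor by independent
point substitutions (default 5% per branch, so up to ~10% pairwise);
planted events of the four types (weighted toward IR, as in real plant
annotations) are realized as extra isoforms at homologous positions in a
species set whose size follows a decreasing sharing distribution; and
replicate counts are binomial draws from planted per-tissue PSI values at
depth 100 × 3 replicates. Retained-intron candidates are generated
GC-richer (0.55 vs 0.40) and shorter, and skipped-exon candidates
GC-poorer (0.32), reproducing the direction of the published biases so
the feature contrasts can be sign-checked.

Three generator choices keep the truth tables exact and deserve
explicitness. Substitutions only (no indels), so exon coordinates remain
homologous by construction; an aligner stress mode is deliberately out of
scope. Planted events within an orthogroup occupy disjoint intron
windows, so isoform combinations never create unplanned events — adjacent
retention/skip/boundary-shift isoforms otherwise interact and produce
extra event pairs. Conserved (multi-species) events carry intermediate
PSI in both tissues, because a conserved event with PSI at 0.98 would
occasionally be observed at exactly 1 and fail the presence filter,
turning cluster recovery into a coin flip on sampling noise; gain/loss
classes are planted only on species-specific events, at PSI 0.98/0.02
against an intermediate partner so that classification power at the
simulated depth is essentially 1.

Consequently, passing the planted-truth criteria shows that the
detector, the RBH machinery and the conservation logic are correct and
deterministic under realistic divergence and depth — it does not show
robustness to indels, assembly artifacts, unequal depths, or boundary
drift of real annotations, all of which degrade real data before this
pipeline sees it.

## Numerical choices and degenerate inputs

* Thresholds are strict inequalities exactly as printed: support `> 3`,
  presence `0 < PSI < 1`, `ΔPSI > 0.2`, `p < 0.05`, gain/loss bounds
  `> 0.95` / `< 0.05`.
* The binomial null probability is clipped to `[1e-6, 1 − 1e-6]`; zero
  total reads in the tested condition make an event unclassifiable and it
  is omitted rather than guessed.
* Events missing from the support table count as zero reads and are
  dropped with a warning tally.
* An empty PSI sample is an error for the KS comparison, as is an empty
  group for the Wilcoxon test; single-transcript genes yield an empty
  event set, not an error.
* Deterministic output ordering by (chrom, start, id) everywhere, and a
  single integer seed fixes the whole cohort.

## Problem sizes

The shipped configuration runs 200 orthogroups × 8 genome units
(~1,600 genes, ~2.7 Mb of genome) through the full pipeline, dominated by
the ~200,000 exon-pair alignments of the homology stage; the oracle
test sweeps 10,000 random multi-isoform genes against an exhaustive
pairwise-definition oracle. These sizes exercise every code path at
full statistical power while remaining desk-scale.

## Known limitations

* A3/A5 conservation is not called — the conservation analysis is
  restricted to IR and ES, whose flank anatomy maps cleanly through exon
  RBH.
* PSI uses pooled replicates; replicate-level dispersion models
  (beta-binomial) are out of scope.
* The e-value calibration is internal; users wanting bit-exact parity
  with an external aligner should treat the thresholds as configuration.
* Real GTF dialect coverage extends to Ensembl-style attributes only.
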