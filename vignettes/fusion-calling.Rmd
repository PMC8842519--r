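---
title: "Calling gene fusions from long transcriptomic reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene fusions from long transcriptomic reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longfuse)
```

## The problem

A long cDNA read that maps to two different genes is a *chimeric read*. Only
a minority of chimeric reads witness a *gene fusion* — a genomic deletion,
inversion or translocation that physically joins two genes so they are
transcribed together. The rest are *read-throughs* (transcriptional
chimeras spliced from two adjacent same-strand genes, with no genomic
event behind them), *trans-splicing* products, or artifacts: template
switching during library preparation and basecaller segmentation errors
both produce *random pairings* of unrelated molecules. In typical long-read
transcriptome data the artifact classes dominate by an order of magnitude,
so the hard part of fusion calling is not finding multi-gene reads but
deciding which of them mean anything.

`longfuse` takes spliced long-read alignments (PAF), a GTF annotation and
optionally the read sequences, and emits a ranked fusion call set in which
every chimeric gene-pair cluster carries one of four labels:

* `PASS:GF` — gene fusion (random-pairing null hypothesis rejected),
* `PASS:RT` — read-through,
* `FAIL:RP` — random pairing,
* `FAIL:LowSupport` — fewer supporting chimeric chains than the threshold.

## Exon chains

Each read's alignments are reduced to *segments*: pairs of a read interval
and a genome interval with a mapping direction $D \in \{-1, +1\}$. All
coordinates are 0-based half-open internally; GTF (1-based closed) and
UCSC-style tables are converted at the boundary. Consecutive segments less
than 10 nt apart on both the read and the genome (measured in the direction
of mapping) are merged, absorbing the small indels typical of long reads.
Segments are then annotated with every exon their genome interval overlaps
— with no minimum overlap, since a fusion breakpoint may clip an exon to a
handful of bases — giving the match list $M$ of 6-tuples (read interval,
genome interval, direction, exon interval, gene, transcript).

A dynamic program selects the subset of $M$ that best explains the read:
the *exon chain*. Writing $w_c = \mathrm{overlap}(I_G^c, I_e^c) \cdot
|I_G^c|$, where overlap is the reciprocal overlap (intersection over the
larger interval), the score of a chain ending at $c$ is

$$S[c] = \max\Big(w_c,\; \max_{p \in \mathrm{parents}(c)} S[p] + w_c \cdot
\mathrm{penalty}(c, p)\Big)$$

with penalty 1 for staying on one transcript, 0.9 for switching isoform
within a gene, and 0.5 for switching gene. A parent must end on the read
before the child starts (with half-open intervals, $r_e^p \le r_s^c$ —
adjacent segments do not overlap) and, when the directions agree, the
genome intervals must advance in the direction of mapping on the same
chromosome; opposite directions and different chromosomes carry no
genomic-order constraint, so inversion and translocation fusions chain
naturally. The penalty ordering means a single-isoform explanation always
beats a multi-isoform one of equal exonic content, and any single-gene
explanation beats a two-gene one: a fusion is only called when the read
genuinely cannot be explained by one gene.

Two consequences of this objective are worth knowing. First, because every
position may also restart a chain ($S[c] \ge w_c$), a very short head-gene
contribution can lose to the gene-switch penalty on the first tail exon:
if the head part's score is smaller than half the next exon's, the optimal
chain drops the head gene and the read is classified normal. This is the
regime of fusions whose head gene contributes only tens of bases (the
simulator exposes it via `short_head_fusion`). Second, ties are broken
toward the lowest index against a deterministically ordered $M$, so
results are exactly reproducible.

Reads are classified from their chains: several genes → chimeric, one gene
→ normal, no chain → intergenic. When read sequences are available, chain
entries whose read interval is more than 70% a single base (A, C, G, T, N
counted separately, case-insensitive) are removed — unclipped poly-A tails
are otherwise happily chained onto spurious exons — and the read is
reclassified.

## Filtering ambiguous chimeras

Three filters discard chimeric chains that are better explained by mapping
ambiguity than by chimeric molecules. Chains whose genes have overlapping
gene bodies are dropped (reads over overlapping loci cannot distinguish a
fusion from ordinary transcription of either gene; this is known to
sacrifice real fusions between overlapping genes, and the accounting keeps
such drops visible). Chains joining genes recorded as homologous — from a
transcriptome self-alignment, or a user-supplied pair list — are dropped.
Chains whose two gene bodies are linked by a segmental-duplication interval
pair are dropped; the lookup is symmetric in the two regions. The filters
are pure per-chain predicates, so their application order is irrelevant,
and they run before clustering so dropped chains contribute to neither
cluster support nor expression. Gene bodies (min exon start to max exon
end) are used for both the overlap and the segmental-duplication filters;
the mapped intervals of the individual chain are deliberately not used, so
the decision is a property of the gene pair, not of one read.

## Characterizing clusters

Gene expression $E_G$ is estimated as the count of single-gene chains of
$G$ — the natural unit here, since chimeric chains are counted in the same
currency. Chimeric chains are clustered per unordered gene pair; the head
gene is the gene appearing first on the majority of supporting reads, with
ties to the lexicographically smaller id. Clusters with fewer than 3
supporting chains (configurable) are set aside as low-support.

**Random-pairing test.** If chimeras between $A$ and $B$ arose by random
pairing at per-read rate $p_{rp}$, one expects about $\mathrm{mean}(E_A,
E_B) \cdot p_{rp}$ of them. With $n = \mathrm{round}(\mathrm{mean}(E_A,
E_B) + N_{A:B})$ and $k = \mathrm{round}(n \cdot p_{rp})$ (half-up
rounding; exact tests need integer counts), the one-tailed Fisher exact
test on the table $[[N_{A:B}, k], [n - N_{A:B}, n - k]]$ gives the
probability of observing at least $N_{A:B}$ chimeras under the null — the
hypergeometric survival probability at $N_{A:B} - 1$ with population $2n$,
$n$ draws and $N_{A:B} + k$ successes. The p-value is monotone
non-increasing in $N_{A:B}$, as evidence should be. $p_{rp}$ defaults to
0.01, matching the random-pairing rate the simulator injects; it is a
modelling constant, not a fitted one, and is exposed in
`fusion_config()`. Because clusters share member genes and the global
$p_{rp}$, the tests are dependent, so the Benjamini–Yekutieli step-up
procedure — valid under arbitrary dependence — adjusts the p-values
(`stats::p.adjust`, method `"BY"`), with rejection at FDR 0.05 by default.

**Read-throughs first.** Read-through transcription cannot be separated
from random pairing by the expression test, so read-throughs are
identified before testing, by three conjunctive rules: same chromosome,
same strand, gene bodies strictly less than 500 kb apart; FiN below 0.5;
and more than 80% of the cluster's chains joining the head gene's
second-to-last exon to the tail gene's second exon (ranks are
transcription-order and strand-aware, and are checked against the
transcript each chain actually used, since isoforms differ in exon
count).

**Scores.** The FiN (fusion-inverse-normal) score
$\mathrm{FiN}_{A:B} = N_{A:B} / (1 + E_A + E_B)$ separates the three
chimera classes: near 0 for random pairings between expressed genes, small
but positive for read-throughs (the members still transcribe normally),
and large for fusions — up to the full fusion read count for homozygous
events, whose member genes no longer produce normal reads. The ff-igf
score ranks accepted fusions by partner promiscuity: with $PG_G$ the set
of partners $X$ whose cluster with $G$ has more than one supporting chain
(computed over all clusters, including low-support ones) and $F$ the set
of retained clusters,
$$\text{ff-igf}_{A:B} = \ln(1 + |PG_A \cap PG_B|) \cdot
\ln\!\frac{|F|}{1 + |PG_A| + |PG_B|},$$
so a gene seen with many partners — at most two genuine fusions are
possible per diploid gene — drags its clusters down the ranking. Final
`PASS:GF` calls are sorted by descending ff-igf.

## The simulator

`simulate_config()` / `make_toy_reference()` / `simulate_reads()` build a
fully synthetic dataset with known truth, at desk scale, emulating the
design used to benchmark long-read fusion callers:

* a random genome (default 4 chromosomes × 1.2 Mb) with non-overlapping
  single-isoform genes (3–8 exons of 100–300 bp, introns 0.2–1 kb,
  intergenic gaps 30–50 kb), log-normal expression (mean 85 reads,
  floor 20 — events are seeded into expressed genes, as validated fusions
  are by construction detectable genes);
* 16 fusions, 10 homozygous and 6 heterozygous, as deletions (same-strand
  pairs ≥ 500 kb apart), inversions (opposite-strand pairs) and
  translocations (different chromosomes). A heterozygous fusion is
  expressed at 50% of its head gene and halves both members' normal
  expression; a homozygous fusion takes 100% and silences both members.
  Junctions keep at least two exons on each side, reflecting that
  validated fusions retain a substantial 5′ head portion; the deliberately
  hard single-80-bp-head case is a flag (`short_head_fusion`), as is one
  fusion between overlapping genes (`overlapping_fusion`);
* read-throughs between adjacent same-strand genes at 5% of head
  expression, containing all exons except the head's last and the tail's
  first — exactly the junction structure the read-through classifier
  expects;
* random pairings: 1% of reads are selected and concatenated two by two.

Alignments are synthesised from the known coordinates (one PAF record per
exon segment) with ±2 bp uniform wobble on genome interval ends, so the
pipeline is tested hermetically, without a mapper. What this does *not*
emulate: sequencing error in the bases (only interval wobble), secondary
or ambiguous mappings, multi-isoform genes, expression estimated from real
cell lines, and mapper-specific artifacts. Passing tests on this fixture
therefore validate the chaining, filtering and statistical machinery —
not robustness to real alignment noise.

```{r example}
cfg <- simulate_config(seed = 7, n_chroms = 2, genes_per_chrom = 8,
                       n_fusions = 3, n_homozygous = 2,
                       n_read_throughs = 2, mean_expression = 40)
e2e <- run_end_to_end(cfg)
e2e$result
e2e$metrics$fusion_recall
e2e$metrics$ari
```

## Evaluation

`pair_counting_ari()` scores a predicted clustering against truth by read
pairs: TP pairs co-clustered in both, TN in neither, FP only in the
prediction, FN only in the truth, and
$\mathrm{ARI} = 2(TP \cdot TN - FN \cdot FP) / ((TP+FN)(FN+TN) +
(TP+FP)(FP+TN))$. Reads the pipeline leaves unassigned are counted as
singleton clusters. The implementation is cross-checked in the test suite
against an independent ARI routine (`mclust::adjustedRandIndex`).

## Numerical and design choices

* Half-open 0-based coordinates everywhere; conversions only at file
  boundaries. The chain parent condition $r_e^p \le r_s^c$ is the
  half-open rendering of "the parent's read interval ends before the
  child's starts" — adjacent intervals share no base.
* All boundary comparisons are strict as documented: merge gaps `< 10`,
  low complexity `> 0.70`, read-through distance `< 500000`, FiN `< 0.5`,
  junction ratio `> 0.8`, support `< 3` for low-support.
* Counts entering the exact test are rounded half-up (`floor(x + 0.5)`),
  avoiding R's round-half-to-even for reproducibility across platforms.
* One chain per read: lacking a principled criterion for emitting
  secondary chains, only the optimal chain is reported; chains touching
  more than two genes are clustered by their first two genes in read
  order.
* If two segments of a read overlap on the read (a mapper artifact), the
  longer is kept and the shorter truncated.
* Expression uses chains, not raw reads; with one chain per read the two
  coincide.
* Default problem sizes (a few thousand reads, ~80 genes) are chosen so
  the full simulation-to-evaluation cycle runs in well under a minute on
  one CPU; all statistical behaviour of interest already manifests at
  this scale.

## Limitations

Breakpoints are reported at exon resolution, not base pair; fusion isoform
structure is not reconstructed. Trans-splicing is not a separate class:
low-expression trans-splicing lands in `FAIL:RP`, high-expression in
`PASS:GF`. Fusions between overlapping genes are filtered by design. The
ff-igf score is a ranking heuristic with values of order unity; only its
order matters. Mapping itself is out of scope — the package consumes PAF
produced by any spliced mapper.
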