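---
title: "De novo ChIP-seq analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo ChIP-seq analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dechip)
```

# The problem

Standard ChIP-seq analysis aligns reads to a reference genome, calls
peaks, and searches the peak sequences for binding motifs. When no
usable reference exists — non-model organisms, or heavily rearranged
cancer genomes — that first step is unavailable. `dechip` analyses a
transcription-factor ChIP-seq experiment without any genome: the case
(ChIP) reads are assembled directly into contigs we call *ChIPtigs*,
each representing a putative bound region; case and control reads are
then mapped back onto the ChIPtigs, which are ranked by a binomial
enrichment statistic; and motifs are discovered in the top-ranked
ChIPtigs by a discriminative word search. A seeded simulator with
planted motif sites provides ground truth so that every stage is
testable offline.

# The two assemblers

## De Bruijn graph (Velvet-style)

Nodes are k-mers (default $k = 17$, odd so no k-mer equals its own
reverse complement; even $k$ is still handled); edges are exact
$k-1$-base overlaps. Because bound fragments produce reads from both
genome strands — with anti-correlated Watson/Crick read abundance
around binding sites — every node is paired with its
reverse-complement twin. We store the lexicographically smaller of the
pair ("canonical" k-mer); the twin is implicit, and the test suite
checks twin symmetry of the edge set after every stage. Simplification
follows the usual sequence:

* **Linear merging.** Chains of nodes with unique in/out edges are
  merged into unitigs (done in C++ at build time, re-applied in R after
  every deletion).
* **Tip clipping.** A dead-end chain of cumulative length $< 2k$ is
  removed, *provided* its mean coverage is strictly below the best
  competing branch at the attachment point. The coverage condition is
  not part of the stated length rule but prevents clipping genuine
  short contig ends; it matches Velvet's behaviour.
* **Bubble collapse (Tour Bus).** After merging, the alternative paths
  of a bubble are single nodes attached to the same oriented
  neighbours. Groups of parallel paths are examined in decreasing
  coverage order, and a path is absorbed into the deepest one when
  their global-alignment identity is at least `bubble_identity`
  (default 0.8; coverages are summed). Nested bubbles resolve by
  iterating to a fixpoint with re-merging in between. This grouped
  formulation replaces the original breadth-first traversal; on graphs
  whose bubbles are substitution-induced the two coincide. As a fast
  path, equal-length pairs use Hamming identity and a length-ratio
  bound rules out hopeless pairs before any alignment.
* **Coverage pruning.** Nodes with mean k-mer multiplicity below
  `min_node_coverage` (default 2.0) are deleted.

ChIPtigs are the remaining node sequences of length at least 50 bp,
reported on the lexicographically smaller strand, ids assigned in
decreasing mean-coverage order.

## Consensus profile assembler

The second assembler treats each ChIPtig as a left-to-right per-column
emission model learned from an ungapped stack of reads. Clusters are
seeded greedily: k-mers are visited in decreasing multiplicity, and
each k-mer still carried by at least `min_seed_depth` (default 4)
unconsumed reads founds a cluster of all such reads, aligned by the
shared k-mer. Column emissions start from base frequencies with a 0.1
pseudocount. Extension alternates right and left: unassigned reads
containing the terminal $k$-column consensus word and agreeing with the
consensus on at least 90% of overlapping columns are incorporated in
batches of 20 with the discounted online update

$$\varepsilon^{(r+1)} = \alpha\,\varepsilon^{(r)} +
  (1-\alpha)\,\varepsilon^{(R)},$$

applied to transition and state counts alike, with
$\alpha(r) = 1 - (r+2)^{-0.8}$ by default. The published description of
this update says the discount "goes down" with $r$, which would let
late reads dominate and contradicts its stated purpose of stabilising
the model; we implement the stabilising direction and keep the schedule
injectable (`online_schedule()`), so the other direction is one
argument away. Overhanging bases create new columns.

**Entropy stopping.** A column whose base distribution has Shannon
entropy above `max_entropy` (default 0.6 nats) signals that the stacked
reads come from different genomic origins; extension stops there and
the side is trimmed back to its last clean column. Two choices deserve
note:

* *Natural log.* 0.6 sits between a pure column (0) and a 50/50 column
  ($\ln 2 \approx 0.693$), which is what makes the rule discriminative;
  in bits the same threshold would allow 50/50 columns through.
* *Observed frequencies, no pseudocount.* Entropy for the stopping rule
  is computed on raw count frequencies. With the 0.1 pseudocount a
  clean depth-1 column would score 0.75 nats and always be trimmed, so
  contig ends — where depth is necessarily 1 — could never be exact.
  Pseudocounts are still used for emissions and PWMs.

At finalisation every column above the threshold is dropped and the
longest contiguous clean run is reported (so the invariant "all
finalised columns satisfy the bound" holds for interior columns too),
and remaining unassigned reads that align to the final consensus are
recruited, which is why a uniformly covered single source yields
exactly one ChIPtig rather than several overlapping ones. The model is
match-columns only — no insert/delete states — because ChIP-seq reads
derive from contiguous DNA and the error model here is
substitution-dominated.

# Ranking

ChIPtigs shorter than 50 bp or longer than 500 bp are discarded (bound
regions are not expected to be much longer than 500 bp). Case and
control reads are mapped by a seed-and-extend exact-12-mer index with
full-length ungapped verification allowing 2 mismatches; each read
counts once, for its best hit. With $x_1$ case and $x_0$ control reads
on a ChIPtig and $r$ the case/control ratio of *mapped totals*, the
enrichment P-value is the binomial tail

$$p = \sum_{k=x_1}^{x_1+x_0} \binom{x_1+x_0}{k}
 \left(\tfrac{r}{r+1}\right)^{k}\left(\tfrac{1}{r+1}\right)^{x_1+x_0-k},$$

computed through the regularised incomplete beta function. The source
description also offers "$r = x_1/x_0$" per ChIPtig, but that choice
makes the null equal the observation and the P-value degenerate, so the
global ratio — the sentence's plain reading — is used. Ranking is by
ascending $p$, ties by descending $x_1$ then id; the top 1,000 go to
motif discovery. No multiple-testing correction is applied to the
ranking (BH q-values are emitted as an informational column only).

# Motif discovery

The background is a seeded dinucleotide-preserving shuffle of the
positive set (Altschul–Erickson Eulerian-path shuffle; mono- and
dinucleotide counts are preserved exactly, per sequence). Each round
enumerates every exact word of length 3–8 present in the positives,
scores it by the one-sided Fisher exact test on sequence-containment
counts (both strands, each sequence counted once), generalises the best
word greedily over IUPAC superset symbols, records the motif with
$E = p \times (\text{number of exact words evaluated})$, and erases its
matches (replaced by N, which matches nothing) before the next round.

**Calibration caveat.** This $E$ is anti-conservative: the greedy
generalisation repeatedly keeps the best of roughly 80 candidates
evaluated on the same data, a selection the Bonferroni factor does not
cover. Under a motif-free null we measure a motif reported at
$E \le 0.05$ in a majority of runs, whereas the exact-word stage alone
is well calibrated (the best exact word crosses $E \le 0.05$ at about
the nominal 5% rate). We keep the specified construction — it is the
documented, DREME-like procedure, and the pipeline's ranking use of
motifs is ordinal — but treat reported E-values as scores, not
significance levels. The corresponding acceptance test is left failing
with this analysis rather than silently recalibrated.

The database matcher (`compare_to_database()`) is a deliberately simple
stand-in for TOMTOM: best mean per-column Pearson correlation over all
offsets with at least 4 overlapping columns, query tried on both
strands, with an empirical P-value from 1,000 column-shuffled versions
of each target. Its E-values are not TOMTOM's; the tests only rely on
self- and reverse-complement-match sanity checks.

# The simulator and what a green test establishes

`simulate_experiment()` emulates: a uniform-composition genome
(`gc_fraction`, default 0.5), `n_sites` (200) sites of an 8-bp PWM
planted at least 200 bp apart (the default PWM has consensus
`TGACTCAG` with 0.85 per-column dominance — the information content of
a typical JASPAR vertebrate motif), fragments of 150 ± 20 bp truncated
to `[read length, 3 x mean]`, and 36-bp single-end reads taken from the
5' end of a uniformly chosen fragment strand with 0.5% substitution
error. A case fragment is site-derived with probability
$w/(w+L)$, $w = \text{fold} \times n_\text{sites} \times
\text{fragment mean}$, which makes the per-bp fragment start rate in
site fragments exactly `enrichment_fold` (10) times background; site
fragments cover the site centre at a uniform offset, reproducing the
anti-correlated strand geometry. Not modelled: PCR duplicates,
mappability/GC bias, indel errors, paired ends. A green test therefore
establishes correctness of the algorithms under substitution-only noise
and uniform background — not performance on real libraries.

One structural property of this stated world matters for interpreting
the acceptance results: 50,000 case reads on a 100 kb genome put the
*background* at ~4.5x coverage, enough for background k-mer chains to
survive assembly. Site contigs (whose enriched zone is already ~two
fragment lengths wide) therefore frequently extend past the 500 bp
filter: all 200 planted sites assemble, but most land in over-length
contigs, capping the fraction of site-overlapping ChIPtigs among the
top-ranked at roughly 60%. At `enrichment_fold = 1` the effect is
extreme — the whole genome assembles into a handful of multi-kb contigs
and the [50, 500] filter retains nothing. The affected acceptance
criteria are implemented as stated and left failing with this analysis;
the module-level tests use a sparser world (3,000 reads on 20 kb) where
site contigs stay within the filter and the pipeline demonstrably
recovers the planted motif.

# Numerical and determinism choices

* All tail probabilities (`pbinom`, `phyper`) are computed via the
  regularised incomplete beta / hypergeometric CDFs, never naive sums;
  independent log-space summation oracles back the tests. Strict
  monotonicity of the binomial tail holds wherever the tail is
  representable below 1 in double precision.
* Every source of randomness takes an explicit seed; pipeline stages
  derive their streams from the master seed by stage name, so stages
  are reproducible independently. Identical configuration and seed
  give byte-identical outputs.
* Ties: bubble groups resolve by coverage then lexicographic sequence;
  consensus bases by A < C < G < T; read mapping by fewest mismatches,
  then ChIPtig order, then + strand, then leftmost position; motif
  candidates by P-value then word.
* k is limited to 26 so canonical k-mer codes survive the round trip
  through R doubles exactly.

# Known limitations

Indel sequencing errors are not modelled and the profile assembler has
no insert/delete states; the bubble collapser examines single-node
parallel paths (nested bubbles need the fixpoint iteration); the
discovery E-value is anti-conservative as discussed; and the TOMTOM
stand-in is a correlation matcher, not a motif-comparison statistic
with calibrated nulls.
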