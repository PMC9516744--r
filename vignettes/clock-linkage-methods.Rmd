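---
title: "Methods: detecting conserved genetic linkage of gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting conserved genetic linkage of gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntlink)
```

## The question and the measurement

Plant genome evolution is dominated by cycles of polyploidy and
fractionation. After a whole-genome duplication (WGD) every gene exists
twice; most duplicates are then deleted, frequently with a bias against
one parental subgenome, and rearrangement further shuffles what remains.
Conserved gene order is therefore the exception, and a pair of
*non-homologous* gene families that remains co-chromosomal — and moves
*closer* together — across independent lineages and WGD events is
evidence of selection on the linkage itself. The motivating case is the
circadian clock: the sMYB transcription-factor sub-clades (LHY/CCA1 and
RVE4/8) in linkage with the pseudo-response regulator sub-clades (PRR5/9
and PRR3/7), plus the light-signaling pair PIF3–PHYA.

The package measures linkage tightness as the number of protein-coding
genes strictly between two loci on one chromosome: loci at ranks $r_a$
and $r_b$ are $|r_a-r_b|-1$ genes apart, so adjacent genes are 0 apart.
Strand is ignored and non-coding genes are excluded from ranking — the
count is defined on the same gene universe the protein-based homology
step sees. In fragmented or giant genomes (bryophytes, gymnosperms)
gene-count thresholds are less meaningful, so `find_linkages()` also
offers a physical mode (start-to-start bp distance, default threshold
12 Mb) mirroring the Mb-scale linkages seen in mosses and conifers.
The printed literature is not perfectly consistent about whether such
counts are strict or include one endpoint; this package is strictly
exclusive throughout, which makes "0 apart" mean adjacent.

## Pipeline stages and their parameters

**Similarity and the C-score (default 0.7).** Input is any 12-column
tabular alignment file (column 12 = score), or the built-in k-mer scorer
(`k = 4` amino acids) for simulated proteomes. The C-score of a pair is
its score divided by the larger of the two genes' best scores; the 0.7
default keeps pairs that are at least 70% as good as the best hit of
either gene, a relative-best-hit filter that tolerates the many-to-many
homology WGDs create where reciprocal-best-hit filtering would not. The
threshold boundary is inclusive ($\ge 0.7$); "best match in either
genome" is read as the *maximum* of the two best scores, the stricter of
the two possible readings. The built-in scorer drops pairs sharing fewer
than `min_score = 2` k-mers: a singleton chance k-mer would otherwise be
some unrelated gene's *best* hit and sail through any relative filter —
on random test proteomes such noise chained into spurious blocks.

**Tandem collapsing (gap 5 ranks).** Members of a tandem array hitting
the same partner are collapsed to the highest-scoring representative
before chaining, so an array contributes one anchor, not a cloud.

**Block chaining (min 5 pairs, max gap 20 genes).** Anchors grouped by
chromosome pair are chained by sparse dynamic programming, separately
for forward and reverse orientation: ranks strictly increasing on side
a, strictly monotone on side b, with the rank gap between consecutive
anchors at most 20 on both sides. These are gap semantics in the
DAGchainer style — chains may skip genes — not a fixed 20-gene window
partition. Block score is the sum of anchor scores (no gap penalty);
blocks are extracted greedily by descending chain score, each anchor
used at most once, ties broken by chromosome pair and start rank, and
chains under 5 anchors discarded. On every anchor set of up to 12
anchors the DP score equals exhaustive enumeration over all valid
chains (tested on 500 random sets).

**Self-synteny (diagonal offset 30).** Within-genome paralog blocks are
found the same way after removing anchors within 30 ranks of the
self-diagonal on the same chromosome; the offset must exceed
tandem-array scale while keeping genuine intra-genome WGD blocks, and
it is exposed as a parameter.

**Family assignment (min C-score 0.3) and split-model merging.**
Families are anchored to a curated seed panel (label → seed proteins) —
a deliberate replacement for de-novo orthology clustering, because the
analysis is panel-driven: each gene joins the family of its
best-C-score seed, and equal-best ties across families are flagged
ambiguous and excluded from linkage scans. Runs of same-family genes
within 1 rank of each other merge into a compound unit (`"A_B"`), the
convention for loci split by gene prediction. A merged unit counts as
one gene in distance computations and its members are never counted as
intervening — distances are measured edge-to-edge between rank spans.

**Retention and the permutation null.** Cross-species retention reports,
per species, hits per linkage class and the fractions of species with at
least one hit, with both sMYB–PRR classes, and with more than one hit in
a single class (to 0.1%). The permutation null shuffles family labels
uniformly over all rank slots genome-wide, preserving family sizes and
chromosome gene counts; the statistic is the minimum cross-family
intervening distance, infinite when the families never share a
chromosome (and infinity compares larger than any finite value). The
add-one estimator $p = (1 + \#\{perm \le obs\})/(n_{perm}+1)$ never
returns 0.

**Ks dating.** Codon alignments are protein-guided: global affine
alignment (BLOSUM62, gap open 10, extend 0.5) back-translated codon-wise;
gap columns are excluded. The estimator is Nei–Gojobori (1986) with
Jukes–Cantor correction, chosen because it has a checkable closed form —
an independent brute-force path-enumeration oracle reproduces it to
1e-9 in the test suite. Two conventions are fixed deliberately: (i)
mutations to stop codons count as nonsynonymous in site counting, so
potential sites satisfy $S + N = 3\times$ usable codons exactly; (ii)
multi-substitution codons average observed differences over all
shortest mutational paths, excluding paths through stop codons, and
codons with all paths blocked are skipped and logged. $p_s \ge 3/4$ is
reported as saturated rather than extrapolated. A block's Ks is the
median over its non-saturated anchor estimates, requiring at least 3
usable anchors, and is binned to named WGD events by user-supplied Ks
intervals. The shipped `inst/extdata/wgd_bins_example.tsv` intervals are
illustrative only: published events are dated in million years, and the
Ks cutoff for a named event is genome- and method-specific, so real
analyses must calibrate their own bins.

## What the simulator emulates — and what it does not

`simulate_clade()` grows a clade from an ancestral genome (default 400
genes, 4 chromosomes, gene lengths 100–300 codons) through an event
script: speciation (nested, so the tree shape lives in the nesting),
WGD/WGT (every chromosome copied, subgenomes tagged), fractionation
(each duplicate group suffers one loss trial per extra copy at
`loss_rate`; the victim comes from the disfavored subgenome with
probability `bias`; a loss hitting a gene participating in a designated
family linkage is vetoed with probability `linkage_preservation` —
the explicit handle on the preferential-retention hypothesis, which
makes power analysis of the permutation test possible), inversions,
translocations, tandem duplication, and codon-level divergence.
Sequence evolution proposes single-nucleotide changes, rejects stops,
always accepts synonymous changes and accepts nonsynonymous ones with
probability dN/dS, stopping when accepted synonymous events reach a
Poisson draw with mean $dS \times S$ — so the target dS is substitutions
per synonymous site *including multiple hits*, exactly what NG86 + JC
estimates. Fractionation operates on duplicate groups only; singletons
are immune, matching the biology of post-WGD gene loss.

The truth set records every gene's full parentage, so true orthologs
(same ancestor copy at the species pair's most recent common ancestor),
WGD paralogs, true blocks, and true linkage states are all queryable,
and `evaluate_recovery()` scores detections at anchor, block (span
Jaccard ≥ 0.5 on both sides), and linkage (gene-pair identity) level.

What it does **not** emulate: intron/UTR structure (genes are single-exon
CDS), transposons and intergenic turnover, gene conversion between
homoeologs, rate variation among sites and lineages beyond the per-branch
dS, and assembly artifacts other than split gene models. Passing tests
therefore demonstrate the *algorithms* are correct and calibrated on
clean, fully-known histories — not that every real-genome complication is
handled; real analyses still depend on annotation quality (the split-model
merger exists precisely because real gene prediction is imperfect).

## Validation design and problem sizes

The package validates itself at these scales, chosen to finish in
minutes on one CPU while leaving no algorithmic branch untested:
chaining optimality on 500 random anchor sets of ≤ 12 anchors (where
exhaustive enumeration is feasible); NG86 against the path-enumeration
oracle on 100 random 10–50-codon pairs at 1e-9; permutation-p exactness
against complete enumeration on 6-gene toy genomes (within 3 binomial
SE); p-value uniformity over 200 neutral single-chromosome simulations
(Kolmogorov–Smirnov, α = 0.01) — single-chromosome by design, because
with several chromosomes the null statistic has a large atom at
"never co-chromosomal", which lands an atom of p-values at 1 and makes
a continuous-uniform comparison meaningless; end-to-end recovery on the
reference regime (two species, shared WGD, lineage-specific
fractionation at loss 0.4 / bias 0.7, dS 0.3 per branch, full linkage
preservation, 400 ancestral genes) requiring block and linkage recall
≥ 0.95; and Ks calibration at true dS ∈ {0.1, 0.5, 1.0} over 200 pairs
of 300 codons, median within 20%. `scripts/acceptance.R` recomputes all
of these from scratch under a caller-supplied seed.

## Numerical and degenerate-input choices

All randomness flows through explicit seeds; package functions restore
the caller's RNG state. The C-score boundary comparison uses a 1e-12
slack so `70/100` at threshold 0.7 is inclusive regardless of binary
representation. Empty inputs return typed empty tables (never NULL);
an empty anchor set yields zero blocks; a detection-free recovery
reports recall 0 and precision NA ("not applicable"). Chain
tie-breaking, block ids, and all written tables are deterministic:
`write_table()` sorts rows lexicographically by all columns, so equal
inputs give byte-identical files, and `run_scan()` manifests digest
identically across reruns.

## Known limitations

The chaining extractor is greedy per chromosome pair: after removing
the optimal chain, subsequent chains are conditionally optimal, which
is the standard practical choice but not a global joint optimum. The
k-mer scorer is a detectability device for simulated divergence
(reliable to dS ≈ 1 at the defaults), not a substitute for a real
aligner on real proteomes. NG86 assumes equal base frequencies and no
transition/transversion bias; with strong codon-usage bias it
underestimates high Ks, one reason saturated pairs are flagged rather
than used. The permutation null conditions on chromosome gene counts
but not on local gene density in bp, so it speaks to gene-rank
proximity, not physical clustering.
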