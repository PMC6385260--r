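---
title: "Methods: models, rules and design choices in genomescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in genomescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomescape)
```

`genomescape` re-implements, as tested and reusable functions, the bespoke
computational steps used in coral genome projects: assembly diagnostics,
gene-model reconciliation, repeat landscape analytics, a phylogenomic
screen for horizontally transferred bacterial gene clusters, a dN-ranked
selection scan, and differential-expression/co-expression hub analysis.
This vignette records the models behind each stage, the parameters that
matter, and the choices made where the original procedures were
underspecified.

## Sequence primitives

All sequence comparison rests on one deterministic global aligner
(Needleman–Wunsch through `Biostrings`) with match = 1, mismatch = 0 and a
gap cost of 1 per position. Identity is the number of matching columns
divided by the aligned columns between the first and last column in which
both rows carry a residue (terminal gap overhangs are excluded; internal
gaps count against identity). Coverage is the fraction of the shorter
sequence inside that aligned core. These definitions stand in for the
word-heuristic engine of Cd-hit at desk scale: they are exact,
order-independent, and checkable against a brute-force dynamic-programming
oracle, which the unit tests do. Where several alignments are co-optimal
the traceback is whatever the aligner returns; the alignment *score* is
unique and is what the oracle tests pin down.

`greedy_cluster()` reproduces the greedy-incremental clustering scheme:
sequences are sorted by descending length (ties broken by id so runs are
reproducible), and each sequence joins the first existing cluster whose
*representative* it matches at the identity cutoff with sufficient
coverage of the shorter sequence, else founds a new cluster. The identity
cutoffs used downstream — 0.85 for repeat-library deduplication, 0.97 for
collapsing near-identical gene models before read mapping, and
0.9/0.7/0.5 with 70% coverage for the whole-genome-duplication test — are
the values the upstream protocols prescribe, not free parameters.

`trim_alignment()` drops columns whose missing-data fraction ("-", ".",
plus `X` for protein or `N` for nucleotide — the trimming-tool convention,
since "missing" is otherwise undefined) is at or above the column
threshold (default 0.3), then rows at or above the row threshold (default
0.5), and repeats the two passes until nothing changes. The fixpoint
iteration is deliberate: dropping a row can push a surviving column back
over its threshold, and a filter whose output changes when applied twice
is a trap for pipelines; iterating to stability makes the operation
idempotent at the cost of (rarely) removing slightly more than a single
pass would. The inequality direction is `>=` on both thresholds, matching
the stated "≥30%" / "≥50%" rules.

`nj_tree()` delegates to the standard neighbor-joining implementation in
`ape`; it exists so that desk-scale screens can build trees without a
maximum-likelihood engine, and the tests confirm that additive distance
matrices are recovered exactly and known topologies are rebuilt with
Robinson–Foulds distance zero.

## Assembly diagnostics

*Genome size from coverage* is `floor(total mapped bases / mean
coverage)`: integer truncation is used because it reproduces the published
worked example exactly (21,356,890,318 bp at 23x gives 928,560,448 bp,
where the unfloored ratio ends in .6).

*The allele-frequency spectrum* bins per-SNP alternate-allele frequencies
(`alt / (ref + alt)`) into 50 half-open bins over [0, 1] (the final bin is
closed). A clean diploid assembly of a single genotype shows a mode at
0.5; a mode near 1 betrays collapsed haplotypes or haploid contamination.
The SNP type is restricted to biallelic records; multi-allelic rows must
be split upstream by the reader, since the upstream caller's internals are
not reproduced here.

*The haplotig scan* filters a self-alignment table to hits strictly above
an identity threshold (default 99%) on distinct contigs and reports the
longest survivor: large survivors indicate alternate haplotypes still in
the primary assembly.

*The WGD test* clusters the full proteome at several identity levels and
asks which cluster size dominates: a recent whole-genome duplication shows
a dominant size of 2, a purged assembly a dominant size of 1. Ties in the
histogram resolve toward the smaller size, which is the conservative
(no-WGD) reading.

## Gene-model reconciliation

Two prediction sets — ab initio and homology-based — are merged with
priority to the ab initio models. Overlap between two models means: same
contig, same strand, and gene-extent intervals (first exon start to last
exon end) intersecting in at least 1 bp. Gene extent was chosen because
the merge procedure never defines "overlap"; it is the most permissive
reading and is declared rather than silent. For each homology model H, in
genome order:

* **rule a** — if two or more *mutually non-overlapping* ab initio models
  overlap H, they are taken to be fragments of the locus H spans: H is
  emitted and those fragments are consumed;
* **rule b** — if exactly one ab initio model A shares the locus, H
  replaces A only when `completeness(H) − completeness(A) > 0.05`
  (absolute difference of coverage fractions — the simplest literal
  reading of "more than 5% higher");
* **rule c** — homology models overlapping nothing are added as-is.

Two or more ab initio models that all overlap each other and the same H
fall under neither rule; the package resolves this in favour of the ab
initio models (H is dropped), consistent with ab initio priority, and
records the decision in the provenance log. Every input model appears
exactly once in that log as emitted, consumed or replaced, which the tests
check as a conservation law, together with equivalence to a brute-force
rule-application oracle on hundreds of random locus configurations.

Completeness is reference-normalised: the fraction of reference-homolog
positions aligned to query residues under the global aligner. The
alternative (query-normalised) reading would make truncated models look
complete, which contradicts the purpose of the rule.

Model filtering discards CDS with in-frame stop codons, CDS whose length
is not a codon multiple (malformed), models with at least half their CDS
covered by repeat-library hits (the package consumes a precomputed
overlap table rather than embedding a search engine; the 0.5 fraction is
configurable), and models with atypical codon usage. Atypicality is not
defined by the upstream protocol, so the package declares one: the
Pearson correlation between a gene's 61-codon relative-frequency vector
and the genome-wide vector, discarding genes under r = 0.5 (configurable).
This flags transposon-like genes whose codon preference ordering differs
from the host's; very short genes are noisy under this statistic, which is
why the planted-truth test uses genes of several hundred codons.

Family expansion statistics use floored integer fold changes
(`floor(count_a / count_b)`), which reproduces the published top-expanded
families table, and the clade-partition logic defines: a *gain* as a
family present only in the focal clade; a *loss* as a family absent from
the focal clade but present in at least two other named groups (so the
family predates the split — the "loss" label would otherwise be
unfalsifiable); *shared* as present in the focal clade and at least one
other group.

## Repeat landscape

Repeat-library curation first deduplicates family consensi by greedy
clustering at 85% identity, keeping the longest consensus per cluster,
then discards families classified "unknown" that hit a protein database
(they are presumed gene fragments); classified families are always kept.
The masked genome fraction is the per-contig interval union of hits
(overlaps counted once) over the assembly length; the summary value is
rounded to the nearest integer percent while machine output retains full
precision.

Compartment assignment uses the hit midpoint: a hit whose midpoint falls
between two exons of a gene is intronic, in an exon exonic, otherwise
intergenic; UTR labels are applied only when UTR features are supplied,
since merged annotations often lack them. Midpoint assignment gives every
hit exactly one label, which is what per-compartment count tables require;
hits straddling a boundary are attributed to the side holding their
midpoint. The SCOR–intron analysis is a Spearman rank correlation
(mid-rank ties, two-sided p) between per-gene total intron length and
per-gene repeat-hit count.

## The HGT screen and GTA hallmarks

The screen automates a procedure that was originally a manual tree
inspection, so every automated call carries its supporting clade for
audit. Stages:

1. **Prefilter** — queries whose top hit (highest bitscore, ties by
   subject id) is metazoan are dropped; queries with no hits are not
   candidates.
2. **Representative selection** — two sets, combined: hits scanned by
   descending bitscore, accepted first-come-first-served with at most 6
   per phylum; then hits with alignment length ≥ 200 aa re-sorted by
   descending identity and scanned the same way. The same per-phylum cap
   applies to both sets (the procedure describes the second set only as
   "a second set", so the cap is exposed as configuration). The union
   preserves first-seen order and always contains the global best hit.
3. **Tree and provenance** — pairwise global-alignment distances
   (1 − identity) over the query and representatives feed neighbor
   joining; the tree is midpoint-rooted (the trees arrive unrooted and no
   rooting is prescribed; outgroup rooting is available). The provenance
   call reads the query's sister clade: the smallest ancestor clade
   holding the query plus at least one other leaf. All-non-metazoan
   sisters give `non_metazoan`, all-metazoan `metazoan`, mixed
   `ambiguous`. The sister-clade rule is the smallest unit of evidence
   that makes the 4-leaf reference cases decidable; requiring two or more
   non-query leaves would leave a query inside a two-leaf cherry
   permanently ambiguous.
4. **GTA hallmarks** — contiguous runs of non-metazoan genes are scored
   on four criteria: span within the 4–14 kbp window that gene transfer
   agents package; every gene intronless (single exon); physical
   contiguity (no interleaved host gene); and a metazoan-provenance gene
   on each flank. The per-criterion booleans are returned rather than a
   single verdict.

Expression of candidates is a lookup: mean normalised count per gene with
an `expressed = mean > 0` flag and no further thresholding, since the
biological claim is only "expressed, albeit at low levels".

## Selection scan

Ortholog pairs are aligned at the protein level, back-translated codon by
codon with the CDS (protein gaps become `---`), and codon columns with a
gap in either row are removed. Gaps are guaranteed to occupy whole codons
by construction; arbitrary nucleotide gaps are rejected rather than
repaired, because silently shifting a reading frame is worse than failing.

dN and dS come from the Nei–Gojobori (1986) counting method: per-codon
synonymous site fractions (changes to stop codons count as
non-synonymous), site counts averaged over the two sequences,
pathway-averaged difference counting for multi-hit codons with
stop-containing pathways excluded, and a Jukes–Cantor correction
`d = −(3/4)·ln(1 − (4/3)p)` per class, flagged undefined when `p ≥ 3/4`.
NG86 replaces the model-averaging estimator used upstream because it is
exact, dependency-free and oracle-checkable; the ranking statistic is dN
alone — chosen upstream precisely because it is robust to estimator
choice — so the substitution does not move the ranked set in any regime
the tests probe. Unit tests pin single-codon results to values computed
with an independent NG86 implementation, and a generative check confirms
dN/dS ≈ 1 when mutations are accepted blind to their effect.

The fast-evolving set is the top `round(fraction × n)` pairs by dN
(round half up, which maps 12,196 pairs at 10% to exactly 1,220; ties at
the cutoff break by pair id). Pairs with undefined dN are excluded from
ranking and their count reported, since ranking an undefined value is
meaningless. Enrichment uses the one-sided hypergeometric tail (the
over-representation convention of the upstream tool) with *no*
multiple-testing correction, matching the "single test p-value < 0.05"
rule; a two-sided variant is available by flag.

## DE filtering and the co-expression network

DE calls require an FDR-adjusted p below 0.05 (strict) and |log2 fold
change| ≥ 1 (inclusive) — the inequality directions are as stated by the
upstream protocol. BH is the FDR procedure, as in the upstream tool's
default. The co-expression graph connects genes whose Pearson correlation
on log2(x+1) values reaches the threshold in absolute value, with |r| as
edge weight; soft-thresholding and topological-overlap transforms of the
original network tool are deliberately *not* reproduced — module labels
may be supplied externally for enrichment. Hubs are nodes in the top
⌈fraction·n⌉ of *both* degree and unweighted Brandes betweenness
(endpoints excluded, unnormalised), boundary ties included so the result
cannot depend on node order; the legend phrasing "top 10% of degree and
betweenness" reads most naturally as an intersection, and a union variant
is exposed. Betweenness is tested against an exhaustive all-pairs BFS
path-counting oracle on every graph up to 60 nodes in the suite.

## The synthetic-data generators

The generators exist so that every stage can be tested against planted
ground truth with no downloads. One integer seed drives one named random
stream per generator (genome, hits, SNPs, expression), so adding a
generator never perturbs another's output and equal seeds give
byte-identical results.

The default genome carries 2 contigs of 60 kbp with 10 structured genes
each (1–5 exons of 150–450 bp, introns 200–1200 bp), a planted intronless
4-gene cluster of 300–380 codons per gene with 150–300 bp spacing — sized
so the cluster span always lies inside the 4–14 kbp GTA packaging window —
flanked by host genes, and 100 intronic plus 150 intergenic repeat copies
from 6 families, placed wholly within introns or intergenic gaps with
per-interval probability proportional to interval length (so repeat
prevalence correlates with intron length, as observed in coral genomes).
The perturbed prediction sets cover every merge rule in known proportions
(intact pairs, truncations above and below the completeness threshold,
split models, and single-predictor loci), so the reconciliation's correct
answer is known per locus.

Hit tables give host genes coral-topped hit lists with weak bacterial
hits below, and planted cluster genes bacterial-topped lists across three
phyla — eight hits in the leading phylum, deliberately above the
per-phylum cap of six so the representative selection is exercised — with
weak metazoan hits below. Subject sequences are mutated copies of the
query at the implied divergence, so alignment distances and the resulting
trees reproduce the planted provenance rather than merely asserting it.

SNPs draw alternate counts from binomial(depth = 30, p = 0.5) at 5,000
sites (a site with zero alternate reads is redrawn — it would not have
been called a SNP); a haploid-contamination mode with p = 1 provides the
negative control.

Expression simulates the 21-library stress design (3 treatments × 2
timepoints × 3 replicates plus 3 time-zero ambient controls) with
negative-binomial counts (dispersion 0.05, the replicate-level dispersion
of controlled-tank RNA-seq; gene-wise log2 means 5–9). Four co-expression
modules of 25 genes each sit at high expression (log2 means 8–10, where
count noise is small relative to signal) and share a per-module latent
factor standardised to unit sample variance — without the
standardisation, a module whose factor happened to be drawn with small
spread would lose its correlation structure wholesale, turning hub
recovery into a coin flip on the factor draw rather than a test of the
detector. The planted hub carries loading 2, members loading 1 with extra
noise of sd 0.45, so hub–member correlations (~0.84) clear an edge
threshold of 0.78 while member–member correlations (~0.72) mostly do not:
each module is star-like around its hub. Planted DE genes (20, half up,
half down, 3 log2 units in the heated samples) are placed at quantifiable
expression for the same reason — a down-shift from an already-low
baseline is undetectable at 3 replicates and would test the generator,
not the filter.

The per-gene DE statistic shipped with the generator is a pooled-variance
t-test on log2(count + 1) with BH adjustment. **This is fixture
machinery**, a stand-in that makes the DE filters exercisable end to end;
it is not a claim about negative-binomial inference, and its null
calibration (~5% at α = 0.05) is itself one of the acceptance checks.

What the generators do *not* emulate: read-level errors, mapping
ambiguity, assembly fragmentation, splice-site sequence, overlapping or
nested genes, repeat sequence actually written into the contigs (repeat
placements are coordinate truth), GC or codon heterogeneity along the
genome, and between-module expression correlation. Passing the planted
tests therefore demonstrates that the *rules and statistics* are
implemented correctly, not that the pipeline is robust to the failure
modes of real sequencing data.

## Problem sizes and numerics

The test and acceptance runs use the generator defaults above: 24-gene
genomes, 5,000-SNP tables, 200-gene × 21-sample expression matrices,
10–20 replicate seeds per recovery rate, and 300–1,000 replicates for the
type-I calibrations — sizes at which every stage, including the
end-to-end HGT screen, completes in seconds per replicate on one core.
Degenerate inputs raise typed conditions (`genomescape_error_*`) rather
than returning sentinel values: empty sequences, alphabet mismatches,
degenerate alignments after trimming, constant vectors in correlation,
zero reference counts in fold changes, undefined Jukes–Cantor corrections
(flagged in the result rather than thrown, since an undefined dS on a
saturated pair is a result, not a bug). Ties are broken lexicographically
by id everywhere a ranking feeds a decision, so all pipelines are
deterministic given their seed.

## Known limitations

* The identity backbone is exact but quadratic; it is a desk-scale
  stand-in, not a replacement for word-heuristic clustering at proteome
  scale beyond a few hundred sequences.
* The provenance call reads a single sister clade and ignores bootstrap
  support; it is conservative and auditable, not a phylogenetic test.
* NG86 with equal pathway weighting underestimates rates at high
  divergence relative to model-based estimators; within the dN-ranking
  use case this does not reorder the set materially.
* The codon-usage atypicality statistic is unreliable for genes under
  ~100 codons.
* The DE t-test stand-in is for fixtures; real count data should be fit
  with a dedicated negative-binomial framework and the resulting
  statistics fed to `de_filter()`.
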