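---
title: "Designing and tracking promoter-reporter (GFP) constructs at scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and tracking promoter-reporter (GFP) constructs at scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterforge)
```

## The problem

Many Arabidopsis genes show no detectable expression on microarrays, and
newly predicted intergenic genes have no expression evidence at all.  One way
to learn where such genes act is to fuse each gene's upstream regulatory
region to a GFP reporter, transform the construct into plants, and record
where fluorescence appears.  Doing this for hundreds of genes requires a
batch pipeline: select candidates from detection calls, extract a promoter
design template around each translation start, design Gateway-compatible
primer pairs under placement constraints, screen the primers genome-wide for
off-target annealing, append recombination tails, order oligos in 96-well
plates, and track every construct through cloning, transformation and
screening.  `promoterforge` implements that pipeline end to end on desk-scale
data, with a seeded synthetic-data layer so every step is testable without
any external download.

## Candidate selection

Genes are classified from per-array Affymetrix present/marginal/absent
(P/M/A) detection calls.  The present fraction is the number of P calls over
the number of arrays; marginal and absent both count as non-expressed.  A
gene with present fraction exactly zero is a *no expression* candidate; a
fraction strictly below 5% makes it a *low expression* candidate; a gene at
or above the threshold is *expressed* (the inequality is strict, so a gene at
exactly 5% is not a candidate — the boundary genes at 69 versus 70 present
calls of 1381 arrays fall on opposite sides).  Candidates with independent
MPSS (massively parallel signature sequencing) transcript evidence are
excluded.  The classifier operates on whatever call matrix it is given; it
does not assume a particular array count or probe-set mapping.

## Promoter template

The design template is the span from 3000 bp upstream of the translation
start through 150 bp downstream of it (the downstream span includes the ATG),
always oriented promoter → ATG → coding; minus-strand genes are
reverse-complemented at extraction.  When a gene model is available its
annotated start is used; unannotated candidates are anchored by exact-matching
the first 30 bp of their CDS against both strands of the genome, doubling the
anchor and retrying when it is ambiguous.  This exact-seed anchoring is a
deterministic stand-in for a spliced aligner and assumes the first exon is at
least as long as the anchor.

Genes closer than 3000 bp to a contig end are clipped, not dropped: the
achieved upstream/downstream spans are recorded, short-downstream templates
are flagged, and templates with under 2150 bp of upstream sequence are marked
undesignable because no legal product can fit.  How the original pipeline
handled genes with short upstream intergenic space is not recorded; clipping
with explicit flags is this package's choice.

## Primer design

On a full template (ATG at offset 3000) a primer pair must satisfy, as hard
constraints:

* product size between 2150 and 2650 bp, containing the 50 bp target window
  that starts at the ATG;
* left primer 5' end at least 2000 bp upstream of the ATG;
* right primer 3' end between 50 and 150 bp downstream of the translation
  start (counted from the A of the ATG inclusive), so the cloned fragment
  carries at least `floor(50/3) = 16` native codons into the reporter fusion.

Within those constraints candidates of 18-27 nt are filtered on melting
temperature (57-63 °C, optimum 60), GC fraction (0.20-0.80), absence of N
and of homopolymer runs longer than 5, and self-complementarity caps.
Survivors are paired and ranked by a penalty equal to the Tm deviations from
optimum plus the length deviations from 20 nt plus the Tm difference between
mates, all with weight 1; weights are exposed in `design_params()` and affect
ranking only.  Ties break deterministically by left start, right end, then
lengths.  `design_for_gene()` walks the ranked list, screening each pair for
specificity, and returns the first pair that passes — or a failure record
listing every rejection, since design failure is a value, not an error.

Melting temperatures use the unified nearest-neighbor table (stack
enthalpies/entropies with terminal initiation terms and the symmetry
correction for self-complementary oligos) at 1 M monovalent, converted to the
annealing strand concentration, then corrected to the working salt with the
Owczarzy reciprocal-temperature monovalent formula.  Default conditions are
50 mM monovalent and 50 nM total strand concentration, recorded in
`tm_conditions()`.  Test values are frozen against an independent
nearest-neighbor summation.

Self-complementarity is scored over all ungapped antiparallel self-alignments
with match = +1 and mismatch = 0: `self_any` is the best score anywhere,
`self_end` the best among 3'-anchored alignments.  Under this counting
convention a random primer scores about a quarter of the overlap length, so
the default caps (14 and 12) trim the dimer-prone upper tail; they are not
comparable to caps used with mismatch-penalized scoring schemes.

An `enforce_frame` option additionally requires the downstream offset to be a
multiple of 3.  It is off by default: the published picker settings impose no
frame constraint, and the reporter architecture tolerates either reading
because the recombination site contributes a linker.

## Specificity screening

A primer "hits" a locus when an ungapped alignment over its full length, on
either strand, reaches at least 80% identity (substitution-only matching: at
these lengths and thresholds indel-containing matches are rare, and the
ungapped rule keeps the oracle exact).  Overlapping windows on a strand merge
into one locus anchored at the best identity, ties leftmost.  A pair is
accepted when each primer has at most 3 loci; the bound is inclusive and the
intended locus counts, since every primer hits itself.  The original
description of "3 hits per pair of primers" is ambiguous between a per-primer
and a per-amplicon reading; the per-primer rule is the default and a stricter
mode capping convergent co-placements (`screen_params(mode = "amplicon")`) is
provided.

Two matchers implement the scan.  `brute_force_matches()` slides the primer
over every window of every contig — exact by construction, and kept as the
oracle.  `seeded_matches()` partitions the primer into `budget + 1` disjoint
exact seeds (budget = `floor(0.2 * length)`); by the pigeonhole principle any
window within budget substitutions contains an intact seed, so seeded results
equal the oracle whenever `(budget + 1) * seed_length <= length`.  If the
condition fails the function warns and falls back to brute force.  The test
suite asserts locus-set equality between the two on 100 randomized draws.

## Gateway output

Accepted pairs get the pipeline's partial attB tails prepended:
`aaaaagcaggct` on the left primer and `agaaagctggt` on the right.  The
printed 11-nt right tail is one G short of the 12-nt suffix of the attB2
adapter (`GGGGACCACTTTGTACAAGAAAGCTGGGT`); the package reproduces the printed
tail by default and offers `gateway_constants(standard_attb2_tail = TRUE)`
for the conventional 12-nt form — the discrepancy is documented, not
resolved.  Tails are stored lowercase, compared case-insensitively, and
emitted uppercase in order files.  Product bookkeeping covers both
amplification stages: stage 1 with the tailed gene-specific primers, stage 2
with the two universal 29-nt adapters completing the attB sites.  The
two-stage thermal programs (a touchdown from 63 to 58 °C with a 9-cycle
final block, then 19 cycles at 56 °C) are emitted as structured metadata
only; reaction chemistry is out of scope.  Plate layout fills 96-well plates
row-major with gene *k*'s left and right oligos at the same well index of
paired plates.

## Funnel tracking and PO analytics

Constructs move through an ordered funnel — primer designed, entry clone,
sequence confirmed, expression clone, Agrobacterium clone, dipped,
transgenic-positive, in soil, GFP-positive — with monotone stage statuses.
`success_rate()` reports 100 × (reached *to*)/(reached *from*), rounded
half-up to one decimal to match conventional percentage reporting.  On the
packaged reference counts this gives 74.8% (designed → entry clone), 75.4%
(dipped → transgenic-positive) and a GFP-positive share of transformed
constructs that rounds to 56%.  Two other published stage rates (94.4% and
79.7%) do not equal what their own printed counts give (442/469 = 94.2%,
353/442 = 79.9%); the package always computes from counts and leaves the
discrepancy documented here.

GFP observations are Plant Ontology (PO) coded per image at four screening
stages (selection plate at ~day 10, rosette, pre-flowering, flowering).  A
line's expression pattern is the union of its PO codes over stages; two lines
agree when their patterns are equal non-empty sets.  Since "same expression
pattern" was never formally defined in the source protocol, exact set
equality is the default and a relaxed non-empty-intersection mode is
available.  Each gene falls in exactly one category: consistent across
multiple lines, single recovered line expressing, one expressing line of
several, inconsistent, or no expression; consistent genes whose agreeing
lines span two or more floral-dip events are flagged independently
confirmed.  `summarize_po()` counts distinct promoters per code (a gene seen
on many images counts once), and `po_query()` answers code, gene and
tissue-substring queries.  The store is a directory of delimited tables — a
desk-scale stand-in for the original LIMS database role.

The packaged reference data carry the screen's aggregate outcomes (1,885
lines, 1,457 in soil, 761 expressing, 2,287 images, 3,371 PO assignments,
the 112/19/14/5 category split, 79 independent-dip promoters).  These depend
on laboratory events and unpublished line-level data, so they are fixture
metadata: the package consistency-checks them (the categories partition the
150 GFP-positive constructs) but never recomputes them.

## What the synthetic data emulate — and what they do not

`generate_genome()` builds i.i.d. background contigs at a chosen GC fraction
and plants genes (ATG + random coding bases) and off-target primer copies
with exactly the requested substitution count, end bases protected so seed
arithmetic stays exact.  Because the background has no repeat structure,
planted truths are provable: a verbatim planted 20-mer is, with overwhelming
probability, the only ≥80%-identity locus in a desk-scale genome.  Real
plant genomes violate this freely — repeat families, segmental duplications,
compositional skew — so passing tests demonstrate correctness of the
machinery, not field performance of the screen on a real genome.
`generate_call_matrix()` plants exact present counts, making label recovery
a certainty check rather than a statistical one.  `generate_funnel()` draws
a Bernoulli chain at the reference screen's realized per-stage rates, with
line counts (per-seedling success 1885/(266·9)), soil survival (1457/1885)
and per-line expression (761/1457) calibrated to the same source; it
emulates the funnel's shape, not laboratory failure modes.

Problem sizes used in the checks — 20-gene batches on 20 kb contigs, 100
matcher draws on genomes up to 100 kb, 200-gene call matrices over 1381
arrays — were chosen as the smallest sizes at which every constraint and
boundary case is exercised.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
  inclusive coordinates are converted at the boundary.
* Intervals beyond contig ends clip and report achieved bounds instead of
  failing; a translation start within 3 bp of a contig end is an error since
  no codon fits.
* N is legal in genomes but never in primers; windows containing N are
  rejected during enumeration, not at genome load.
* Gene models whose annotated start codon is not ATG are returned flagged,
  never silently dropped.
* Half-up rounding for percentages (base R rounds half to even).
* All generator randomness is seed-determined; identical spec and seed give
  byte-identical FASTA output.

## Known limitations

The anchoring step does not handle first exons shorter than the anchor.  The
Tm model implements one pinned convention (unified table, Owczarzy monovalent
correction); divalent cations and dNTP binding are not modeled.  The
specificity scan is ungapped and has no 3'-end-weighted mispriming model, no
E-values, and no thermodynamic mispriming score.  The picker does not
implement every penalty term of the original external design tool (no
secondary-structure free energies, no template mispriming term).  Category
analytics assume each line's observations are complete; missed observations
bias toward the no-expression category exactly as they would in the
laboratory.
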