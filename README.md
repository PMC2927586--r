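# promoterforge

Batch design and tracking of promoter-reporter (GFP) constructs for plant
genes with little or no expression evidence.

Hundreds of Arabidopsis genes show no detectable transcript on expression
microarrays, and predicted intergenic genes have no expression data at all.
A standard way to learn where such genes act is to clone each gene's
upstream regulatory region in front of a GFP reporter, transform the fusion
into plants, and record where fluorescence appears. `promoterforge`
implements the computational side of that pipeline:

* **Candidate selection** — classify genes from Affymetrix P/M/A detection
  calls (present fraction `#P / #arrays`; candidates show presence in none,
  or in strictly less than 5%, of the arrays) and exclude genes with MPSS
  transcript evidence.
* **Template extraction** — locate the translation start from annotation or
  by anchoring the CDS 5' prefix to the genome, and extract the region from
  3000 bp upstream of the ATG to 150 bp downstream of it, strand-aware and
  boundary-clipped.
* **Primer design** — enumerate and rank primer pairs under the pipeline's
  constraints: product size 2150–2650 bp containing the 50 bp target window
  at the ATG, left primer ≥ 2000 bp upstream of the ATG, right primer 3' end
  50–150 bp downstream of it (so the fusion carries ≥ 16 native codons),
  Tm 57–63 °C from unified nearest-neighbor thermodynamics with an Owczarzy
  monovalent salt correction.
* **Specificity screening** — count genomic loci matching each primer at
  ≥ 80% ungapped identity on either strand; accept a pair only if each
  primer has ≤ 3 loci (a primer always hits itself). A pigeonhole-complete
  seeded matcher provides the fast path; an exhaustive scanner is kept as
  the oracle it must agree with.
* **Gateway output** — prepend the attB tails (`aaaaagcaggct` /
  `agaaagctggt`), track expected two-stage product sizes against the 29-nt
  universal adapters, emit the two-stage touchdown PCR programs as
  structured metadata, and write 96-well plate order files.
* **Funnel tracking and PO analytics** — monotone stage statuses from primer
  design through GFP-positive lines, stage-to-stage success rates,
  GFP-consistency categories across transgenic lines, and Plant Ontology
  (PO) summaries and queries of where each promoter is active.

A seeded synthetic-data layer (`generate_genome()`, `generate_call_matrix()`,
`generate_funnel()`) plants genes, off-target primer copies, exact present
counts and funnel realizations so the whole pipeline is testable offline.

## Worked example

Design a construct for one synthetic gene planted on a 20 kb contig:

```r
library(promoterforge)

spec <- synthetic_genome_spec(
  seed = 1, n_contigs = 1, contig_length = 20000,
  genes = data.frame(gene_id = "g1", contig = 1, offset = 5000,
                     strand = "+", cds_length = 300))
gen <- generate_genome(spec)

tpl <- build_template(gen$genome, gen$models[["g1"]])
tpl
#> <promoter_template g1 len=3150 atg_offset=3000 up=3000 down=150>

pair <- design_for_gene(tpl, screen = specificity_screen(gen$genome))
pair
#> <primer_pair g1 accepted product=2462bp up=2348 down=114 penalty=0.21
#>   L ACCTCCCGGCCCGAGAGATA (tm=60.1)
#>   R AGCCCCCTAAACCGAGCACC (tm=60.1)>
pair$specificity
#> <specificity_report PASS: left 1, right 1 loci (max 3 @ >=80% identity, per_primer)>

check_coding_inclusion(tpl, pair)
#> $codons_included
#> [1] 38
#> $in_frame
#> [1] TRUE

add_tails(pair)
#> <tailed_primer_pair g1
#>   L AAAAAGCAGGCTACCTCCCGGCCCGAGAGATA
#>   R AGAAAGCTGGTAGCCCCCTAAACCGAGCACC
#>   stage1 2485 bp, stage2 2520 bp>
```

The template holds the full 3000 bp upstream span (ATG at offset 3000). The
accepted pair places its left primer 2348 bp upstream of the ATG and its
right primer 114 bp into the coding sequence (38 complete codons, in frame),
amplifying a 2462 bp product; both primers match exactly one genomic locus
(themselves), so the pair passes the ≤ 3-hit screen. Tailing prepends the
12-nt/11-nt attB sequences: the stage-1 product grows by 23 bp and the
stage-2 re-amplification with the universal adapters brings it to 2520 bp.

Funnel analytics on the packaged reference counts:

```r
counts <- load_funnel_fixture()
success_rate(counts, "primer_designed", "entry_clone")     # 74.8
success_rate(counts, "dipped", "transgenic_positive")      # 75.4

ps <- load_po_summary_fixture()
attr(ps, "n_distinct_codes")                               # 81
po_query(ps, tissue = "hydathode")
#>      po_code   po_name n_promoters
#> 1 PO:0005660 hydathode          35
```

A thin CLI (`exec/promoterforge`) wraps the same functions for shell use
(`prepare`, `design`, `order`, `funnel` subcommands).

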