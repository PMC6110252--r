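# pseudoscan

Classify the functionality of multi-exon gene copies — intact, partial,
defective (pseudogene), absent, or not determined — directly from genome
assemblies.

`pseudoscan` was built for gene-family loss surveys of the kind done for
the Tas1r umami/sweet taste-receptor genes across reptile genomes:
given (a) assemblies as FASTA scaffolds, (b) a query gene model (the
ordered coding exons of a reference gene), and (c) protein queries for
the two genes flanking the target in conserved synteny, it answers, per
species and gene, *is this gene still working, broken, incomplete, or
gone?* — with the full evidence trail for every call.

## Method in brief

1. **Translated homology search** (`find_loci`): six-frame translation
   of every scaffold, exact amino-acid 4-mer seeding, ungapped diagonal
   extension, then affine-gap Smith–Waterman (BLOSUM62, gap 11/1) on
   seeded windows; hits within 20 kb on one scaffold/strand merge into
   loci, reuniting exon hits across introns.
2. **Exon mapping & reconstruction** (`reconstruct_gene`): the locus is
   extended 5′/3′, each query exon is aligned semi-globally (exon
   end-to-end, target local), and found exons are stitched in gene
   orientation into the reconstructed CDS.
3. **ORF diagnostics** (`diagnose_orf`): indels are read off the exon
   alignments; a frameshift exists when a prefix sum of signed indel
   lengths is ≢ 0 (mod 3); the CDS is translated in the query-anchored
   frame to find premature stop codons (codons containing `N` are never
   stops).
4. **Transmembrane check** (`predict_tm_helices`): Kyte–Doolittle
   sliding-window hydropathy (window 19, threshold 1.6) counts the
   seven helices expected of an intact GPCR; externally computed TMHMM
   counts can be imported instead (`import_tm_prediction`).
5. **Synteny** (`check_flanking`): the two flanking-gene proteins are
   searched with the same engine; finding both certifies the
   neighborhood was assembled and licenses an "absent" call.
6. **Classification** (`classify_functionality`), first match wins:
   no/too-short (< 100 bp) hits → *absent* (neighbors found) or *not
   determined*; ≥ 1 premature stop → *defective*; `N` regions or missing
   exons → *partial*; 7 TM helices → *intact*, else *partial*.

A synthetic-genome simulator (`simulate_genome`, `simulate_panel`)
plants gene copies in all eight functionality states — with random
introns, flanking genes, and exact ground truth — so the entire
pipeline is testable without downloading an assembly.

## Worked example

```r
library(pseudoscan)

query     <- synthetic_query_gene(101)        # 6-exon, 7-TM gene model
neighbors <- synthetic_neighbor_proteins(202) # two flanking proteins

# plant one genome per functionality state (200-kb scaffolds)
panel <- simulate_panel(query, neighbors, seed = 42)

cfg <- pipeline_config(
  genomes   = panel$genomes,
  queries   = list(query),
  neighbors = setNames(list(neighbors), query$gene_name))
res <- run_pipeline(cfg)
res$calls[, c("species", "call", "rule")]
#>                     species           call                     rule
#> 1                sim_intact         intact         seven_tm_helices
#> 2             sim_partial_n        partial n_region_or_missing_exon
#> 3  sim_partial_missing_exon        partial n_region_or_missing_exon
#> 4            sim_partial_tm        partial     tm_helices_not_seven
#> 5  sim_defective_frameshift      defective           premature_stop
#> 6    sim_defective_nonsense      defective           premature_stop
#> 7   sim_absent_with_synteny         absent     no_or_too_short_hits
#> 8        sim_region_missing not_determined     no_or_too_short_hits
```

Every call matches the planted state. The defective rows carry the
per-exon indel bookkeeping, e.g. the frameshift genome's planted 7-bp
exon-2 deletion:

```r
format_indel_table(res)[, c("species", "exon2_deletion", "premature_stops")]
#>                    species exon2_deletion premature_stops
#> 1 sim_defective_frameshift           7 bp     19 at exon6
#> 2   sim_defective_nonsense              -      1 at exon3
```

(the exact stop tally depends on the panel seed; with this query model
the shifted frame first hits stop codons inside the codon-diverse
transmembrane exon), and
`summarize_matrix(res$calls)` renders the species × gene matrix with
`I/P/D/A/?` symbols, appending flanking-gene evidence to absent cells.
For real assemblies, supply FASTA paths in `genomes`, a query built with
`read_query_exons_fasta()` or `read_query_gff3()`, and the flanking
proteins as an amino-acid FASTA; `inst/scripts/pseudoscan.R` wraps the
same calls for shell use, and `inst/scripts/external_benchmark.R`
documents a full survey across real downloaded assemblies.

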