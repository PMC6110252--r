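---
title: "Classifying gene-copy functionality from genome assemblies with pseudoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene-copy functionality from genome assemblies with pseudoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether a species retains a working copy of a gene family member -- here,
the Tas1r umami/sweet taste-receptor genes -- can be read off its genome
assembly, provided one is careful about the distinction between *a gene
that is damaged*, *a gene that is incompletely assembled*, and *a gene
that is genuinely gone*. `pseudoscan` implements that survey as a
reusable pipeline. Given a genome assembly (FASTA scaffolds, possibly
containing runs of `N`), a query gene model (the ordered coding exons of
a reference gene, e.g. mouse Tas1r1), and protein queries for the two
genes flanking the target in conserved synteny, it produces one of five
calls per gene and genome, with the complete evidence trail:

* **intact** -- all exons recovered, no frameshift, no premature stop, no
  unsequenced region, and the translated protein shows all seven
  transmembrane helices expected of a GPCR;
* **partial** -- the coding region is recovered but incomplete: missing
  exons, `N` runs inside the coding sequence, or fewer than seven
  transmembrane helices;
* **defective** -- a pseudogene: the reading frame is disrupted by at
  least one premature stop codon (from a frameshift indel or a nonsense
  substitution);
* **absent** -- no usable homology hit, while *both* flanking genes are
  found, certifying that the neighborhood was assembled and the gene is
  really not there;
* **not determined** -- no usable hit and no flanking-gene evidence; the
  gene may be lost or the region may simply be unassembled.

The calls are produced by four rules applied first-match-wins, in the
order: absence check, stop-codon check, completeness check,
transmembrane check. The ordering embodies two judgements worth making
explicit. Defectiveness outranks partialness: a premature stop codon is
decisive damage, while an `N` run is mere uncertainty, so a gene showing
both is reported as a pseudogene (with the `N` evidence retained in the
call's evidence bundle). And a nonsense substitution without any
frameshift is treated as defective even though the field's bookkeeping
tradition emphasizes frameshift-induced stops -- both disrupt the open
reading frame identically; such calls carry
`caused_by_frameshift = FALSE` in their stop records so users can
re-label if they prefer the narrower definition.

## The pipeline

### Translated homology search

`find_loci()` is a seed-and-extend translated search (the role TblastN
plays in manual surveys). All six reading frames of every scaffold are
translated (`N`-containing codons become `X`); exact amino-acid 4-mer
seeds against the query protein are extended ungapped along their
diagonal (best contiguous segment, Kadane's algorithm); diagonals whose
segment scores at least `min_ungapped_score` (default 40) define
candidate windows, which are then aligned to the full query with an
affine-gap Smith-Waterman under BLOSUM62 (gap open 11, extend 1). Hits
on the same scaffold and strand within `merge_distance` (default 20 kb)
are merged into loci, so the exon-wise hits of a multi-exon gene,
separated by introns, reunite into one locus spanning the gene.

Two scoring choices matter. First, `X` scores zero against everything,
so unsequenced regions neither attract nor repel alignments. Second,
the hit threshold `min_hit_score` defaults to a raw score of 80: by
Karlin-Altschul statistics, a raw BLOSUM62 score of 60 on a six-frame
search space of a few hundred kilobases already has an expectation near
one chance hit per scan, which would corrupt absence calls, whereas 80
keeps the expectation below 0.01 while leaving even the shortest real
exon hit (a 50-residue exact match scores roughly 250) untouched. Both
are configurable through `search_params()`.

A locus is usable when it spans at least `min_hit_nt` = 100 bp;
anything shorter counts as "no hit" and routes to the synteny check.
This threshold is the survey's published criterion and is deliberately
expressed in genomic base pairs.

### Exon mapping and reconstruction

The locus window is extended `pad` bases (default 50 kb) in both
directions -- homology hits need not cover terminal exons -- and, for
minus-strand loci, reverse-complemented so all downstream work happens
in gene orientation. Each query exon is aligned semi-globally (exon
end-to-end, target local; match 2, mismatch -3, gap open 5, extend 2,
`N` scoring zero) inside candidate windows located by exact nucleotide
11-mer seeds, with a full-region alignment as fallback when no seed
exists. An exon counts as *found* when its score reaches 40% of its
self-alignment score **and** its column identity reaches 0.5. The
two-part threshold is deliberately permissive of failure: short exons in
poor-quality, `N`-rich regions legitimately fail to map (the real
surveys see exactly this for the short first exon of Tas1r1 in
turtles), and "not found" must remain a reachable outcome.

Found exons are stitched in gene order into the reconstructed CDS.
Out-of-order or overlapping exon placements are resolved by dropping the
lower-identity exon to missing, with a warning. Intron boundaries are
taken from the alignments themselves; no GT-AG splice-site model is
enforced, matching the exon-by-exon alignment strategy the pipeline
emulates (and letting the simulator use unconstrained random introns).

### ORF diagnostics

Indels are read directly off each exon alignment as maximal gap runs:
extra target bases are insertions, absent ones deletions, each with its
position on the query CDS. Gap runs touching an exon's first or last
aligned column are flagged `low_confidence` (alignment-edge
uncertainty) rather than dropped. A frameshift exists when, after some
indel, the running sum of signed indel lengths is not a multiple of 3 --
so in-frame indels never shift the frame and compensating pairs restore
it downstream of the compensation point.

Premature stops are found by translating the reconstructed CDS in the
*query-anchored* frame: codon boundaries start where the query's codons
start, and indels shift them exactly as they would in vivo, letting a
frameshift in exon 3 surface as stop codons in exon 6. One subtlety is
not defined by the survey tradition: what frame to use *after a missing
exon*, whose length is generally not a multiple of 3. Carrying the
frame naively across the junction would fabricate frameshifts out of
assembly gaps, so the scanner re-anchors to the query frame at each
contiguous block of found exons and never reports stops spanning a
junction. Codons containing `N` translate to `X` and are never stops;
the query's own terminal stop is never premature.

### Transmembrane check

The intact/partial boundary for a clean reconstruction is the
seven-transmembrane-helix architecture of the receptor. Rather than
bundling an HMM topology predictor, `predict_tm_helices()` uses the
classical Kyte-Doolittle sliding-window scan (window 19, threshold 1.6
-- the original recommendation for membrane-spanning segments; minimum
span 15, runs closer than 3 residues merged). This is a deliberate
stand-in: it is self-contained, deterministic and testable, and on the
clean helix/loop architecture the classifier consults it for, window
widths 17-21 give identical counts. It is *not* byte-compatible with
HMM predictors on real, marginal sequences; users wanting exact parity
can run TMHMM themselves and feed its short-format output in via
`import_tm_prediction()` and `pipeline_config(tm_counts = ...)`. A
span's reported `mean_hydropathy` is the mean over the qualifying
window scores of its run (the expanded span necessarily includes
sub-threshold flanking residues, so a span-wide mean would be
misleading). The classifier consults the count only when the
reconstruction is complete and `N`-free, so partial proteins are never
fed to the predictor.

### Synteny

`check_flanking()` searches the two flanking-gene proteins with the same
engine and declares a neighbor found at query coverage >= 30% and score
>= `min_hit_score`. The floor is permissive on purpose: the neighbors
are only evidence that the region was assembled, not objects of study.
Both neighbors are required for an absence call by default
(`require_both_neighbors = FALSE` relaxes to one); co-localization on
the same scaffold is recorded when determinable but not required, since
assembly fragmentation routinely splits conserved neighborhoods across
scaffolds. The check never looks at the target gene's own locus, so
absence evidence stays independent of the absence claim.

### Orchestration

`run_pipeline()` runs search, reconstruction, diagnosis, transmembrane
and synteny checks for every species x gene pair and emits a calls
table, a per-exon indel report in the field's tabular style ("1, 2, 8
bp" per exon, "2 at exon3" stop summaries), a synteny table, and the
full evidence per call. Everything is a pure function of the inputs:
reruns are byte-identical. An optional second pass (`refine = TRUE`)
re-searches unresolved genomes using intact reconstructions recovered in
the first pass as additional protein queries -- the classical
"iterate with your best finds" step; it runs exactly once, keeping the
pipeline's output a finite deterministic function of its inputs.

## The simulator, and what passing tests mean

`simulate_genome()` builds a random background scaffold (default 200 kb,
GC 0.41 -- a typical vertebrate composition), plants the query gene with
independent random introns (uniform 200-2000 bp, no splice-site
structure), plants the two flanking genes as single-exon
back-translations 25 kb away (beyond the 20-kb merge distance, so
neighbor hits never fuse with the gene locus), and applies the mutation
set of one of eight states: `intact`, `partial_n` (a 30-bp `N` block
inside a middle exon), `partial_missing_exon` (exon 1 replaced by `N`,
emulating an unsequenced short first exon), `partial_tm` (an in-frame,
codon-aligned deletion of one transmembrane helix), `defective_frameshift`
(a 7-bp exon-2 deletion -- the canonical snake pseudogene lesion),
`defective_nonsense` (a codon-aligned TGA substitution),
`absent_with_synteny` (gene not planted, neighbors planted) and
`region_missing` (nothing planted). The simulator validates that
defective-state mutation sets really produce a premature stop and
records every planted feature as ground truth. The bundled
`synthetic_query_gene()` emits a GPCR-shaped 833-residue protein -- long
hydrophilic N-terminal domain, seven 21-residue hydrophobic blocks
separated by 24-residue strongly hydrophilic loops -- back-translated
and split into six exons with a short (152 bp) first exon and a long
final exon carrying the transmembrane domain, mirroring the real gene
family's architecture.

What the simulator does *not* emulate is worth stating plainly: real
substitution divergence between query and target species, repeats and
segmental duplications, assembly chimerism beyond `N` blocks, splice
signals, and paralogs. Passing the recovery tests therefore shows the
pipeline's logic is correct on unambiguous inputs -- that planted states
are recovered exactly, indel bookkeeping is exact, and strand handling
is an involution -- not that its sensitivity matches NCBI TblastN on
diverged real genomes. The search and transmembrane stand-ins are the
two places where real-data behavior can diverge from any manual survey,
and both are swappable (parameters for the former, `tm_counts` import
for the latter).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open on the forward strand everywhere,
  with explicit strand flags; exon stitching and reverse-complement
  arithmetic are exact under this convention.
* IUPAC ambiguity codes other than `N` are normalized to `N` (with a
  warning): every downstream rule already treats non-called bases as
  assembly uncertainty.
* Ties among equal-scoring loci are broken by (scaffold, start) order
  for determinism; the empty local alignment scores 0, so all-mismatch
  pairs align with score 0 rather than a negative score.
* Zero-length indels cannot be represented or emitted; table cells like
  "0 bp" in published inventories are treated as "none recorded".
* A gene whose every exon fails to map raises a dedicated condition and
  is routed to the absence logic rather than producing an empty
  reconstruction.
* All randomness (simulator, back-translation) runs under local seeds
  that never disturb the caller's RNG stream.

## Problem sizes used in the validation suite

The packaged tests run the full pipeline on eight 200-kb single-scaffold
genomes (one per state) for the end-to-end recovery check, 40-kb
genomes for the 20-seed strand round-trip and the module-level
fixtures, 200 random pairs (length <= 30) for alignment-oracle
equality, and 200 single-indel exon-recovery trials. These sizes were
chosen as the smallest at which every component exercises its real code
path -- multi-exon merging needs introns, absence calls need enough
background for chance-hit statistics to matter -- while keeping the
whole suite comfortably fast on one CPU.

## Known limitations

* Sensitivity on diverged targets depends on exact 4-mer seeding; very
  fast-evolving genes may need a smaller `seed_k` or lower thresholds.
* The hydropathy scan cannot distinguish a signal peptide from a first
  transmembrane helix; for the gene family this package was built
  around, the classifier only consults the *count*, on complete
  reconstructions, where the distinction has not mattered in practice.
* One reconstruction per genome: a locus list with true paralogs is
  reported (all loci are returned, sorted), but downstream stages use
  the best locus only.
* E-value statistics are not computed; thresholds are raw scores.
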