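---
title: "Visualizing fusion genes with superTranscript references"
author: "fuseviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing fusion genes with superTranscript references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseviz)
```

## The model

A **superTranscript** is the intron-free union of all annotated exons of
a gene, laid out 5′→3′ in transcriptional direction. fuseviz constructs
it deterministically from the annotation: exon intervals across all
transcripts are merged (overlaps unioned), ordered by ascending genomic
coordinate for `+` genes and descending for `-` genes, and the sequence
of each block is extracted from the genome FASTA (reverse-complemented
for `-` genes). The *block map* records the bijection between exonic
genomic positions and superTranscript positions; it drives all liftover
of transcripts, protein domains and breakpoints. This is an
annotation-driven flattening, not an assembly from reads: it is
reproducible from GTF + FASTA alone and exactly testable against
per-base enumeration.

For a fusion call, the two breakpoints are assigned to genes by a
deterministic cascade — exon hit, then gene-span hit, then nearest gene
within a 10 kb window (ties broken by exon distance, then symbol). The
annotation's own symbols are always used; caller-reported symbols are
parsed but never trusted for identity, since naming conventions vary
widely between callers. The **fusion superTranscript** is the
concatenation of the full-length 5′-partner and 3′-partner
superTranscripts. Keeping both genes full length means reads from gene
regions *not* involved in the fusion remain visible, showing relative
expression of fused and non-fused portions. The offset where the 3′
gene begins is the *gene boundary* `b`; caller breakpoints are lifted
into fusion coordinates as the expected donor (< `b`) and acceptor
(≥ `b`).

The alignment reference contains every fusion sequence plus a normal
superTranscript for every gene *not* embedded in a fusion. Competitive
mapping against the non-fused genes prevents reads from normal
transcripts being spuriously attracted to fusion sequences. Partner
genes are deliberately excluded from the normals: their full sequence
already exists inside the fusion superTranscript, and keeping a second
copy would make every partner-gene read multi-mapping, hiding exactly
the coverage the figure is meant to show. This exclusion is the only
choice under which unique-mapping coverage of the partners is
observable, and it keeps the invariant that fusions and normals
together cover the annotated gene set exactly once.

Distinct breakpoint pairs on the same gene pair collapse to one
reference sequence — the sequence is breakpoint-independent because both
partners are full length — with every expected breakpoint kept as
metadata. This is what makes multi-isoform readouts possible: several
fusion isoforms of one gene pair appear as distinct junctions on a
single sequence.

## Split-read analysis

After splice-aware alignment to this reference, a fusion manifests as
splicing between the concatenated genes: a read whose CIGAR contains a
reference skip (`N`) crossing the boundary. The analysis:

* walks each primary, mapped, non-supplementary alignment's CIGAR;
  reference-consuming ops are M/=/X/D/N, but only M/=/X count as
  aligned flank and coverage;
* records each gap `[start, end)` with its left/right flanks — the
  aligned bases between the gap and the read's neighboring gap or read
  end (an interior segment between two gaps counts toward both);
* drops reads where any gap has `min(left, right) < min_flank`
  (default **5 bases**; exactly 5 is retained — *fewer than* 5 is
  removed). Short anchors are the signature of incorrect split
  alignment;
* aggregates junctions by exact `(refname, start, end)` — no fuzzy
  merging, since splice-aware aligners report exact gap edges and
  nearby isoform breakpoints must stay distinct;
* flags a junction as fusion-supporting when `start < b ≤ end`, and
  annotates the donor/acceptor dinucleotides read from the reference
  (canonical splicing gives `GT/AG`);
* marks junctions with support below `min_support` (default **3
  reads**) as not displayable; they stay in the raw junction table but
  draw no sashimi arc, suppressing spurious splicing events;
* normalizes coverage as RPM = raw × 10⁶ / library size, where the
  library size is the count of primary mapped records (each read
  counted once, avoiding double-counting of multimappers); a track can
  be normalized only once.

Total spanning-read support for a fusion is the sum of support over its
boundary-crossing junctions, reported per isoform with the distance to
the nearest expected breakpoint (`|start − (donor+1)| +
|end − acceptor|`, zero for a read splicing exactly where the caller
predicted).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_flank` | 5 | bases | minimum aligned anchor on each side of a gap |
| `min_support` | 3 | reads | minimum junction support for figure display |
| `window` | 10 000 | bases | maximum breakpoint-to-gene-span distance in assignment |
| coverage scale | RPM | — | raw × 10⁶ / primary mapped reads |

All are exposed as function arguments and CLI flags; the defaults are
the package's operating point and the values exercised by the test
suite.

## Handling degenerate input

* **Intronic breakpoints.** A breakpoint inside an intron has no image
  on the superTranscript. It is projected to the nearest exonic base
  and flagged (`donor_projected`/`acceptor_projected`, `~` suffix in
  the breakpoint BED) rather than dropped — the visualization stays
  usable without inventing sequence.
* **Unassignable breakpoints.** Calls whose breakpoints match no gene
  within the window are skipped, logged, and listed in the reference
  manifest with reasons; a build where *all* calls are unassignable
  aborts.
* **Same-gene events.** Both breakpoints assigning to one gene still
  build (a tandem-duplication-like reference) with a warning.
* **Name collisions.** Reference names are
  `<5′symbol>_<3′symbol>`, sanitized to SAM-legal characters, with a
  numeric suffix on collision.
* **Zero fusion calls** produce a normals-only reference with a
  warning; **zero-exon genes** in the GTF are excluded with a warning;
  `chr`-prefix mismatches between GTF/BED/call tables and the genome
  are reconciled automatically.

## The simulator, and what it does not emulate

`make_toy_locus()` builds one gene per toy chromosome with fixed-size
exons/introns, alternating strands, uniform ACGT sequence, and
canonical GT/AG dinucleotides planted at intron edges and at the
superTranscript-space edges of the intended fusion junction.
`simulate_fusion_alignments()` writes primary SAM alignments that
realize requested junctions at requested flank lengths (sequences
copied from the reference, so records are self-consistent), plus
unspliced background reads, and records the expected post-filter
outcome computed directly from the flank/support rules.

This emulates exactly the geometry the method operates on — gapped
alignments, flank lengths, junction multiplicity, boundary crossing —
and nothing else. There are no sequencing errors, no quality model, no
expression realism, no multi-mapping ambiguity, and no aligner: reads
are placed where the truth says. Passing tests therefore demonstrate
that the reference construction, liftover, filters, counting and
normalization are correct *given* an alignment, not that any particular
aligner will produce those alignments on real data. Real-data behavior
additionally depends on aligner stringency, which is out of scope here.

## Numerical and design choices

* All internal coordinates are 0-based half-open; GTF (1-based
  inclusive) and SAM positions are converted at the I/O boundary, BED
  is native. One convention internally eliminates off-by-one drift.
* The generic fusion-call dialect (`chrom1 pos1 strand1 chrom2 pos2
  strand2 sample`) uses 0-based positions; JAFFA/STAR-Fusion dialects
  convert from 1-based on read.
* `genome_to_st` returns `NA` for non-exonic positions — not exonic is
  a value, not an error; `st_to_genome` bounds-checks strictly.
* Domain features are positional annotations: they are lifted by
  coordinates only, ignoring feature strand, and may split across
  blocks (rows share the name).
* Boundary-crossing uses `start < b ≤ end`; a junction starting exactly
  at `b` does not cross (its donor base is already in the 3′ gene).
* Figures default to uncompressed vector PDF with creation/modification
  timestamps zeroed after rendering, so identical input yields
  byte-identical output; colors default to the Okabe–Ito
  colorblind-safe palette.
* Exactly-5-base flanks are retained; the filter removes *fewer than*
  5.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: toy loci of 2–4 genes with 3 exons of 80–100 bp, liftover checked
against brute-force per-base tables on 200 random gene models (≤ 5
exons on a 500 bp chromosome, both strands), and 20 end-to-end
simulate→build→analyze rounds of ~30 alignments each. These sizes give
full coverage of the coordinate arithmetic and filter logic while the
whole suite completes in well under a minute.

## Known limitations

* Two-partner fusions only; no reference for three-way events.
* Split-read evidence only: read-pair (spanning-fragment) support is
  not counted, so support totals are conservative relative to callers
  that count both.
* Overlapping genes are flattened independently; a breakpoint in a
  region shared by two genes goes to the exon-level winner of the
  assignment cascade.
* No GFF3 input, no downloading of references, no live protein-domain
  database access (a precomputed domain BED stands in), and no
  built-in aligner — alignments are consumed as SAM/BAM.
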