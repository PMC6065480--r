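# fuseviz

Fusion-gene visualization for RNA-seq via superTranscript references.

## The problem

Fusion callers (JAFFA, STAR-Fusion, Pizzly, ...) report candidate gene
fusions as pairs of genomic breakpoints, but inspecting the evidence is
hard: against a genome reference the two partners sit on different
chromosomes and read coverage is shredded by introns. fuseviz builds a
compact, fusion-aware reference instead:

1. **superTranscript construction.** Each gene *g* is flattened to the
   union of its annotated exons, oriented 5′→3′ in transcriptional
   direction — a single intron-free sequence ST(*g*) with a block map
   linking every base back to the genome.
2. **Fusion reference.** For a called fusion with 5′ partner *A* and 3′
   partner *B*, the sequences ST(*A*) and ST(*B*) are concatenated
   full-length into one fusion superTranscript; the offset where *B*
   starts is the *gene boundary* b. The reference also carries the
   superTranscripts of all non-fused genes so reads map competitively
   and are not spuriously attracted to the fusion sequences.
3. **Split-read analysis.** After splice-aware re-alignment, a read
   supporting the fusion aligns with a gap (CIGAR `N`) crossing b.
   Split reads with fewer than 5 aligned bases flanking a gap on either
   side are filtered out as likely mis-alignments; junctions are keyed
   by exact gap coordinates, and junctions supported by fewer than 3
   retained reads are dropped from figures. Coverage is normalized to
   reads per million: RPM = raw depth × 10⁶ / (primary mapped reads).
4. **Tracks and figures.** Everything is emitted in reference
   coordinates as IGV-loadable FASTA/BED/bedGraph, plus multi-track
   figures (scale axis, coverage, gene boundaries, protein domains,
   transcripts, sashimi arcs labeled with read support) and a
   multi-sample overlay that stacks one coverage panel per sample.

A deterministic simulator generates complete toy studies (genome, GTF,
domain BED, fusion calls, spliced SAM alignments with known truth), so
the whole pipeline runs and is tested without external data or an
aligner.

## Worked example

```r
library(fuseviz)

dir <- tempfile("demo")
truth <- cmd_simulate(dir, seed = 42)          # toy study with a known fusion
analysis <- cmd_analyze(file.path(dir, "alignments.sam"),
                        file.path(dir, "reference"),
                        file.path(dir, "analysis"))
print(analysis)
#> <fusion_analysis> 2 junction(s), library size 30
#>   GENEA_GENEB: 10 spanning read(s), 2 isoform junction(s)

print(analysis$junctions)
#>       refname start end support crosses_boundary motif display
#> 1 GENEA_GENEB   100 400       6             TRUE GT/AG    TRUE
#> 2 GENEA_GENEB   100 500       4             TRUE GT/CC    TRUE

print(analysis$support[[1]]$isoforms)
#>   start end support motif display expected_donor expected_acceptor distance
#> 1   100 400       6 GT/AG    TRUE             99               400        0
#> 2   100 500       4 GT/CC    TRUE             99               400      100

cmd_plot(file.path(dir, "analysis"), file.path(dir, "reference"),
         file.path(dir, "figures"))
```

The simulated fusion joins GENEA (boundary at 300) to GENEB. Both
planted junctions cross the boundary: the canonical one splices exactly
at the expected caller breakpoint (distance 0) with 6 supporting reads
and the canonical GT/AG motif; the alternate isoform skips one further
exon (distance 100) with 4 reads. The total spanning-read support (10)
is the sum over boundary-crossing junctions. `cmd_plot` writes a
six-track PDF (axis, coverage, gene boundary, domains, transcripts,
sashimi) with the breakpoints drawn as vertical lines.

A thin command-line wrapper with the same subcommands
(`simulate | build | analyze | plot | run`) is installed at
`inst/cli/fuseviz`.

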