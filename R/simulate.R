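# Deterministic toy-data generator. Produces a complete miniature study:
# a genome with multi-exon genes on alternating strands, a GTF, a protein
# domain BED, a fusion-call table and spliced SAM alignments against the
# fusion reference with known truth (which junctions were planted, with
# how many reads at which flank lengths), so the whole pipeline is
# testable without an external aligner or any downloaded reference.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s)
  paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")

#' Generate a toy genome, annotation and intended fusion
#'
#' Builds `n_genes` genes, one per toy chromosome (`chrT1`, `chrT2`, ...),
#' with fixed-size exons and introns and strands alternating +/-.
#' Sequences are drawn uniformly over ACGT; canonical GT/AG dinucleotides
#' (in transcriptional direction) are planted at every intron edge, and at
#' the superTranscript-space edges of the intended fusion junction so that
#' the junction motif read from the fusion reference is `GT/AG`. Genes
#' with three or more exons get a second, middle-exon-skipping transcript.
#'
#' When `n_genes >= 2` the truth records an intended fusion joining the
#' 3' end of gene 1's first exon (the donor) to the start of gene 2's
#' second exon (the acceptor; first exon when the gene has only one).
#' Two protein domains are planted: one inside gene 1's first exon, one
#' spanning gene 2's second intron (so it splits across superTranscript
#' blocks).
#'
#' @param dir Output directory for `genome.fa`, `annotation.gtf`,
#'   `domains.bed`, `fusions.tsv` (generic dialect, 0-based positions)
#'   and `truth.json`. Created if needed.
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Exons per gene (>= 1).
#' @param exon_len Exon length in bases (>= 10).
#' @param intron_len Intron length in bases (>= 4; room for the motifs).
#' @param seed Random seed; identical seeds give identical files.
#' @return A `sim_truth`: list with `genome` (`genome_seq`), `genes`
#'   (`gene_set`), `domains`, `calls`, `fusion` (gene pair, genomic
#'   breakpoints and expected fusion-coordinate junction), file `paths`,
#'   and the `params` used.
#' @export
make_toy_locus <- function(dir, n_genes = 2L, exons_per_gene = 3L,
                           exon_len = 100L, intron_len = 200L, seed = 1L) {
  if (n_genes < 1L || exons_per_gene < 1L || exon_len < 10L ||
      intron_len < 4L)
    stop("invalid sizes: need n_genes,exons_per_gene >= 1, exon_len >= 10, intron_len >= 4")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  flank <- 100L
  chrom_len <- 2L * flank + exons_per_gene * exon_len +
    max(0L, exons_per_gene - 1L) * intron_len

  chrom_seqs <- list()
  gene_list <- list()
  for (i in seq_len(n_genes)) {
    chrom <- paste0("chrT", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    starts <- flank + (seq_len(exons_per_gene) - 1L) * (exon_len + intron_len)
    ends <- starts + exon_len
    # canonical splice motifs at intron edges, transcriptional direction
    if (exons_per_gene > 1L) for (k in seq_len(exons_per_gene - 1L)) {
      d <- ends[k]       # first intron base (genomic)
      a <- starts[k + 1L] - 1L  # last intron base
      if (strand == "+") {
        bases[d + 1L] <- "G"; bases[d + 2L] <- "T"
        bases[a] <- "A"; bases[a + 1L] <- "G"
      } else {
        # transcription runs right to left: donor GT is revcomp "AC" at
        # the intron's genomic right edge, acceptor AG is revcomp "CT"
        # at its left edge
        bases[a] <- "A"; bases[a + 1L] <- "C"
        bases[d + 1L] <- "C"; bases[d + 2L] <- "T"
      }
    }
    chrom_seqs[[chrom]] <- bases
    ex <- data.frame(start = starts, end = ends)
    transcripts <- list(t1 = ex)
    if (exons_per_gene >= 3L)
      transcripts$t2 <- ex[-2L, , drop = FALSE]
    names(transcripts) <- paste0("G", i, ".t", seq_along(transcripts))
    gene_list[[paste0("G", i)]] <- structure(
      list(gene_id = paste0("G", i),
           symbol = paste0("GENE", if (i <= 26L) LETTERS[i] else i),
           chrom = chrom, strand = strand, transcripts = transcripts),
      class = "gene_model")
  }
  genes <- structure(gene_list, class = "gene_set")

  fusion <- NULL
  if (n_genes >= 2L) {
    g1 <- genes[["G1"]]; g2 <- genes[["G2"]]
    bm1 <- make_block_map(g1$transcripts[[1]]$start, g1$transcripts[[1]]$end,
                          g1$strand, g1$chrom)
    bm2 <- make_block_map(g2$transcripts[[1]]$start, g2$transcripts[[1]]$end,
                          g2$strand, g2$chrom)
    donor_s <- exon_len - 1L                       # last base of exon 1
    acceptor_s <- if (exons_per_gene >= 2L) exon_len else 0L
    pos5 <- st_to_genome(bm1, donor_s)
    pos3 <- st_to_genome(bm2, acceptor_s)
    # plant the junction motif in superTranscript space: GT right after
    # the donor, AG right before the acceptor
    set_st_base <- function(chrom, bm, spos, base) {
      g <- st_to_genome(bm, spos)
      chrom_seqs[[chrom]][g + 1L] <<-
        if (bm$strand == "+") base else COMPLEMENT[[base]]
    }
    if (donor_s + 2L < bm1$total_length) {
      set_st_base(g1$chrom, bm1, donor_s + 1L, "G")
      set_st_base(g1$chrom, bm1, donor_s + 2L, "T")
    }
    if (acceptor_s >= 2L) {
      set_st_base(g2$chrom, bm2, acceptor_s - 2L, "A")
      set_st_base(g2$chrom, bm2, acceptor_s - 1L, "G")
    }
    boundary <- bm1$total_length
    fusion <- list(
      gene5 = "G1", gene3 = "G2",
      chrom5 = g1$chrom, pos5 = pos5, strand5 = g1$strand,
      chrom3 = g2$chrom, pos3 = pos3, strand3 = g2$strand,
      boundary = boundary,
      expected_donor = donor_s,
      expected_acceptor = boundary + acceptor_s,
      junction = c(start = donor_s + 1L, end = boundary + acceptor_s)
    )
  }

  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(chrom_seqs), function(ch) {
    s <- paste(chrom_seqs[[ch]], collapse = "")
    c(paste0(">", ch),
      substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59,
                                              nchar(s))))
  })), fa)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(genes, gtf)

  dom_rows <- character(0)
  if (n_genes >= 2L) {
    g1 <- genes[["G1"]]; g2 <- genes[["G2"]]
    e1 <- g1$transcripts[[1]]
    dom_rows <- sprintf("%s\t%d\t%d\t%s", g1$chrom,
                        e1$start[1] + 10L, e1$end[1] - 10L, "Receptor")
    if (exons_per_gene >= 3L) {
      e2 <- g2$transcripts[[1]]
      dom_rows <- c(dom_rows, sprintf("%s\t%d\t%d\t%s", g2$chrom,
                                      e2$start[2] + 10L, e2$end[3] - 10L,
                                      "Kinase"))
    }
  }
  bed <- file.path(dir, "domains.bed")
  writeLines(dom_rows, bed)

  tsv <- file.path(dir, "fusions.tsv")
  header <- "chrom1\tpos1\tstrand1\tchrom2\tpos2\tstrand2\tsample"
  rows <- if (is.null(fusion)) character(0) else
    sprintf("%s\t%d\t%s\t%s\t%d\t%s\tsim1", fusion$chrom5, fusion$pos5,
            fusion$strand5, fusion$chrom3, fusion$pos3, fusion$strand3)
  writeLines(c(header, rows), tsv)

  genome <- open_genome(fa)
  calls <- parse_fusion_calls(tsv, "generic")
  domains <- read_domain_bed(bed)
  truth <- structure(
    list(genome = genome, genes = genes, domains = domains, calls = calls,
         fusion = fusion,
         paths = c(genome = fa, gtf = gtf, domains = bed, fusions = tsv),
         params = list(n_genes = n_genes, exons_per_gene = exons_per_gene,
                       exon_len = exon_len, intron_len = intron_len,
                       seed = seed)),
    class = "sim_truth")
  json <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(fusion = fusion, params = truth$params), json,
    auto_unbox = TRUE, null = "null")
  truth$paths[["truth"]] <- json
  truth
}

#' Simulate spliced alignments over a fusion reference
#'
#' Writes a SAM file of primary alignments realizing each requested
#' junction with reads at the requested flank lengths, plus unspliced
#' background reads spread over all reference sequences. Read sequences
#' are copied from the reference, so alignments are self-consistent.
#' The returned truth records, per junction, how many reads were planted
#' and how many survive the flank filter at `min_flank`, plus which
#' junctions reach `min_support` among the retained reads — the exact
#' quantities [analyze_alignments()] should recover.
#'
#' @param truth A `sim_truth` from [make_toy_locus()].
#' @param ref The `fusion_reference` built from the same toy locus.
#' @param path Output SAM path.
#' @param junctions data.frame with `start`, `end` (fusion-coordinate gap
#'   intervals); default: the intended fusion junction from the truth.
#' @param reads_per_junction Integer vector, recycled over junctions.
#' @param flank_profile Integer vector of left-flank lengths; read i of a
#'   junction takes the i-th value (recycled). The right flank is
#'   `right_flank` for every read.
#' @param right_flank Right-flank length in bases (default 50).
#' @param n_background Unspliced 80 bp background reads (default 20).
#' @param min_flank,min_support Thresholds at which the expected
#'   post-filter counts in the returned truth are computed (defaults 5
#'   and 3, the analysis defaults).
#' @param seed Random seed for background read placement.
#' @return The `sim_truth` with a `sim` field: `sam` path, `reads`
#'   (per-read origin table), `junctions` (planted junction table with
#'   `n_reads`, `expected_retained`, `expected_displayed`), and the
#'   thresholds used.
#' @export
simulate_fusion_alignments <- function(truth, ref, path, junctions = NULL,
                                       reads_per_junction = 6L,
                                       flank_profile = c(20L, 35L),
                                       right_flank = 50L,
                                       n_background = 20L,
                                       min_flank = 5L, min_support = 3L,
                                       seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(ref, "fusion_reference"))
  if (length(ref$fusions) == 0L) stop("reference contains no fusion sequence")
  fname <- names(ref$fusions)[[1]]
  fseq <- ref$fusions[[fname]]$sequence
  flen <- nchar(fseq)
  if (is.null(junctions)) {
    if (is.null(truth$fusion)) stop("truth has no intended fusion")
    junctions <- data.frame(start = truth$fusion$junction[["start"]],
                            end = truth$fusion$junction[["end"]])
  }
  stopifnot(all(junctions$start < junctions$end),
            all(junctions$start >= 1L), all(junctions$end <= flen))
  n_j <- nrow(junctions)
  reads_per_junction <- rep_len(as.integer(reads_per_junction), n_j)
  if (any(flank_profile < 1L) || right_flank < 1L)
    stop("flank lengths must be >= 1")

  set.seed(seed)
  seqs <- reference_sequences(ref)
  records <- character(0)
  read_tab <- list()
  rid <- 0L
  for (j in seq_len(n_j)) {
    js <- junctions$start[j]; je <- junctions$end[j]
    for (i in seq_len(reads_per_junction[j])) {
      lf <- flank_profile[((i - 1L) %% length(flank_profile)) + 1L]
      if (js - lf < 0L)
        stop("left flank ", lf, " runs past the reference start for gap at ",
             js)
      if (je + right_flank > flen)
        stop("right flank ", right_flank, " runs past the reference end")
      rid <- rid + 1L
      qname <- sprintf("jx%02d_r%04d", j, rid)
      pos0 <- js - lf
      cigar <- sprintf("%dM%dN%dM", lf, je - js, right_flank)
      sq <- paste0(substr(fseq, pos0 + 1L, js),
                   substr(fseq, je + 1L, je + right_flank))
      records <- c(records, paste(qname, 0L, fname, pos0 + 1L, 60L, cigar,
                                  "*", 0L, 0L, sq,
                                  strrep("I", nchar(sq)), sep = "\t"))
      read_tab[[length(read_tab) + 1L]] <- data.frame(
        read_id = qname, junction = j, gap_start = js, gap_end = je,
        left_flank = lf, right_flank = right_flank,
        retained = min(lf, right_flank) >= min_flank,
        stringsAsFactors = FALSE)
    }
  }
  bg_len <- 80L
  ref_pool <- names(seqs)[nchar(seqs) >= bg_len]
  if (length(ref_pool) > 0L) for (i in seq_len(n_background)) {
    rn <- ref_pool[[sample.int(length(ref_pool), 1L)]]
    pos0 <- sample.int(nchar(seqs[[rn]]) - bg_len + 1L, 1L) - 1L
    rid <- rid + 1L
    qname <- sprintf("bg_r%04d", rid)
    sq <- substr(seqs[[rn]], pos0 + 1L, pos0 + bg_len)
    records <- c(records, paste(qname, 0L, rn, pos0 + 1L, 60L,
                                paste0(bg_len, "M"), "*", 0L, 0L, sq,
                                strrep("I", bg_len), sep = "\t"))
  }

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  writeLines(c(header, records), path)

  reads <- do.call(rbind, read_tab)
  if (is.null(reads))
    reads <- data.frame(read_id = character(0), junction = integer(0),
                        gap_start = integer(0), gap_end = integer(0),
                        left_flank = integer(0), right_flank = integer(0),
                        retained = logical(0))
  jx_truth <- junctions
  jx_truth$n_reads <- reads_per_junction
  jx_truth$expected_retained <- vapply(seq_len(n_j), function(j)
    sum(reads$retained[reads$junction == j]), integer(1))
  jx_truth$expected_displayed <- jx_truth$expected_retained >= min_support
  truth$sim <- list(sam = path, refname = fname, reads = reads,
                    junctions = jx_truth, n_background = n_background,
                    min_flank = min_flank, min_support = min_support,
                    seed = seed)
  truth
}

#' Write simulated reads as FASTQ
#'
#' Companion output for integration runs through a real splice-aware
#' aligner; the core test surface consumes the SAM directly.
#'
#' @param sam_path SAM written by [simulate_fusion_alignments()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
sam_to_fastq <- function(sam_path, path) {
  lines <- readLines(sam_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  out <- unlist(lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    c(paste0("@", f[[1]]), f[[10]], "+", f[[11]])))
  writeLines(out, path)
  invisible(path)
}
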