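# In-code fixtures and independent brute-force oracles shared by the suite.

# --- object builders -------------------------------------------------------

toy_gene <- function(gene_id, chrom, strand, exon_sets, symbol = gene_id) {
  transcripts <- lapply(exon_sets, function(m)
    data.frame(start = m[, 1], end = m[, 2]))
  names(transcripts) <- paste0(gene_id, ".t", seq_along(transcripts))
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, transcripts = transcripts),
            class = "gene_model")
}

toy_gene_set <- function(...) {
  genes <- list(...)
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "gene_set")
}

# genome from named character strings, no file round trip
toy_genome <- function(...) {
  seqs <- c(...)
  structure(list(seqs = Biostrings::DNAStringSet(toupper(seqs)), path = NA),
            class = "genome_seq")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random small gene model on a fresh chromosome (<= 5 exons, len <= 500)
random_gene_model <- function(gene_id = "R1", chrom = "chrR") {
  n_exon <- sample.int(5L, 1L)
  bounds <- sort(sample.int(498L, 2L * n_exon)) - 1L
  starts <- bounds[seq(1L, by = 2L, length.out = n_exon)]
  ends <- bounds[seq(2L, by = 2L, length.out = n_exon)]
  keep <- ends > starts
  if (!any(keep)) { starts <- 10L; ends <- 60L; keep <- TRUE }
  strand <- sample(c("+", "-"), 1L)
  toy_gene(gene_id, chrom, strand, list(cbind(starts[keep], ends[keep])))
}

# --- brute-force oracles ---------------------------------------------------

# per-base genome -> superTranscript lookup table, built by enumeration:
# exonic positions of the merged exon union, ordered in transcriptional
# direction, indexed 0..L-1
brute_st_table <- function(starts, ends, strand) {
  pos <- sort(unique(unlist(mapply(function(s, e) seq(s, e - 1L), starts,
                                   ends, SIMPLIFY = FALSE))))
  if (strand == "-") pos <- rev(pos)
  data.frame(g = pos, s = seq_along(pos) - 1L)
}

# per-unit CIGAR interpreter: expands ops one unit at a time and derives
# gap intervals and flank counts from the expanded walk
brute_cigar_gaps <- function(pos, cigar) {
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  expanded <- rep(ops, lens)
  refpos <- pos
  segs <- list(); cur_aligned <- 0L
  gaps <- list(); cur_gap <- NULL
  for (op in expanded) {
    if (op %in% c("M", "=", "X")) {
      if (!is.null(cur_gap)) {
        gaps[[length(gaps) + 1L]] <- cur_gap; cur_gap <- NULL
      }
      cur_aligned <- cur_aligned + 1L
      refpos <- refpos + 1L
    } else if (op == "D") {
      if (!is.null(cur_gap)) {
        gaps[[length(gaps) + 1L]] <- cur_gap; cur_gap <- NULL
      }
      refpos <- refpos + 1L
    } else if (op == "N") {
      if (is.null(cur_gap)) {
        segs[[length(segs) + 1L]] <- cur_aligned
        cur_aligned <- 0L
        cur_gap <- c(refpos, refpos)
      }
      cur_gap[2] <- cur_gap[2] + 1L
      refpos <- refpos + 1L
    }
  }
  if (!is.null(cur_gap)) gaps[[length(gaps) + 1L]] <- cur_gap
  segs[[length(segs) + 1L]] <- cur_aligned
  if (length(gaps) == 0L) return(NULL)
  data.frame(
    gap_start = vapply(gaps, `[[`, 0L, 1L),
    gap_end = vapply(gaps, `[[`, 0L, 2L),
    left_flank = unlist(segs)[seq_along(gaps)],
    right_flank = unlist(segs)[seq_along(gaps) + 1L])
}

# per-base coverage interpreter over one reference
brute_coverage <- function(positions, cigars, ref_length) {
  depth <- integer(ref_length)
  for (i in seq_along(positions)) {
    ops <- strsplit(gsub("[0-9]+", "", cigars[i]), "")[[1]]
    lens <- as.integer(regmatches(cigars[i],
                                  gregexpr("[0-9]+", cigars[i]))[[1]])
    refpos <- positions[i]
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        idx <- seq(refpos + 1L, refpos + lens[k])
        depth[idx] <- depth[idx] + 1L
        refpos <- refpos + lens[k]
      } else if (ops[k] %in% c("D", "N")) {
        refpos <- refpos + lens[k]
      }
    }
  }
  depth
}

# --- SAM writing -----------------------------------------------------------

# minimal SAM with given (qname, flag, rname, pos0, cigar) rows over
# reference sequences `seqs` (named character). SEQ is taken from the
# reference so records are self-consistent.
write_test_sam <- function(path, rows, seqs) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  body <- vapply(rows, function(r) {
    read_len <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar,
                                   perl = TRUE))[[1]]))
    sq <- if (read_len > 0) strrep("A", read_len) else "*"
    paste(r$qname, r$flag, r$rname, r$pos0 + 1L, 60L, r$cigar, "*", 0L, 0L,
          sq, if (read_len > 0) strrep("I", read_len) else "*", sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

sam_row <- function(qname, rname, pos0, cigar, flag = 0L)
  list(qname = qname, flag = flag, rname = rname, pos0 = pos0, cigar = cigar)

# quick simulated pipeline for reuse across tests
sim_pipeline <- function(dir, seed = 1L, ...) {
  truth <- cmd_simulate(dir, seed = seed, ...)
  refdir <- file.path(dir, "reference")
  analysis <- cmd_analyze(file.path(dir, "alignments.sam"), refdir,
                          file.path(dir, "analysis"))
  list(truth = truth, refdir = refdir, analysis = analysis)
}
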