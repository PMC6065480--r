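# SuperTranscript construction and genome <-> superTranscript liftover.
#
# A superTranscript is the intron-free union of all annotated exons of a
# gene, oriented 5'->3' in transcriptional direction. The block map records
# which genomic interval each stretch of superTranscript sequence came
# from; all annotation liftover (transcripts, domains, breakpoints) runs
# through it.

#' Build the block map for a set of exonic intervals
#'
#' Merges overlapping genomic intervals and lays them out along the
#' superTranscript: ascending genomic order for "+" genes, descending for
#' "-" genes, so superTranscript coordinates always run 5' to 3' in
#' transcriptional direction. Within a "-" block the per-base map is
#' reversed.
#'
#' @param starts,ends Genomic exon intervals, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name carried along for liftover bookkeeping.
#' @return A `block_map`: list with `blocks` (data.frame `gstart, gend,
#'   sstart, send`), `strand`, `chrom`, `total_length`.
#' @export
make_block_map <- function(starts, ends, strand, chrom = NA_character_) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L,
            strand %in% c("+", "-"))
  if (any(ends <= starts)) stop("exon interval with end <= start")
  merged <- IRanges::reduce(IRanges::IRanges(start = starts + 1L,
                                             end = ends))
  gstart <- IRanges::start(merged) - 1L
  gend <- IRanges::end(merged)
  if (strand == "-") {
    ord <- order(gstart, decreasing = TRUE)
    gstart <- gstart[ord]; gend <- gend[ord]
  }
  widths <- gend - gstart
  send <- cumsum(widths)
  sstart <- send - widths
  structure(
    list(blocks = data.frame(gstart = gstart, gend = gend,
                             sstart = sstart, send = send),
         strand = strand, chrom = chrom,
         total_length = sum(widths)),
    class = "block_map"
  )
}

#' Map a genomic position into superTranscript coordinates
#'
#' @param bm A `block_map`.
#' @param gpos Genomic position(s), 0-based. Vectorized.
#' @return Integer superTranscript offset(s); `NA` where the position is
#'   not exonic (intronic/intergenic positions have no image).
#' @export
genome_to_st <- function(bm, gpos) {
  stopifnot(inherits(bm, "block_map"))
  b <- bm$blocks
  vapply(gpos, function(g) {
    hit <- which(b$gstart <= g & g < b$gend)
    if (length(hit) == 0L) return(NA_integer_)
    i <- hit[[1]]
    if (bm$strand == "+") b$sstart[i] + (g - b$gstart[i])
    else b$sstart[i] + (b$gend[i] - 1L - g)
  }, integer(1))
}

#' Map a superTranscript position back to the genome
#'
#' Exact inverse of [genome_to_st()] on exonic positions.
#'
#' @param bm A `block_map`.
#' @param spos SuperTranscript position(s) in `[0, total_length)`.
#' @return Integer genomic position(s).
#' @export
st_to_genome <- function(bm, spos) {
  stopifnot(inherits(bm, "block_map"))
  if (any(spos < 0L | spos >= bm$total_length))
    stop("superTranscript position out of range [0, ", bm$total_length, ")")
  b <- bm$blocks
  vapply(spos, function(s) {
    i <- which(b$sstart <= s & s < b$send)[[1]]
    if (bm$strand == "+") b$gstart[i] + (s - b$sstart[i])
    else b$gend[i] - 1L - (s - b$sstart[i])
  }, integer(1))
}

#' Lift a genomic interval into superTranscript space
#'
#' Returns the image of the interval's exonic part as maximal
#' superTranscript intervals. An exon (a sub-interval of one block) lifts
#' to exactly one interval; a feature spanning several blocks may split,
#' and pieces adjacent in superTranscript space are merged.
#'
#' @param bm A `block_map`.
#' @param gstart,gend Genomic interval, 0-based half-open.
#' @return data.frame with columns `start`, `end` (superTranscript
#'   coordinates, sorted); zero rows when the interval is fully
#'   intronic/intergenic.
#' @export
lift_interval <- function(bm, gstart, gend) {
  stopifnot(inherits(bm, "block_map"), gend > gstart)
  b <- bm$blocks
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    lo <- max(gstart, b$gstart[i]); hi <- min(gend, b$gend[i])
    if (lo >= hi) next
    if (bm$strand == "+") {
      s1 <- b$sstart[i] + (lo - b$gstart[i])
      pieces[[length(pieces) + 1L]] <- c(s1, s1 + (hi - lo))
    } else {
      s1 <- b$sstart[i] + (b$gend[i] - hi)
      pieces[[length(pieces) + 1L]] <- c(s1, s1 + (hi - lo))
    }
  }
  if (length(pieces) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge pieces that are adjacent in superTranscript space
  out <- list(m[1, ])
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[[2]])
      out[[length(out)]] <- c(last[[1]], max(last[[2]], m[i, 2]))
    else out[[length(out) + 1L]] <- m[i, ]
  }
  res <- do.call(rbind, out)
  data.frame(start = as.integer(res[, 1]), end = as.integer(res[, 2]))
}

#' Flatten a gene into its superTranscript
#'
#' Computes the genomic union of all exons across the gene's transcripts,
#' extracts the corresponding sequence (reverse-complemented, block by
#' block in descending genomic order, for "-" genes) and lifts every
#' transcript's exons into superTranscript coordinates.
#'
#' @param gene A `gene_model`.
#' @param genome A `genome_seq` from [open_genome()].
#' @return A `supertranscript`: list with `gene_id`, `symbol`, `chrom`,
#'   `strand`, `sequence`, `block_map`, `transcripts` (named list of
#'   lifted exon tables) and `domains` (filled by [lift_domains()]).
#' @export
build_supertranscript <- function(gene, genome) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- do.call(rbind, gene$transcripts)
  if (is.null(ex) || nrow(ex) == 0L)
    stop("gene ", gene$gene_id, " has no exons")
  bm <- make_block_map(ex$start, ex$end, gene$strand, gene$chrom)
  b <- bm$blocks
  seqs <- vapply(seq_len(nrow(b)), function(i)
    genome_fetch(genome, gene$chrom, b$gstart[i], b$gend[i]), "")
  if (gene$strand == "-")
    seqs <- vapply(seqs, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      "", USE.NAMES = FALSE)
  lifted_tx <- lapply(gene$transcripts, function(tx) {
    do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
      li <- lift_interval(bm, tx$start[i], tx$end[i])
      stopifnot(nrow(li) == 1L)  # exons are sub-intervals of blocks
      li
    }))
  })
  lifted_tx <- lapply(lifted_tx, function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]; rownames(tx) <- NULL; tx
  })
  structure(
    list(gene_id = gene$gene_id, symbol = gene$symbol, chrom = gene$chrom,
         strand = gene$strand, sequence = paste(seqs, collapse = ""),
         block_map = bm, transcripts = lifted_tx,
         domains = data.frame(name = character(0), start = integer(0),
                              end = integer(0))),
    class = "supertranscript"
  )
}

#' @export
print.supertranscript <- function(x, ...) {
  cat(sprintf("<supertranscript> %s (%s) %s:%s, %d bp, %d block(s), %d transcript(s)\n",
              x$symbol, x$gene_id, x$chrom, x$strand,
              x$block_map$total_length, nrow(x$block_map$blocks),
              length(x$transcripts)))
  invisible(x)
}

#' Lift protein-domain intervals onto a superTranscript
#'
#' Domains are positional annotations: they are lifted by coordinates only
#' and feature strand is ignored. Domains on other chromosomes or fully
#' intronic are dropped; a domain spanning several blocks may split into
#' multiple rows sharing the name.
#'
#' @param st A `supertranscript`.
#' @param domains A `domain_features` table from [read_domain_bed()].
#' @return `st` with its `domains` field filled (columns `name`, `start`,
#'   `end` in superTranscript coordinates).
#' @export
lift_domains <- function(st, domains) {
  stopifnot(inherits(st, "supertranscript"))
  if (is.null(domains) || nrow(domains) == 0L) return(st)
  dom <- domains[domains$chrom == st$chrom, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(dom))) {
    li <- lift_interval(st$block_map, dom$start[i], dom$end[i])
    if (nrow(li) == 0L) next
    li$name <- dom$name[i]
    pieces[[length(pieces) + 1L]] <- li
  }
  if (length(pieces) > 0L) {
    res <- do.call(rbind, pieces)[, c("name", "start", "end")]
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
    st$domains <- res
  }
  st
}

#' Assign a genomic breakpoint to a gene
#'
#' Deterministic assignment used to identify the two partner genes of a
#' fusion call, preferred over any caller-reported symbol:
#' 1. genes with an exon containing the breakpoint;
#' 2. else genes whose span (min exon start to max exon end) contains it;
#' 3. else the nearest gene within `window` bases of its span.
#' Ties break by distance to the nearest exon, then by symbol.
#'
#' @param chrom,pos Breakpoint (0-based position).
#' @param genes A `gene_set`.
#' @param window Maximum distance (bases) from a gene span for rule 3.
#'   Default 10 kb.
#' @return The winning `gene_model`. Signals a condition of class
#'   `fuseviz_unassignable` when no gene qualifies, so callers can log and
#'   skip the event.
#' @export
assign_gene <- function(chrom, pos, genes, window = 10000L) {
  cand <- Filter(function(g) g$chrom == chrom, genes)
  if (length(cand) > 0L) {
    info <- lapply(cand, function(g) {
      ex <- do.call(rbind, g$transcripts)
      in_exon <- any(ex$start <= pos & pos < ex$end)
      span <- c(min(ex$start), max(ex$end))
      in_span <- span[1] <= pos && pos < span[2]
      span_dist <- if (in_span) 0L else min(abs(pos - span[1]),
                                            abs(pos - (span[2] - 1L)))
      exon_dist <- min(pmax(ex$start - pos, 0L) + pmax(pos - (ex$end - 1L), 0L))
      list(gene = g, in_exon = in_exon, in_span = in_span,
           span_dist = span_dist, exon_dist = exon_dist)
    })
    pick <- function(cands) {
      ord <- order(vapply(cands, `[[`, 0L, "span_dist"),
                   vapply(cands, `[[`, 0L, "exon_dist"),
                   vapply(cands, function(x) x$gene$symbol, ""))
      cands[[ord[[1]]]]$gene
    }
    exon_hits <- Filter(function(x) x$in_exon, info)
    if (length(exon_hits) > 0L) return(pick(exon_hits))
    span_hits <- Filter(function(x) x$in_span, info)
    if (length(span_hits) > 0L) return(pick(span_hits))
    near <- Filter(function(x) x$span_dist <= window, info)
    if (length(near) > 0L) return(pick(near))
  }
  cond <- structure(
    class = c("fuseviz_unassignable", "error", "condition"),
    list(message = sprintf(
      "breakpoint %s:%d not assignable to any gene within %d bp",
      chrom, pos, window), call = NULL,
      breakpoint = list(chrom = chrom, pos = pos))
  )
  stop(cond)
}

#' Project a genomic position to the nearest exonic base
#'
#' Breakpoints reported inside introns have no direct image on the
#' superTranscript (introns are absent from it); such positions are moved
#' to the closest exonic base and flagged so downstream output can mark
#' the breakpoint as approximate.
#'
#' @param bm A `block_map`.
#' @param gpos Genomic position.
#' @return list with `gpos` (possibly moved), `spos` (its superTranscript
#'   offset) and `projected` (TRUE when the input was not exonic).
#' @export
project_to_exonic <- function(bm, gpos) {
  s <- genome_to_st(bm, gpos)
  if (!is.na(s)) return(list(gpos = gpos, spos = s, projected = FALSE))
  b <- bm$blocks
  edges <- c(b$gstart, b$gend - 1L)
  nearest <- edges[which.min(abs(edges - gpos))]
  list(gpos = nearest, spos = genome_to_st(bm, nearest), projected = TRUE)
}
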