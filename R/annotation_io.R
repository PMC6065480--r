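# Readers for the standard inputs: GTF annotation, genome FASTA, protein
# domain BED and fusion-caller breakpoint tables. All coordinates are held
# internally in 0-based half-open convention; conversion from the 1-based
# inclusive GTF (and from 1-based caller breakpoints) happens here and only
# here.

#' Read a GTF gene annotation into gene models
#'
#' Parses the exon records of a Gencode-style GTF file into a set of gene
#' models. Coordinates are converted from the GTF 1-based inclusive
#' convention to the package-internal 0-based half-open convention. Genes
#' are keyed by `gene_id`; the display symbol is taken from the `gene_name`
#' attribute and falls back to `gene_id` when absent. Caller-supplied gene
#' symbols in fusion tables are never used for gene identity; the symbol
#' always comes from the annotation, so all outputs carry consistent names.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_set`: a named list of `gene_model`
#'   objects, each with fields `gene_id`, `symbol`, `chrom`, `strand` and
#'   `transcripts` (a named list of exon tables with 0-based half-open
#'   `start`/`end` columns, sorted and disjoint within each transcript).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
#'   'gene_id "G1"; transcript_id "G1.t1"; gene_name "ALPHA";',
#'   sep = "\t"), gtf)
#' genes <- read_gtf(gtf)
#' genes[["G1"]]$transcripts[["G1.t1"]]  # exon [100, 200)
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  exons <- gr[!is.na(meta$type) & meta$type == "exon"]
  all_gene_ids <- unique(stats::na.omit(meta$gene_id))
  if (length(exons) == 0L) {
    if (length(all_gene_ids) > 0L)
      warning("no exon records; ", length(all_gene_ids), " gene(s) excluded")
    return(structure(list(), class = "gene_set"))
  }
  em <- S4Vectors::mcols(exons)
  if (is.null(em$gene_id) || anyNA(em$gene_id))
    stop("GTF exon records must carry a gene_id attribute")
  if (is.null(em$transcript_id) || anyNA(em$transcript_id))
    stop("GTF exon records must carry a transcript_id attribute")

  df <- data.frame(
    gene_id = as.character(em$gene_id),
    transcript_id = as.character(em$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    symbol = if (!is.null(em$gene_name)) as.character(em$gene_name)
             else NA_character_,
    stringsAsFactors = FALSE
  )

  genes <- lapply(split(df, df$gene_id), build_gene_model)
  genes <- genes[order(names(genes))]

  dropped <- setdiff(all_gene_ids, names(genes))
  if (length(dropped) > 0L)
    warning("gene(s) without exon records excluded: ",
            paste(dropped, collapse = ", "))
  structure(genes, class = "gene_set")
}

# Structural pre-scan so malformed input fails with a line number, which
# rtracklayer's parser does not report.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L)
      stop("malformed GTF line ", i, ": expected >= 8 tab-separated fields")
    st <- suppressWarnings(as.integer(fields[4]))
    en <- suppressWarnings(as.integer(fields[5]))
    if (is.na(st) || is.na(en))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (en < st)
      stop("invalid GTF line ", i, ": end < start")
    if (!fields[7] %in% c("+", "-", "."))
      stop("malformed GTF line ", i, ": bad strand '", fields[7], "'")
  }
  invisible(TRUE)
}

build_gene_model <- function(df) {
  gid <- df$gene_id[[1]]
  if (length(unique(df$chrom)) != 1L)
    stop("gene ", gid, ": transcripts on multiple chromosomes")
  if (length(unique(df$strand)) != 1L)
    stop("gene ", gid, ": transcripts on both strands")
  if (any(df$strand == "."))
    stop("gene ", gid, ": exon records without strand")
  sym <- stats::na.omit(unique(df$symbol))
  sym <- if (length(sym) > 0L && nzchar(sym[[1]])) sym[[1]] else gid
  transcripts <- lapply(split(df, df$transcript_id), function(tx) {
    ex <- tx[order(tx$start), c("start", "end"), drop = FALSE]
    rownames(ex) <- NULL
    if (any(ex$end <= ex$start))
      stop("gene ", gid, ": exon with non-positive length")
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("gene ", gid, ", transcript ", tx$transcript_id[[1]],
           ": overlapping exons")
    ex
  })
  structure(
    list(gene_id = gid, symbol = sym, chrom = df$chrom[[1]],
         strand = df$strand[[1]], transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d transcript(s)\n",
              x$symbol, x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d gene(s): %s\n", length(x),
              paste(utils::head(vapply(x, `[[`, "", "symbol"), 8L),
                    collapse = ", ")))
  invisible(x)
}

#' Write gene models back to GTF
#'
#' Emits one exon row per exon per transcript, converting internal 0-based
#' half-open coordinates back to GTF 1-based inclusive. Re-reading the file
#' with [read_gtf()] reproduces the input gene models.
#'
#' @param genes A `gene_set` from [read_gtf()] or [make_toy_locus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- character(0)
  for (g in genes) {
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                       g$gene_id, tid, g$symbol)
      rows <- c(rows, sprintf("%s\tfuseviz\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, ex$start + 1L, ex$end, g$strand, attrs))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Open a genome FASTA for random access
#'
#' Loads a FASTA file into memory as an uppercase sequence set. Sequence
#' names are truncated at the first whitespace, matching common FASTA
#' header usage.
#'
#' @param path Path to a FASTA file with unique sequence names.
#' @return An object of class `genome_seq` supporting [genome_fetch()].
#' @export
open_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA: ", path)
  structure(list(seqs = seqs, path = path), class = "genome_seq")
}

#' Fetch a genomic subsequence
#'
#' @param genome A `genome_seq` from [open_genome()].
#' @param name Sequence name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase character string of `end - start` bases.
#' @export
genome_fetch <- function(genome, name, start, end) {
  stopifnot(inherits(genome, "genome_seq"))
  if (!name %in% names(genome$seqs))
    stop("unknown sequence name: ", name)
  len <- length(genome$seqs[[name]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("query [%d,%d) out of bounds for %s (length %d)",
                 start, end, name, len))
  toupper(as.character(Biostrings::subseq(genome$seqs[[name]],
                                          start + 1L, end)))
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %d sequence(s), %d bp total\n",
              length(x$seqs), sum(Biostrings::width(x$seqs))))
  invisible(x)
}

#' Parse fusion-caller breakpoint tables
#'
#' Reads fusion calls from one of three tabular dialects into a uniform
#' breakpoint table. Breakpoints keep the caller's reported 5'/3' partner
#' order. Exact duplicate rows (same breakpoints and sample) are collapsed
#' to a single call with a message.
#'
#' Dialects:
#' \describe{
#'   \item{`generic`}{Headered TSV with columns `chrom1, pos1, strand1,
#'     chrom2, pos2, strand2, sample`. Positions are 0-based, matching the
#'     package's internal convention. This is the dialect written by
#'     [simulate_fusion_locus()].}
#'   \item{`jaffa`}{CSV with columns including `chrom1, base1, chrom2,
#'     base2` and optionally `sample` and `spanning reads`. Positions are
#'     1-based and converted on read.}
#'   \item{`star_fusion`}{TSV with `LeftBreakpoint`/`RightBreakpoint`
#'     columns holding `chr:pos:strand` strings (1-based positions) and
#'     optionally `JunctionReadCount`.}
#' }
#'
#' @param path Path to the fusion call table.
#' @param dialect One of `"generic"`, `"jaffa"`, `"star_fusion"`.
#' @return A data.frame of class `fusion_calls` with columns `chrom5, pos5,
#'   strand5, chrom3, pos3, strand3, sample, caller, caller_support`
#'   (positions 0-based).
#' @export
parse_fusion_calls <- function(path, dialect = c("generic", "jaffa",
                                                 "star_fusion")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("fusion call file not found: ", path)
  calls <- switch(dialect,
    generic = parse_calls_generic(path),
    jaffa = parse_calls_jaffa(path),
    star_fusion = parse_calls_starfusion(path)
  )
  if (nrow(calls) > 0L) {
    if (any(calls$pos5 < 0 | calls$pos3 < 0))
      stop("negative breakpoint position in ", path)
    if (any(!nzchar(calls$chrom5) | !nzchar(calls$chrom3)))
      stop("empty chromosome name in ", path)
    key <- paste(calls$chrom5, calls$pos5, calls$chrom3, calls$pos3,
                 calls$sample)
    if (anyDuplicated(key)) {
      message("collapsed ", sum(duplicated(key)), " duplicate fusion call(s)")
      calls <- calls[!duplicated(key), , drop = FALSE]
    }
  }
  rownames(calls) <- NULL
  class(calls) <- c("fusion_calls", "data.frame")
  calls
}

as_breakpoint_pos <- function(x, path) {
  pos <- suppressWarnings(as.numeric(x))
  if (anyNA(pos))
    stop("non-numeric breakpoint position in ", path, ": ",
         paste(utils::head(x[is.na(pos)], 3L), collapse = ", "))
  as.integer(pos)
}

parse_calls_generic <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "sample")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("generic fusion table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L)
    return(data.frame(chrom5 = character(0), pos5 = integer(0),
                      strand5 = character(0), chrom3 = character(0),
                      pos3 = integer(0), strand3 = character(0),
                      sample = character(0), caller = character(0),
                      caller_support = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(
    chrom5 = as.character(tab$chrom1),
    pos5 = as_breakpoint_pos(tab$pos1, path),
    strand5 = as.character(tab$strand1),
    chrom3 = as.character(tab$chrom2),
    pos3 = as_breakpoint_pos(tab$pos2, path),
    strand3 = as.character(tab$strand2),
    sample = as.character(tab$sample),
    caller = "generic",
    caller_support = NA_integer_,
    stringsAsFactors = FALSE
  )
}

parse_calls_jaffa <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom1", "base1", "chrom2", "base2")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("JAFFA table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  support <- if ("spanning reads" %in% names(tab))
    suppressWarnings(as.integer(tab[["spanning reads"]])) else NA_integer_
  data.frame(
    chrom5 = as.character(tab$chrom1),
    pos5 = as_breakpoint_pos(tab$base1, path) - 1L,   # 1-based to 0-based
    strand5 = if ("strand1" %in% names(tab)) as.character(tab$strand1)
              else NA_character_,
    chrom3 = as.character(tab$chrom2),
    pos3 = as_breakpoint_pos(tab$base2, path) - 1L,
    strand3 = if ("strand2" %in% names(tab)) as.character(tab$strand2)
              else NA_character_,
    sample = if ("sample" %in% names(tab)) as.character(tab$sample)
             else "sample1",
    caller = "jaffa",
    caller_support = support,
    stringsAsFactors = FALSE
  )
}

parse_calls_starfusion <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  need <- c("LeftBreakpoint", "RightBreakpoint")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("STAR-Fusion table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  split_bp <- function(x) {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad))
      stop("malformed breakpoint string in ", path, ": ",
           x[bad][[1]])
    list(chrom = vapply(parts, `[[`, "", 1L),
         pos = as_breakpoint_pos(vapply(parts, `[[`, "", 2L), path) - 1L,
         strand = vapply(parts, function(p)
           if (length(p) >= 3L) p[[3]] else NA_character_, ""))
  }
  left <- split_bp(tab$LeftBreakpoint)
  right <- split_bp(tab$RightBreakpoint)
  data.frame(
    chrom5 = left$chrom, pos5 = left$pos, strand5 = left$strand,
    chrom3 = right$chrom, pos3 = right$pos, strand3 = right$strand,
    sample = if ("sample" %in% names(tab)) as.character(tab$sample)
             else "sample1",
    caller = "star_fusion",
    caller_support = if ("JunctionReadCount" %in% names(tab))
      suppressWarnings(as.integer(tab$JunctionReadCount)) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Read protein-domain intervals from a BED file
#'
#' Accepts BED4+ (chrom, start, end, name; 0-based half-open). The name
#' column is required because it labels the domain in figures and tracks.
#' Rows on chromosomes absent from the annotation are kept here and
#' filtered later during liftover.
#'
#' @param path Path to a BED4+ file.
#' @return A data.frame of class `domain_features` with columns
#'   `chrom, start, end, name` (0-based half-open).
#' @export
read_domain_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("domain_features", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("domain BED requires >= 4 columns (chrom, start, end, name)")
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    name = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-numeric coordinates in BED: ", path)
  if (any(out$end <= out$start))
    stop("BED interval with end <= start in ", path)
  class(out) <- c("domain_features", "data.frame")
  out
}

#' Reconcile "chr" prefix conventions against the genome
#'
#' GTF, BED and fusion tables in the wild disagree on the "chr" prefix.
#' This maps a vector of chromosome names onto the naming used by the
#' genome FASTA by adding or stripping the prefix where that produces a
#' match; names that match neither way are returned unchanged.
#'
#' @param chroms Character vector of chromosome names.
#' @param genome_names Character vector of names as used by the genome.
#' @return Character vector of reconciled names.
#' @export
normalize_chroms <- function(chroms, genome_names) {
  vapply(chroms, function(ch) {
    if (ch %in% genome_names) return(ch)
    alt <- if (startsWith(ch, "chr")) sub("^chr", "", ch)
           else paste0("chr", ch)
    if (alt %in% genome_names) alt else ch
  }, "", USE.NAMES = FALSE)
}
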