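# Split-read and coverage analysis of alignments against the fusion
# reference. A fusion expresses itself as splicing between the two
# concatenated genes: a spliced (N-containing CIGAR) alignment whose gap
# crosses the gene boundary is a fusion-supporting read. Two filters are
# applied before junctions reach a figure: reads with fewer than
# `min_flank` (default 5) aligned bases flanking a gap on either side are
# discarded as likely mis-split alignments, and junctions supported by
# fewer than `min_support` (default 3) retained reads are dropped from
# figure payloads (but kept in the raw junction table).

#' Read alignments from SAM or BAM
#'
#' Loads the fields needed for junction and coverage analysis. SAM input
#' is converted on the fly via samtools (Rsamtools).
#'
#' @param path Path to a SAM or BAM file.
#' @return data.frame with columns `qname, flag, rname, pos, cigar`
#'   (`pos` converted to 0-based; unmapped records keep `NA` pos).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")))[[1]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos - 1L,
    cigar = res$cigar,
    stringsAsFactors = FALSE
  )
}

is_primary_mapped <- function(flag) {
  bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
}

parse_cigar <- function(cigar) {
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " +")[[1]])
  lens <- lens[!is.na(lens)]
  stopifnot(length(ops) == length(lens))
  list(ops = ops, lens = lens)
}

# Walk one CIGAR: gap intervals (N ops) in reference coordinates plus the
# number of aligned (M/=/X) bases between each gap and its neighbouring
# gap or read end. D advances the reference but contributes no flank.
cigar_gaps <- function(pos, cigar) {
  cg <- parse_cigar(cigar)
  refpos <- pos
  aligned_run <- 0L            # M/=/X bases since read start or last gap
  runs <- integer(0)           # aligned run lengths between consecutive gaps
  gap_start <- integer(0); gap_end <- integer(0)
  for (i in seq_along(cg$ops)) {
    op <- cg$ops[[i]]; len <- cg$lens[[i]]
    if (op %in% c("M", "=", "X")) {
      aligned_run <- aligned_run + len
      refpos <- refpos + len
    } else if (op == "D") {
      refpos <- refpos + len
    } else if (op == "N") {
      runs <- c(runs, aligned_run)
      aligned_run <- 0L
      gap_start <- c(gap_start, refpos)
      gap_end <- c(gap_end, refpos + len)
      refpos <- refpos + len
    }
    # I, S, H, P consume no reference and no aligned flank
  }
  runs <- c(runs, aligned_run)
  if (length(gap_start) == 0L) return(NULL)
  data.frame(gap_start = gap_start, gap_end = gap_end,
             left_flank = runs[seq_along(gap_start)],
             right_flank = runs[seq_along(gap_start) + 1L])
}

#' Extract split-read gap events from alignments
#'
#' One gap row per N (reference skip) operation of every primary mapped
#' alignment on `refname`. For each gap the flanks are the aligned
#' (M/=/X) reference bases between the gap and the read's previous/next
#' gap or read end; an interior aligned segment between two gaps counts
#' toward both gaps' inner flanks.
#'
#' @param aln Alignment table from [read_alignments()].
#' @param refname Reference sequence to analyse.
#' @return data.frame of class `split_read_gaps` with columns `read_id,
#'   refname, gap_start, gap_end, left_flank, right_flank` (0-based
#'   half-open gap intervals). Zero rows when no spliced reads exist.
#' @export
extract_split_reads <- function(aln, refname) {
  keep <- !is.na(aln$rname) & aln$rname == refname &
    is_primary_mapped(aln$flag)
  aln <- aln[keep, , drop = FALSE]
  miss <- is.na(aln$cigar) | aln$cigar == "*"
  if (any(miss)) {
    warning(sum(miss), " mapped record(s) without CIGAR skipped")
    aln <- aln[!miss, , drop = FALSE]
  }
  has_gap <- grepl("N", aln$cigar, fixed = TRUE)
  aln <- aln[has_gap, , drop = FALSE]
  rows <- lapply(seq_len(nrow(aln)), function(i) {
    g <- cigar_gaps(aln$pos[i], aln$cigar[i])
    if (is.null(g)) return(NULL)
    g$read_id <- aln$qname[i]
    g
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gap_start = integer(0), gap_end = integer(0),
                      left_flank = integer(0), right_flank = integer(0),
                      read_id = character(0))
  out$refname <- rep(refname, nrow(out))
  out <- out[, c("read_id", "refname", "gap_start", "gap_end",
                 "left_flank", "right_flank")]
  rownames(out) <- NULL
  class(out) <- c("split_read_gaps", "data.frame")
  out
}

#' Filter split reads by minimum flanking sequence
#'
#' Split reads with few aligned bases flanking a gap on one side are
#' typically products of incorrect split alignment. A read is retained
#' only if every one of its gaps has at least `min_flank` aligned bases
#' on both sides; exactly `min_flank` passes (fewer is removed). The
#' default cutoff is 5 bases.
#'
#' @param gaps A `split_read_gaps` table.
#' @param min_flank Minimum flank length in bases (default 5);
#'   `min_flank = 0` retains everything.
#' @return The retained subset, same class.
#' @export
filter_split_reads <- function(gaps, min_flank = 5L) {
  if (nrow(gaps) == 0L) return(gaps)
  read_min <- tapply(pmin(gaps$left_flank, gaps$right_flank),
                     gaps$read_id, min)
  keep_reads <- names(read_min)[read_min >= min_flank]
  out <- gaps[gaps$read_id %in% keep_reads, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("split_read_gaps", "data.frame")
  out
}

#' Aggregate retained split reads into junctions
#'
#' Junctions are keyed by exact gap coordinates (splice-aware aligners
#' report exact gap edges, and nearby isoform breakpoints must stay
#' distinct). Each junction carries its read support, whether it crosses
#' the fusion gene boundary (`gap_start < boundary <= gap_end`), the
#' donor/acceptor dinucleotide motif read from the reference sequence,
#' and a `display` flag: junctions below `min_support` retained reads are
#' dropped from figure payloads but remain in this table.
#'
#' @param gaps A flank-filtered `split_read_gaps` table.
#' @param ref The `fusion_reference` the reads were aligned to (provides
#'   sequence for motifs and the gene boundary).
#' @param min_support Minimum read support for display (default 3).
#' @return data.frame of class `junction_table`: `refname, start, end,
#'   support, crosses_boundary, motif, display`, sorted by position.
#' @export
count_junctions <- function(gaps, ref, min_support = 3L) {
  empty <- data.frame(refname = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      crosses_boundary = logical(0), motif = character(0),
                      display = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("junction_table", "data.frame")
  if (nrow(gaps) == 0L) return(empty)
  key <- paste(gaps$refname, gaps$gap_start, gaps$gap_end, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    refname = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    support = as.integer(tab),
    stringsAsFactors = FALSE
  )
  seqs <- reference_sequences(ref)
  boundaries <- vapply(ref$fusions, `[[`, 0L, "boundary")
  out$crosses_boundary <- vapply(seq_len(nrow(out)), function(i) {
    b <- boundaries[out$refname[i]]
    !is.na(b) && out$start[i] < b && b <= out$end[i]
  }, logical(1))
  out$motif <- vapply(seq_len(nrow(out)), function(i) {
    sq <- seqs[[out$refname[i]]]
    if (is.null(sq) || out$end[i] > nchar(sq) || out$end[i] - out$start[i] < 2L)
      return(NA_character_)
    paste0(substr(sq, out$start[i] + 1L, out$start[i] + 2L), "/",
           substr(sq, out$end[i] - 1L, out$end[i]))
  }, "")
  out$display <- out$support >= min_support
  out <- out[order(out$refname, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("junction_table", "data.frame")
  out
}

#' Compute per-base read coverage on one reference sequence
#'
#' Depth counts primary mapped alignments only (secondary and
#' supplementary records would double-count reads). Aligned operations
#' (M/=/X) add depth; reference skips (N) and deletions (D) do not.
#'
#' @param aln Alignment table from [read_alignments()].
#' @param refname Reference sequence name.
#' @param ref_length Length of that sequence in bases.
#' @return A `coverage_track`: list with `refname`, `depth` (integer
#'   vector of length `ref_length`), `scale = "raw"`, `library_size = NA`.
#' @export
compute_coverage <- function(aln, refname, ref_length) {
  keep <- !is.na(aln$rname) & aln$rname == refname &
    is_primary_mapped(aln$flag) & !is.na(aln$cigar) & aln$cigar != "*"
  aln <- aln[keep, , drop = FALSE]
  depth <- integer(ref_length)
  if (nrow(aln) > 0L) {
    ga <- GenomicAlignments::GAlignments(
      seqnames = factor(rep(refname, nrow(aln)), levels = refname),
      pos = aln$pos + 1L, cigar = aln$cigar,
      strand = S4Vectors::Rle(factor(rep("+", nrow(aln)),
                                     levels = c("+", "-", "*"))))
    cov <- GenomicAlignments::coverage(ga, width = ref_length,
                                       drop.D.ranges = TRUE)[[refname]]
    depth <- as.integer(cov)
  }
  structure(list(refname = refname, depth = depth, scale = "raw",
                 library_size = NA_integer_),
            class = "coverage_track")
}

#' Total primary mapped reads in an alignment table
#'
#' The library size used for reads-per-million normalization: every
#' primary mapped record across all reference sequences, counted once.
#'
#' @param aln Alignment table from [read_alignments()].
#' @return Integer count.
#' @export
count_library_size <- function(aln) {
  sum(is_primary_mapped(aln$flag) & !is.na(aln$rname))
}

#' Normalize a coverage track to reads per million
#'
#' RPM = raw depth x 10^6 / library size, enabling comparison between
#' samples of different sequencing depth. A track can be normalized only
#' once.
#'
#' @param track A raw-scale `coverage_track`.
#' @param library_size Total primary mapped reads in the sample
#'   (see [count_library_size()]); must be >= 1.
#' @return The track with `depth` rescaled and `scale = "rpm"`.
#' @export
normalize_rpm <- function(track, library_size) {
  stopifnot(inherits(track, "coverage_track"))
  if (identical(track$scale, "rpm"))
    stop("track is already on the reads-per-million scale")
  if (is.na(library_size) || library_size < 1L)
    stop("library_size must be >= 1")
  track$depth <- track$depth * 1e6 / library_size
  track$scale <- "rpm"
  track$library_size <- library_size
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, scale %s, max %.3g\n",
              x$refname, length(x$depth), x$scale, max(c(0, x$depth))))
  invisible(x)
}

#' Summarize split-read support for one fusion
#'
#' Reports every boundary-crossing junction of the fusion sequence with
#' its support, motif and the nearest expected (caller-reported)
#' breakpoint pair; the distance is |gap start - (donor+1)| +
#' |gap end - acceptor|, zero when the read splices exactly at the
#' expected breakpoint. Total spanning-read support is the sum over
#' boundary-crossing junctions.
#'
#' @param junctions A `junction_table`.
#' @param fusion A `fusion_st`.
#' @return list with `fusion` (name), `total_support`, and `isoforms`
#'   (data.frame, one row per boundary-crossing junction). When no
#'   junction crosses the boundary the report flags `no read support`.
#' @export
summarize_fusion_support <- function(junctions, fusion) {
  jx <- junctions[junctions$refname == fusion$name &
                  junctions$crosses_boundary, , drop = FALSE]
  bp <- fusion$breakpoints
  if (nrow(jx) == 0L) {
    return(list(fusion = fusion$name, total_support = 0L,
                isoforms = data.frame(), note = "no read support"))
  }
  nearest <- t(vapply(seq_len(nrow(jx)), function(i) {
    d <- abs(jx$start[i] - (bp$donor + 1L)) + abs(jx$end[i] - bp$acceptor)
    k <- which.min(d)
    c(bp$donor[k], bp$acceptor[k], d[k])
  }, numeric(3)))
  iso <- data.frame(
    start = jx$start, end = jx$end, support = jx$support,
    motif = jx$motif, display = jx$display,
    expected_donor = as.integer(nearest[, 1]),
    expected_acceptor = as.integer(nearest[, 2]),
    distance = as.integer(nearest[, 3]),
    stringsAsFactors = FALSE
  )
  iso <- iso[order(-iso$support), , drop = FALSE]
  rownames(iso) <- NULL
  list(fusion = fusion$name, total_support = sum(iso$support),
       isoforms = iso, note = NA_character_)
}

#' Run the full alignment analysis against a fusion reference
#'
#' For every fusion sequence: extract split reads, apply the flank
#' filter, aggregate junctions, compute raw and RPM coverage, and build
#' the per-fusion support report.
#'
#' @param path SAM/BAM path (aligned against the reference FASTA written
#'   by [write_reference_fasta()]).
#' @param ref The matching `fusion_reference`.
#' @param min_flank Flank filter cutoff in bases (default 5).
#' @param min_support Display support threshold in reads (default 3).
#' @return list of class `fusion_analysis`: `junctions` (all fusion
#'   sequences pooled), `coverage` (named list of RPM `coverage_track`s),
#'   `coverage_raw`, `support` (named list of per-fusion reports),
#'   `library_size`, `min_flank`, `min_support`.
#' @export
analyze_alignments <- function(path, ref, min_flank = 5L, min_support = 3L) {
  aln <- read_alignments(path)
  ref_names <- c(names(ref$fusions), names(ref$normals))
  seen <- unique(stats::na.omit(aln$rname))
  unknown <- setdiff(seen, ref_names)
  if (length(unknown) > 0L)
    stop("alignment reference name(s) not in the fusion reference: ",
         paste(unknown, collapse = ", "))
  lib <- count_library_size(aln)
  junctions <- list(); cov_raw <- list(); cov_rpm <- list(); support <- list()
  for (nm in names(ref$fusions)) {
    f <- ref$fusions[[nm]]
    gaps <- extract_split_reads(aln, nm)
    retained <- filter_split_reads(gaps, min_flank)
    jx <- count_junctions(retained, ref, min_support)
    junctions[[nm]] <- jx
    track <- compute_coverage(aln, nm, nchar(f$sequence))
    cov_raw[[nm]] <- track
    cov_rpm[[nm]] <- if (lib >= 1L) normalize_rpm(track, lib) else track
    support[[nm]] <- summarize_fusion_support(jx, f)
  }
  jx_all <- do.call(rbind, junctions)
  if (is.null(jx_all)) jx_all <- count_junctions(
    structure(data.frame(), class = c("split_read_gaps", "data.frame")), ref)
  rownames(jx_all) <- NULL
  class(jx_all) <- c("junction_table", "data.frame")
  structure(list(junctions = jx_all, coverage = cov_rpm,
                 coverage_raw = cov_raw, support = support,
                 library_size = lib, min_flank = min_flank,
                 min_support = min_support),
            class = "fusion_analysis")
}

#' @export
print.fusion_analysis <- function(x, ...) {
  cat(sprintf("<fusion_analysis> %d junction(s), library size %d\n",
              nrow(x$junctions), x$library_size))
  for (s in x$support)
    cat(sprintf("  %s: %d spanning read(s), %d isoform junction(s)\n",
                s$fusion, s$total_support,
                if (is.data.frame(s$isoforms)) nrow(s$isoforms) else 0L))
  invisible(x)
}

#' Write analysis tables and coverage tracks
#'
#' Writes the raw junction table (TSV), the per-fusion support report
#' (TSV) and per-fusion coverage as bedGraph in both raw and RPM scales.
#'
#' @param analysis A `fusion_analysis`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(junctions = file.path(dir, "junctions.tsv"),
             support = file.path(dir, "fusion_support.tsv"))
  utils::write.table(analysis$junctions, paths[["junctions"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sup_rows <- do.call(rbind, lapply(analysis$support, function(s) {
    if (!is.data.frame(s$isoforms) || nrow(s$isoforms) == 0L)
      return(data.frame(fusion = s$fusion, start = NA, end = NA,
                        support = 0L, motif = NA, display = FALSE,
                        expected_donor = NA, expected_acceptor = NA,
                        distance = NA, total_support = 0L,
                        stringsAsFactors = FALSE))
    cbind(fusion = s$fusion, s$isoforms, total_support = s$total_support)
  }))
  utils::write.table(sup_rows, paths[["support"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(analysis$coverage_raw)) {
    for (scale in c("raw", "rpm")) {
      track <- if (scale == "raw") analysis$coverage_raw[[nm]]
               else analysis$coverage[[nm]]
      p <- file.path(dir, sprintf("%s.coverage.%s.bedgraph", nm, scale))
      writeLines(bedgraph_lines(track), p)
      paths[[paste0(nm, ".", scale)]] <- p
    }
  }
  invisible(paths)
}

# Run-length encode a depth vector as bedGraph rows (zero runs skipped).
bedgraph_lines <- function(track) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  sprintf("%s\t%d\t%d\t%s", track$refname, starts[keep], ends[keep],
          format(r$values[keep], trim = TRUE, scientific = FALSE))
}
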