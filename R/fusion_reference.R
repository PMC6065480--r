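# Assembly of the sample-specific fusion reference: one fusion
# superTranscript per called gene pair (5' partner sequence followed by 3'
# partner sequence, both full length) plus the superTranscripts of all
# non-fused genes, so reads from normal transcripts map competitively and
# are not spuriously attracted to the fusion sequences. All annotation is
# re-expressed in reference coordinates and written as IGV-loadable
# FASTA/BED tracks.

sanitize_ref_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

fusion_st_new <- function(st5, st3, breakpoints, name) {
  boundary <- st5$block_map$total_length
  structure(
    list(name = name, st5 = st5, st3 = st3, boundary = boundary,
         sequence = paste0(st5$sequence, st3$sequence),
         breakpoints = breakpoints),
    class = "fusion_st"
  )
}

#' @export
print.fusion_st <- function(x, ...) {
  cat(sprintf("<fusion_st> %s: %s (%d bp) | %s (%d bp), boundary %d, %d breakpoint pair(s)\n",
              x$name, x$st5$symbol, x$boundary, x$st3$symbol,
              nchar(x$sequence) - x$boundary, x$boundary,
              nrow(x$breakpoints)))
  invisible(x)
}

lift_breakpoints <- function(call_rows, st5, st3) {
  boundary <- st5$block_map$total_length
  do.call(rbind, lapply(seq_len(nrow(call_rows)), function(i) {
    p5 <- project_to_exonic(st5$block_map, call_rows$pos5[i])
    p3 <- project_to_exonic(st3$block_map, call_rows$pos3[i])
    data.frame(
      donor = p5$spos,
      acceptor = boundary + p3$spos,
      donor_projected = p5$projected,
      acceptor_projected = p3$projected,
      sample = call_rows$sample[i],
      caller = call_rows$caller[i],
      caller_support = call_rows$caller_support[i],
      stringsAsFactors = FALSE
    )
  }))
}

#' Build one fusion superTranscript from a fusion call
#'
#' Assigns both breakpoints to genes (via [assign_gene()]), flattens each
#' partner to its superTranscript and concatenates them 5' partner first.
#' Both partners are included full length, so reads mapping to gene
#' regions not involved in the fusion remain visible. Breakpoints falling
#' in introns are projected to the nearest exonic base and flagged.
#'
#' @param call One row of a `fusion_calls` table.
#' @param genes A `gene_set`.
#' @param genome A `genome_seq`.
#' @param domains Optional `domain_features` to lift onto both partners.
#' @param window Gene-assignment window passed to [assign_gene()].
#' @return A `fusion_st` object. Its `boundary` is the offset where the 3'
#'   gene begins; `breakpoints` holds the expected donor/acceptor
#'   positions in fusion coordinates.
#' @export
make_fusion_st <- function(call, genes, genome, domains = NULL,
                           window = 10000L) {
  g5 <- assign_gene(call$chrom5, call$pos5, genes, window)
  g3 <- assign_gene(call$chrom3, call$pos3, genes, window)
  if (identical(g5$gene_id, g3$gene_id))
    warning("both breakpoints assign to gene ", g5$symbol,
            "; building a same-gene (tandem-duplication-like) reference")
  st5 <- build_supertranscript(g5, genome)
  st3 <- build_supertranscript(g3, genome)
  if (!is.null(domains)) {
    st5 <- lift_domains(st5, domains)
    st3 <- lift_domains(st3, domains)
  }
  name <- sanitize_ref_name(paste0(g5$symbol, "_", g3$symbol))
  fusion_st_new(st5, st3, lift_breakpoints(call, st5, st3), name)
}

#' Build the full fusion reference for a sample
#'
#' Produces the alignment reference: every called fusion as a fusion
#' superTranscript, plus a normal superTranscript for every annotated gene
#' that is not already embedded in a fusion sequence. Partner genes of a
#' fusion are excluded from the normals: their full sequence already
#' exists inside the fusion superTranscript, and keeping both copies would
#' make every partner-gene read multi-mapping and hide unique coverage.
#'
#' Calls whose breakpoints cannot be assigned to any gene are skipped and
#' reported in the `skipped` field. Distinct breakpoint pairs on one gene
#' pair collapse to a single reference sequence (the sequence is
#' breakpoint independent since both partners are full length); all
#' expected breakpoints are kept as metadata so multiple fusion isoforms
#' can be displayed on one sequence.
#'
#' @param calls A `fusion_calls` table (may have zero rows).
#' @param genes A `gene_set`.
#' @param genome A `genome_seq`.
#' @param domains Optional `domain_features`.
#' @param window Gene-assignment window in bases (default 10 kb).
#' @return A `fusion_reference`: list with `fusions` (named list of
#'   `fusion_st`), `normals` (named list of `supertranscript`) and
#'   `skipped` (data.frame of unplaceable calls with reasons).
#' @export
build_reference <- function(calls, genes, genome, domains = NULL,
                            window = 10000L) {
  genome_names <- names(genome$seqs)
  skipped <- data.frame(chrom5 = character(0), pos5 = integer(0),
                        chrom3 = character(0), pos3 = integer(0),
                        sample = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  assigned <- list()
  if (is.null(calls) || nrow(calls) == 0L) {
    warning("no fusion calls; building a normals-only reference")
  } else {
    calls$chrom5 <- normalize_chroms(calls$chrom5, genome_names)
    calls$chrom3 <- normalize_chroms(calls$chrom3, genome_names)
    for (i in seq_len(nrow(calls))) {
      row <- calls[i, , drop = FALSE]
      res <- tryCatch({
        g5 <- assign_gene(row$chrom5, row$pos5, genes, window)
        g3 <- assign_gene(row$chrom3, row$pos3, genes, window)
        list(g5 = g5, g3 = g3, row = row)
      }, fuseviz_unassignable = function(e) e)
      if (inherits(res, "fuseviz_unassignable")) {
        message("skipping call ", row$chrom5, ":", row$pos5, " - ",
                row$chrom3, ":", row$pos3, ": ", conditionMessage(res))
        skipped <- rbind(skipped, data.frame(
          chrom5 = row$chrom5, pos5 = row$pos5, chrom3 = row$chrom3,
          pos3 = row$pos3, sample = row$sample,
          reason = conditionMessage(res), stringsAsFactors = FALSE))
        next
      }
      key <- paste0(res$g5$gene_id, "|", res$g3$gene_id)
      assigned[[key]] <- if (is.null(assigned[[key]])) res
        else { prev <- assigned[[key]]; prev$row <- rbind(prev$row, res$row); prev }
    }
  }

  st_cache <- new.env(parent = emptyenv())
  get_st <- function(g) {
    if (is.null(st_cache[[g$gene_id]])) {
      st <- build_supertranscript(g, genome)
      if (!is.null(domains)) st <- lift_domains(st, domains)
      st_cache[[g$gene_id]] <- st
    }
    st_cache[[g$gene_id]]
  }

  fusions <- list()
  fused_gene_ids <- character(0)
  for (key in names(assigned)) {
    a <- assigned[[key]]
    if (identical(a$g5$gene_id, a$g3$gene_id))
      warning("both breakpoints of ", key, " assign to gene ",
              a$g5$symbol, "; building a same-gene reference")
    st5 <- get_st(a$g5); st3 <- get_st(a$g3)
    name <- sanitize_ref_name(paste0(a$g5$symbol, "_", a$g3$symbol))
    if (name %in% names(fusions)) {
      k <- 2L
      while (paste0(name, ".", k) %in% names(fusions)) k <- k + 1L
      name <- paste0(name, ".", k)
    }
    fusions[[name]] <- fusion_st_new(st5, st3,
                                     lift_breakpoints(a$row, st5, st3), name)
    fused_gene_ids <- union(fused_gene_ids, c(a$g5$gene_id, a$g3$gene_id))
  }

  normals <- list()
  for (g in genes) {
    if (g$gene_id %in% fused_gene_ids) next
    nm <- sanitize_ref_name(g$symbol)
    if (nm %in% names(normals) || nm %in% names(fusions)) {
      k <- 2L
      while (paste0(nm, ".", k) %in% c(names(normals), names(fusions)))
        k <- k + 1L
      nm <- paste0(nm, ".", k)
    }
    st <- get_st(g)
    st$name <- nm
    normals[[nm]] <- st
  }

  structure(list(fusions = fusions, normals = normals, skipped = skipped),
            class = "fusion_reference")
}

#' @export
print.fusion_reference <- function(x, ...) {
  cat(sprintf("<fusion_reference> %d fusion(s), %d normal gene(s), %d skipped call(s)\n",
              length(x$fusions), length(x$normals), nrow(x$skipped)))
  for (f in x$fusions) print(f)
  invisible(x)
}

# All reference sequences as a named character vector.
reference_sequences <- function(ref) {
  c(vapply(ref$fusions, `[[`, "", "sequence"),
    vapply(ref$normals, `[[`, "", "sequence"))
}

# Length lookup for one reference sequence name.
reference_length <- function(ref, refname) {
  seqs <- reference_sequences(ref)
  if (!refname %in% names(seqs)) stop("unknown reference sequence: ", refname)
  nchar(seqs[[refname]])
}

#' Write the reference FASTA
#'
#' One record per reference sequence (fusions first, then normals),
#' 60-column wrapped, names free of whitespace so they are valid SAM
#' reference names.
#'
#' @param ref A `fusion_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- reference_sequences(ref)
  if (length(seqs) == 0L) stop("empty reference: nothing to write")
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Write IGV-compatible annotation tracks for a reference
#'
#' Emits, in reference coordinates (all loadable in IGV against the
#' reference FASTA):
#' \describe{
#'   \item{`gene_boundaries.bed`}{BED4, one interval per constituent gene
#'     of every reference sequence.}
#'   \item{`transcripts.bed`}{BED12, one row per transcript per
#'     constituent gene, exon structure in the block fields; rows of the
#'     3' partner offset by the fusion boundary.}
#'   \item{`domains.bed`}{BED4 protein-domain intervals; a domain split
#'     across blocks yields multiple rows sharing the name.}
#'   \item{`breakpoints.bed`}{BED4, one 1-bp interval per expected donor
#'     and acceptor position, flagged `~` when projected from an intron.}
#' }
#'
#' @param ref A `fusion_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_annotation_tracks <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  boundaries <- character(0); tx12 <- character(0)
  doms <- character(0); bps <- character(0)

  emit_gene <- function(refname, st, offset) {
    L <- st$block_map$total_length
    boundaries <<- c(boundaries, sprintf("%s\t%d\t%d\t%s", refname, offset,
                                         offset + L, st$symbol))
    for (tid in names(st$transcripts)) {
      ex <- st$transcripts[[tid]]
      txs <- offset + ex$start[[1]]
      txe <- offset + ex$end[[nrow(ex)]]
      sizes <- paste0(paste(ex$end - ex$start, collapse = ","), ",")
      starts <- paste0(paste(offset + ex$start - txs, collapse = ","), ",")
      tx12 <<- c(tx12, sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d\t0\t%d\t%s\t%s",
                               refname, txs, txe, tid, txs, txe, nrow(ex),
                               sizes, starts))
    }
    if (nrow(st$domains) > 0L)
      doms <<- c(doms, sprintf("%s\t%d\t%d\t%s", refname,
                               offset + st$domains$start,
                               offset + st$domains$end, st$domains$name))
  }

  for (nm in names(ref$fusions)) {
    f <- ref$fusions[[nm]]
    emit_gene(nm, f$st5, 0L)
    emit_gene(nm, f$st3, f$boundary)
    bp <- f$breakpoints
    for (i in seq_len(nrow(bp))) {
      bps <- c(bps,
        sprintf("%s\t%d\t%d\tdonor_%s%s", nm, bp$donor[i], bp$donor[i] + 1L,
                bp$sample[i], if (bp$donor_projected[i]) "~" else ""),
        sprintf("%s\t%d\t%d\tacceptor_%s%s", nm, bp$acceptor[i],
                bp$acceptor[i] + 1L, bp$sample[i],
                if (bp$acceptor_projected[i]) "~" else ""))
    }
  }
  for (nm in names(ref$normals)) emit_gene(nm, ref$normals[[nm]], 0L)

  paths <- c(gene_boundaries = file.path(dir, "gene_boundaries.bed"),
             transcripts = file.path(dir, "transcripts.bed"),
             domains = file.path(dir, "domains.bed"),
             breakpoints = file.path(dir, "breakpoints.bed"))
  writeLines(boundaries, paths[["gene_boundaries"]])
  writeLines(tx12, paths[["transcripts"]])
  writeLines(doms, paths[["domains"]])
  writeLines(bps, paths[["breakpoints"]])
  invisible(paths)
}
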