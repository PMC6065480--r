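# CIGAR gap extraction, the flank and support filters, junction
# aggregation and coverage, cross-checked against per-base brute-force
# interpreters and GenomicAlignments.

# small in-memory reference with one fusion (boundary 500, length 1200)
mock_fusion_ref <- function(seed = 99) {
  withr::local_seed(seed, .local_envir = parent.frame())
  st_stub <- function(symbol, len) {
    structure(list(gene_id = symbol, symbol = symbol, chrom = NA,
                   strand = "+", sequence = random_dna(len),
                   block_map = make_block_map(0L, len, "+"),
                   transcripts = list(), domains = data.frame(
                     name = character(0), start = integer(0),
                     end = integer(0))),
              class = "supertranscript")
  }
  st5 <- st_stub("AAA", 500L); st3 <- st_stub("BBB", 700L)
  f <- structure(list(name = "AAA_BBB", st5 = st5, st3 = st3,
                      boundary = 500L,
                      sequence = paste0(st5$sequence, st3$sequence),
                      breakpoints = data.frame(
                        donor = 479L, acceptor = 620L,
                        donor_projected = FALSE, acceptor_projected = FALSE,
                        sample = "S1", caller = "generic",
                        caller_support = NA_integer_)),
                 class = "fusion_st")
  structure(list(fusions = list(AAA_BBB = f), normals = list(),
                 skipped = data.frame()),
            class = "fusion_reference")
}

aln_df <- function(...) {
  rows <- list(...)
  data.frame(qname = vapply(rows, `[[`, "", 1L),
             flag = as.integer(vapply(rows, `[[`, 0, 2L)),
             rname = vapply(rows, `[[`, "", 3L),
             pos = as.integer(vapply(rows, `[[`, 0, 4L)),
             cigar = vapply(rows, `[[`, "", 5L),
             stringsAsFactors = FALSE)
}

test_that("CIGAR walk finds gaps and flanks, matching worked examples", {
  aln <- aln_df(list("r1", 0L, "AAA_BBB", 96L, "4M100N50M"),
                list("r2", 0L, "AAA_BBB", 10L, "50M"),
                list("r3", 0L, "AAA_BBB", 0L, "10M20N10M30N10M"))
  ev <- extract_split_reads(aln, "AAA_BBB")
  r1 <- ev[ev$read_id == "r1", ]
  expect_equal(r1$gap_start, 100L)
  expect_equal(r1$gap_end, 200L)
  expect_equal(r1$left_flank, 4L)
  expect_equal(r1$right_flank, 50L)
  expect_false("r2" %in% ev$read_id)   # no N, no event
  r3 <- ev[ev$read_id == "r3", ]
  expect_equal(nrow(r3), 2L)
  # middle aligned segment counts for both gaps' inner sides
  expect_equal(r3$gap_start, c(10L, 40L))
  expect_equal(r3$gap_end, c(30L, 70L))
  expect_equal(r3$left_flank, c(10L, 10L))
  expect_equal(r3$right_flank, c(10L, 10L))
  expect_equal(brute_cigar_gaps(0L, "10M20N10M30N10M")[, 1:4],
               data.frame(gap_start = c(10L, 40L), gap_end = c(30L, 70L),
                          left_flank = c(10L, 10L),
                          right_flank = c(10L, 10L)))
})

test_that("secondary/supplementary/unmapped records are ignored", {
  aln <- aln_df(list("p", 0L, "AAA_BBB", 0L, "10M50N10M"),
                list("s", 256L, "AAA_BBB", 0L, "10M50N10M"),
                list("u", 4L, "AAA_BBB", 0L, "10M50N10M"),
                list("sup", 2048L, "AAA_BBB", 0L, "10M50N10M"))
  ev <- extract_split_reads(aln, "AAA_BBB")
  expect_equal(ev$read_id, "p")
})

test_that("gap extraction agrees with the brute-force CIGAR interpreter", {
  withr::local_seed(21)
  random_cigar <- function() {
    n_gap <- sample(0:2, 1)
    parts <- paste0(sample(5:30, 1), "M")
    for (k in seq_len(n_gap))
      parts <- c(parts, paste0(sample(10:100, 1), "N"),
                 paste0(sample(1:30, 1), "M"))
    if (stats::runif(1) < 0.3)  # sprinkle I/D/S ops
      parts <- c(paste0(sample(1:5, 1), "S"), parts,
                 paste0(sample(1:5, 1), "I"))
    if (stats::runif(1) < 0.3)
      parts <- append(parts, paste0(sample(1:5, 1), "D"), after = 1)
    paste(parts, collapse = "")
  }
  for (rep in 1:8) {
    n <- sample(1:50, 1)
    aln <- do.call(aln_df, lapply(seq_len(n), function(i)
      list(paste0("r", i), 0L, "AAA_BBB", sample(0:500, 1),
           random_cigar())))
    ev <- extract_split_reads(aln, "AAA_BBB")
    for (i in seq_len(n)) {
      want <- brute_cigar_gaps(aln$pos[i], aln$cigar[i])
      got <- as.data.frame(ev)[ev$read_id == aln$qname[i],
                c("gap_start", "gap_end", "left_flank", "right_flank")]
      rownames(got) <- NULL
      if (is.null(want)) expect_equal(nrow(got), 0L)
      else expect_equal(got, want)
    }
    # independent package cross-check of gap coordinates
    spliced <- grepl("N", aln$cigar)
    if (any(spliced)) {
      ga <- GenomicAlignments::GAlignments(
        seqnames = factor(rep("AAA_BBB", sum(spliced))),
        pos = aln$pos[spliced] + 1L, cigar = aln$cigar[spliced],
        strand = S4Vectors::Rle(factor(rep("+", sum(spliced)),
                                       levels = c("+", "-", "*"))))
      jx <- GenomicAlignments::junctions(ga)
      want_gaps <- sort(unlist(lapply(jx, function(j)
        paste(BiocGenerics::start(j) - 1L, BiocGenerics::end(j)))))
      got_gaps <- sort(paste(ev$gap_start, ev$gap_end))
      expect_equal(got_gaps, unname(want_gaps))
    }
  }
})

test_that("flank filter removes reads below 5 and keeps exactly 5", {
  aln <- aln_df(list("short", 0L, "AAA_BBB", 96L, "4M100N50M"),
                list("edge", 0L, "AAA_BBB", 95L, "5M100N50M"),
                list("long", 0L, "AAA_BBB", 50L, "50M100N50M"))
  ev <- extract_split_reads(aln, "AAA_BBB")
  kept <- filter_split_reads(ev, min_flank = 5L)
  expect_setequal(kept$read_id, c("edge", "long"))
  expect_equal(nrow(filter_split_reads(ev, min_flank = 0L)), nrow(ev))
})

test_that("a read is dropped when any one of its gaps fails the filter", {
  aln <- aln_df(list("mixed", 0L, "AAA_BBB", 0L, "20M50N3M50N20M"))
  ev <- extract_split_reads(aln, "AAA_BBB")
  expect_equal(nrow(filter_split_reads(ev, 5L)), 0L)
})

test_that("filters are monotone in their thresholds", {
  withr::local_seed(13)
  ref <- mock_fusion_ref()
  aln <- do.call(aln_df, lapply(1:40, function(i)
    list(paste0("r", i), 0L, "AAA_BBB", sample(400:470, 1),
         sprintf("%dM%dN%dM", sample(1:12, 1), sample(60:80, 1),
                 sample(1:12, 1)))))
  ev <- extract_split_reads(aln, "AAA_BBB")
  kept_n <- vapply(0:12, function(mf)
    nrow(filter_split_reads(ev, mf)), integer(1))
  expect_true(all(diff(kept_n) <= 0))
  retained <- filter_split_reads(ev, 5L)
  disp_n <- vapply(1:6, function(ms)
    sum(count_junctions(retained, ref, ms)$display), integer(1))
  expect_true(all(diff(disp_n) <= 0))
})

test_that("junctions aggregate by exact coordinates with support counts", {
  ref <- mock_fusion_ref()
  rows <- c(lapply(1:3, function(i)
    list(paste0("a", i), 0L, "AAA_BBB", 460L, "20M140N30M")),
    lapply(1:2, function(i)
      list(paste0("b", i), 0L, "AAA_BBB", 80L, "20M100N30M")))
  ev <- extract_split_reads(do.call(aln_df, rows), "AAA_BBB")
  jx <- count_junctions(filter_split_reads(ev, 5L), ref, min_support = 3L)
  expect_equal(nrow(jx), 2L)
  j1 <- jx[jx$start == 480L, ]
  expect_equal(j1$support, 3L)
  expect_true(j1$display)
  expect_true(j1$crosses_boundary)     # 480 < 500 <= 620
  j2 <- jx[jx$start == 100L, ]
  expect_equal(j2$support, 2L)
  expect_false(j2$display)             # below the 3-read threshold
  expect_false(j2$crosses_boundary)
  # conservation: support sums equal retained gap observations
  expect_equal(sum(jx$support), nrow(filter_split_reads(ev, 5L)))
})

test_that("junction motifs are read from the reference sequence", {
  ref <- mock_fusion_ref()
  f <- ref$fusions[[1]]
  sq <- f$sequence
  substr(sq, 481, 482) <- "GT"
  substr(sq, 619, 620) <- "AG"
  ref$fusions[[1]]$sequence <- sq
  ev <- extract_split_reads(
    aln_df(list("r", 0L, "AAA_BBB", 460L, "20M140N30M")), "AAA_BBB")
  jx <- count_junctions(ev, ref, min_support = 1L)
  expect_equal(jx$motif, "GT/AG")
})

test_that("coverage counts aligned bases only and conserves totals", {
  ref <- mock_fusion_ref()
  aln <- aln_df(list("r1", 0L, "AAA_BBB", 96L, "4M100N50M"),
                list("r2", 0L, "AAA_BBB", 96L, "4M100N50M"),
                list("sec", 256L, "AAA_BBB", 0L, "30M"))
  tr <- compute_coverage(aln, "AAA_BBB", 1200L)
  expect_equal(tr$depth[97:100], rep(2L, 4))     # [96,100) depth 2
  expect_equal(tr$depth[101:200], rep(0L, 100))  # inside the gap
  expect_equal(tr$depth[201:250], rep(2L, 50))
  expect_equal(sum(tr$depth), 2L * 54L)          # primary aligned bases only

  empty <- compute_coverage(aln[0, ], "AAA_BBB", 1200L)
  expect_equal(sum(empty$depth), 0L)
  expect_length(empty$depth, 1200L)
})

test_that("coverage matches the per-base brute-force interpreter", {
  withr::local_seed(31)
  for (rep in 1:3) {
    n <- sample(5:30, 1)
    aln <- do.call(aln_df, lapply(seq_len(n), function(i)
      list(paste0("r", i), 0L, "AAA_BBB", sample(0:900, 1),
           sprintf("%dM%dN%dM", sample(5:40, 1), sample(10:80, 1),
                   sample(5:40, 1)))))
    tr <- compute_coverage(aln, "AAA_BBB", 1200L)
    expect_equal(tr$depth, brute_coverage(aln$pos, aln$cigar, 1200L))
  }
})

test_that("RPM normalization is raw x 1e6 / library size, applied once", {
  tr <- structure(list(refname = "x", depth = rep(10L, 5), scale = "raw",
                       library_size = NA_integer_),
                  class = "coverage_track")
  rpm <- normalize_rpm(tr, 2e6)
  expect_equal(rpm$depth, rep(5, 5))
  expect_equal(rpm$scale, "rpm")
  ident <- normalize_rpm(tr, 1e6)
  expect_equal(ident$depth, tr$depth)
  expect_error(normalize_rpm(rpm, 2e6), "already")
  expect_error(normalize_rpm(tr, 0), ">= 1")
})

test_that("fusion support sums boundary-crossing junctions per isoform", {
  ref <- mock_fusion_ref()
  f <- ref$fusions[[1]]
  jx <- data.frame(refname = "AAA_BBB",
                   start = c(480L, 485L, 100L),
                   end = c(620L, 650L, 200L),
                   support = c(5L, 3L, 50L),
                   crosses_boundary = c(TRUE, TRUE, FALSE),
                   motif = "GT/AG", display = TRUE)
  class(jx) <- c("junction_table", "data.frame")
  rep_ <- summarize_fusion_support(jx, f)
  expect_equal(rep_$total_support, 8L)
  expect_equal(nrow(rep_$isoforms), 2L)
  # exact splice at the expected breakpoint has distance 0
  expect_equal(rep_$isoforms$distance[rep_$isoforms$start == 480L], 0L)

  none <- summarize_fusion_support(jx[3, ], f)
  expect_equal(none$total_support, 0L)
  expect_equal(none$note, "no read support")
})

test_that("SAM files round-trip through read_alignments", {
  ref <- mock_fusion_ref()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, list(
    sam_row("r1", "AAA_BBB", 460L, "20M140N30M"),
    sam_row("r2", "AAA_BBB", 10L, "40M")),
    c(AAA_BBB = ref$fusions[[1]]$sequence))
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$pos[aln$qname == "r1"], 460L)   # back to 0-based
  expect_equal(aln$cigar[aln$qname == "r1"], "20M140N30M")
  expect_equal(count_library_size(aln), 2L)
})

test_that("analyze_alignments rejects foreign reference names", {
  ref <- mock_fusion_ref()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, list(sam_row("r1", "OTHER", 0L, "30M")),
                 c(OTHER = random_dna(100)))
  expect_error(analyze_alignments(sam, ref), "OTHER")
})
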