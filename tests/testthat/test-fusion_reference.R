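# Fusion superTranscript assembly, the competitive reference and the
# IGV track writers.

make_two_gene_setup <- function(seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  genes <- toy_gene_set(
    toy_gene("G1", "chrA", "+",
             list(cbind(c(100L, 400L), c(300L, 700L))), symbol = "AAA"),
    toy_gene("G2", "chrB", "+",
             list(cbind(c(50L, 500L, 900L), c(250L, 800L, 1100L))),
             symbol = "BBB"),
    toy_gene("G3", "chrA", "+", list(cbind(2000L, 2500L)), symbol = "CCC"))
  genome <- toy_genome(chrA = random_dna(3000), chrB = random_dna(1500))
  call <- data.frame(chrom5 = "chrA", pos5 = 250L, strand5 = "+",
                     chrom3 = "chrB", pos3 = 500L, strand3 = "+",
                     sample = "S1", caller = "generic",
                     caller_support = NA_integer_)
  list(genes = genes, genome = genome, call = call)
}

test_that("fusion sequence is the byte-for-byte partner concatenation", {
  s <- make_two_gene_setup()
  fst <- make_fusion_st(s$call, s$genes, s$genome)
  st5 <- build_supertranscript(s$genes[["G1"]], s$genome)
  st3 <- build_supertranscript(s$genes[["G2"]], s$genome)
  expect_equal(fst$sequence, paste0(st5$sequence, st3$sequence))
  expect_equal(fst$boundary, st5$block_map$total_length)
  expect_equal(nchar(fst$sequence),
               st5$block_map$total_length + st3$block_map$total_length)
  expect_equal(fst$name, "AAA_BBB")
})

test_that("expected breakpoints land at lifted positions, acceptor offset", {
  s <- make_two_gene_setup()
  fst <- make_fusion_st(s$call, s$genes, s$genome)
  # G1 exon1 [100,300): genomic 250 -> st 150
  expect_equal(fst$breakpoints$donor, 150L)
  # G2 exon1 [50,250), exon2 [500,800): genomic 500 -> st 200, + boundary
  expect_equal(fst$breakpoints$acceptor, fst$boundary + 200L)
  expect_false(fst$breakpoints$donor_projected)
  expect_true(fst$breakpoints$donor < fst$boundary)
  expect_true(fst$boundary <= fst$breakpoints$acceptor)
  expect_true(fst$breakpoints$acceptor < nchar(fst$sequence))
})

test_that("intronic caller breakpoints are projected and flagged", {
  s <- make_two_gene_setup()
  call <- s$call
  call$pos5 <- 345L   # intron of G1, nearest exonic base is 299
  fst <- make_fusion_st(call, s$genes, s$genome)
  expect_true(fst$breakpoints$donor_projected)
  expect_equal(fst$breakpoints$donor, 199L)  # genome_to_st(299)
})

test_that("distinct breakpoint pairs on one gene pair share one sequence", {
  s <- make_two_gene_setup()
  calls <- rbind(s$call, within(s$call, pos3 <- 900L))
  class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome)
  expect_length(ref$fusions, 1L)
  expect_equal(nrow(ref$fusions[[1]]$breakpoints), 2L)
})

test_that("fused partners are excluded from the normals (competitive set)", {
  s <- make_two_gene_setup()
  calls <- s$call; class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome)
  expect_length(ref$fusions, 1L)
  expect_named(ref$normals, "CCC")
  # gene coverage: fusions + normals == full annotated set, no overlap
  covered <- c("G1", "G2", ref$normals[["CCC"]]$gene_id)
  expect_setequal(covered, names(s$genes))
})

test_that("zero calls yield a normals-only reference with a warning", {
  s <- make_two_gene_setup()
  empty <- s$call[0, ]
  expect_warning(ref <- build_reference(empty, s$genes, s$genome),
                 "normals-only")
  expect_length(ref$fusions, 0L)
  expect_length(ref$normals, 3L)
})

test_that("two fusions sharing a partner exclude all three genes", {
  s <- make_two_gene_setup()
  calls <- rbind(s$call,
                 data.frame(chrom5 = "chrA", pos5 = 250L, strand5 = "+",
                            chrom3 = "chrA", pos3 = 2200L, strand3 = "+",
                            sample = "S1", caller = "generic",
                            caller_support = NA_integer_))
  class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome)
  expect_length(ref$fusions, 2L)
  expect_length(ref$normals, 0L)
})

test_that("unassignable calls are skipped with a logged reason", {
  s <- make_two_gene_setup()
  calls <- rbind(s$call,
                 data.frame(chrom5 = "chrZ", pos5 = 10L, strand5 = "+",
                            chrom3 = "chrB", pos3 = 500L, strand3 = "+",
                            sample = "S1", caller = "generic",
                            caller_support = NA_integer_))
  class(calls) <- c("fusion_calls", "data.frame")
  expect_message(ref <- build_reference(calls, s$genes, s$genome),
                 "skipping")
  expect_length(ref$fusions, 1L)
  expect_equal(nrow(ref$skipped), 1L)
  expect_match(ref$skipped$reason, "not assignable")
})

test_that("same-gene events still build, with a warning", {
  s <- make_two_gene_setup()
  call <- s$call
  call$chrom3 <- "chrA"; call$pos3 <- 500L   # both in G1
  class(call) <- c("fusion_calls", "data.frame")
  expect_warning(ref <- build_reference(call, s$genes, s$genome),
                 "same-gene")
  expect_length(ref$fusions, 1L)
  expect_equal(ref$fusions[[1]]$st5$gene_id, ref$fusions[[1]]$st3$gene_id)
})

test_that("reference FASTA round-trips and rejects an empty reference", {
  s <- make_two_gene_setup()
  calls <- s$call; class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[["AAA_BBB"]]), ref$fusions[[1]]$sequence)
  expect_equal(as.character(back[["CCC"]]), ref$normals[["CCC"]]$sequence)
  expect_false(any(grepl("\\s", names(back))))

  empty_ref <- structure(list(fusions = list(), normals = list(),
                              skipped = data.frame()),
                         class = "fusion_reference")
  expect_error(write_reference_fasta(empty_ref, fa), "empty reference")
})

test_that("annotation tracks are coordinate-consistent with the reference", {
  s <- make_two_gene_setup()
  dom <- data.frame(chrom = "chrB", start = c(60L, 600L),
                    end = c(200L, 950L), name = c("Receptor", "Kinase"))
  class(dom) <- c("domain_features", "data.frame")
  calls <- s$call; class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome, domains = dom)
  dir <- withr::local_tempdir()
  paths <- write_annotation_tracks(ref, dir)
  f <- ref$fusions[[1]]
  L <- nchar(f$sequence)

  gb <- read.delim(paths[["gene_boundaries"]], header = FALSE,
                   col.names = c("ref", "start", "end", "name"))
  fus <- gb[gb$ref == "AAA_BBB", ]
  expect_equal(fus$start, c(0L, f$boundary))
  expect_equal(fus$end, c(f$boundary, L))
  expect_equal(fus$name, c("AAA", "BBB"))

  tx <- read.delim(paths[["transcripts"]], header = FALSE)
  expect_true(all(tx$V2 >= 0))
  fus_tx <- tx[tx$V1 == "AAA_BBB", ]
  expect_true(all(fus_tx$V3 <= L))
  # 3'-partner transcript rows sit at st3 coordinates + boundary exactly
  st3_row <- fus_tx[fus_tx$V4 == "G2.t1", ]
  st3 <- f$st3
  expect_equal(st3_row$V2, f$boundary + st3$transcripts[["G2.t1"]]$start[1])

  # the Kinase domain spans an intron: one merged st interval; all rows
  # within bounds and 3' features offset by the boundary
  dm <- read.delim(paths[["domains"]], header = FALSE,
                   col.names = c("ref", "start", "end", "name"))
  fus_dm <- dm[dm$ref == "AAA_BBB", ]
  expect_setequal(fus_dm$name, c("Receptor", "Kinase"))
  expect_true(all(fus_dm$start >= f$boundary & fus_dm$end <= L))
  expect_equal(fus_dm$start[fus_dm$name == "Receptor"],
               f$boundary + 10L)   # chrB 60 -> st3 10

  bp <- read.delim(paths[["breakpoints"]], header = FALSE)
  expect_equal(nrow(bp), 2L)
  expect_equal(bp$V3 - bp$V2, c(1L, 1L))
})

test_that("whitespace and colon in symbols are sanitized for SAM names", {
  s <- make_two_gene_setup()
  s$genes[["G1"]]$symbol <- "A:A A"
  calls <- s$call; class(calls) <- c("fusion_calls", "data.frame")
  ref <- build_reference(calls, s$genes, s$genome)
  expect_equal(names(ref$fusions), "A_A_A_BBB")
})
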