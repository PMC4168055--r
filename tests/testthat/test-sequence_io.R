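test_that("FASTA reading normalises case and U, tolerates wrapping", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "acgu", ">b", "AC", "GT"), f)
  fa <- read_fasta(f)
  expect_equal(fa$id, c("a", "b"))
  expect_equal(fa$sequence, c("ACGT", "ACGT"))
})

test_that("FASTA edge cases: empty file warns, empty record errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_warning(fa <- read_fasta(f), "empty")
  expect_equal(nrow(fa), 0)
  writeLines(c(">a", "", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "a")
})

test_that("FASTA round-trips modulo normalisation", {
  f <- withr::local_tempfile(fileext = ".fa")
  ids <- c("x", "y")
  seqs <- c(strrep("ACGT", 40), "TTTTAA")
  write_fasta(ids, seqs, f)
  fa <- read_fasta(f)
  expect_equal(fa$id, ids)
  expect_equal(fa$sequence, seqs)
})

test_that("FASTQ reading enforces 4-line records and quality length", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGU", "+", "IIII"), f)
  fq <- read_fastq(f)
  expect_equal(nrow(fq), 1)
  expect_equal(fq$sequence, "ACGT")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACG"), f)
  expect_error(read_fastq(f), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "r1")
})

test_that("count tables order deterministically and round-trip", {
  lib <- srna_library(c(ACGT = 3L, TTTT = 3L, AAAC = 9L), name = "x")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(lib, f)
  tab <- read.delim(f)
  # descending count, ties broken lexicographically
  expect_equal(tab$sequence, c("AAAC", "ACGT", "TTTT"))
  back <- read_count_table(f, name = "x")
  expect_equal(back$tags, lib$tags)
  expect_equal(back$total_redundant, 15L)
  expect_equal(back$total_nonredundant, 3L)
})

test_that("count table reading rejects duplicates and bad counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount", "ACGT\t2", "ACGT\t1"), f)
  expect_error(read_count_table(f), "duplicate")
  writeLines(c("sequence\tcount", "ACGT\t-2"), f)
  expect_error(read_count_table(f), "count")
})

test_that("library totals always equal recomputed sums", {
  lib <- srna_library(c("ACGT", "ACGT", "TTTA"))
  expect_equal(lib$total_redundant, sum(lib$tags))
  expect_equal(lib$total_nonredundant, length(lib$tags))
  expect_error(srna_library(c(ACGT = 0L)), "tags")
})

test_that("methylation track validates context and level", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr2\t100\tCG\t0.9", f)
  tr <- read_methylation_track(f)
  expect_equal(tr$position, 100L)
  expect_equal(tr$level, 0.9)
  writeLines("chr2\t100\tCG\t1.2", f)
  expect_error(read_methylation_track(f), "line 1")
  writeLines("chr2\t100\tXX\t0.5", f)
  expect_error(read_methylation_track(f), "context")
  writeLines(character(0), f)
  expect_warning(tr <- read_methylation_track(f), "empty")
  expect_equal(nrow(tr), 0)
})

test_that("BED, GFF3 and Vienna writers use their dialect conventions", {
  h <- structure(list(id = "g1", start = 520L, end = 570L, density = 12.5,
                      global_density = 1, end_bias = "3p"),
                 class = "hotspot_call")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(list(h), f)
  bed <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(bed[2:3], c("520", "570"))     # BED stays 0-based
  nov <- data.frame(id = "novel_miR_01", seqid = "chr1", start = 99L,
                    end = 174L, mature = "ACGT", star = "TTGG",
                    stringsAsFactors = FALSE)
  g <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(nov, g)
  gff <- readLines(g)
  expect_equal(gff[1], "##gff-version 3")
  expect_match(gff[2], "\t100\t174\t")        # 1-based closed
  s <- fold_mfe("GGGGAAAACCCC")
  v <- withr::local_tempfile(fileext = ".str")
  write_vienna(s, v)
  lines <- readLines(v)
  expect_equal(lines[1], "GGGGAAAACCCC")
  expect_match(lines[2], "^\\(\\(\\(\\(\\.\\.\\.\\.\\)\\)\\)\\) \\(-4.28\\)$")
})
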