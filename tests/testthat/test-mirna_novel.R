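test_that("exact mapping reports stranded occurrences", {
  tag <- "ACGTAGGTTCAAGTCCACGTTT"
  genome <- c(chr1 = paste0(random_dna(200), tag, random_dna(100),
                            revcomp(tag), random_dna(50)))
  lib <- srna_library(setNames(c(4L, 1L), c(tag, "TTGACCTGAGGACCTGAAGGCC")))
  m <- map_reads(lib, genome)
  h <- m$hits[m$hits$tag == tag, ]
  expect_equal(nrow(h), 2)
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(sort(h$pos), c(200L, 322L))
  # absent tag: no positions
  expect_false("TTGACCTGAGGACCTGAAGGCC" %in% m$hits$tag)
  expect_error(map_reads(lib, character(0)), "genome")
})

test_that("exact mapping agrees with the scanning oracle", {
  set.seed(21)
  genome <- c(chr1 = random_dna(400), chr2 = random_dna(300))
  tags <- c(substr(genome[[1]], 51, 74), substr(genome[[2]], 101, 121),
            revcomp(substr(genome[[1]], 201, 224)), random_dna(24))
  lib <- srna_library(setNames(rep(1L, 4), tags))
  m <- map_reads(lib, genome)
  o <- oracle_hamming_scan(names(lib$tags), unname(genome), 0)
  got <- m$hits[order(m$hits$tag, m$hits$seqid, m$hits$pos, m$hits$strand), ]
  o$tag_seq <- names(lib$tags)[o$tag]
  o$seqid <- names(genome)[o$ref]
  o <- o[order(o$tag_seq, o$seqid, o$pos, o$strand), ]
  expect_equal(got$pos, o$pos)
  expect_equal(got$strand, o$strand)
  expect_equal(got$tag, o$tag_seq)
})

test_that("locus clustering is gap-driven with most-abundant candidate", {
  hits <- data.frame(tag = c("A1", "B1", "C1"),
                     count = c(10L, 3L, 7L),
                     seqid = "chr1", pos = c(100L, 150L, 650L),
                     strand = "+", mismatches = 0L, repetitive = FALSE,
                     stringsAsFactors = FALSE)
  hits$tag <- c(strrep("AC", 12), strrep("AG", 12), strrep("AT", 12))
  loci <- cluster_loci(hits, max_gap = 100L)
  expect_length(loci, 2)
  expect_equal(loci[[1]]$candidate, strrep("AC", 12))  # count 10 beats 3
  # 500 nt apart: separate loci
  expect_equal(loci[[2]]$candidate, strrep("AT", 12))
})

test_that("precursor windows always contain the candidate read", {
  genome <- c(chr1 = random_dna(2000))
  tag <- substr(genome[[1]], 1001, 1024)
  lib <- srna_library(setNames(3L, tag))
  m <- map_reads(lib, genome)
  loci <- cluster_loci(m$hits)
  ws <- propose_precursors(loci[[1]], genome)
  expect_gt(length(ws), 3)
  for (w in ws) {
    expect_equal(substr(w$sequence, w$read_offset + 1,
                        w$read_offset + 24), tag)
    expect_true(nchar(w$sequence) %in% c(75, 150, 250))
  }
  # read near the chromosome start: windows are clipped but keep the read
  tag2 <- substr(genome[[1]], 6, 29)
  lib2 <- srna_library(setNames(2L, tag2))
  loci2 <- cluster_loci(map_reads(lib2, genome)$hits)
  ws2 <- propose_precursors(loci2[[1]], genome)
  for (w in ws2)
    expect_equal(substr(w$sequence, w$read_offset + 1,
                        w$read_offset + 24), tag2)
  # window smaller than the read is rejected with a warning
  expect_warning(ws3 <- propose_precursors(loci[[1]], genome,
                                           window_lengths = 10L),
                 "smaller")
  expect_length(ws3, 0)
})

test_that("hairpin validation accepts designed stems and infers the star", {
  set.seed(31)
  mature <- random_dna(24, gc = 0.45)
  hp <- make_stem_window(mature)
  v <- validate_hairpin(hp$window, 24)
  expect_true(v$accepted)
  expect_equal(v$arm, "5p")
  expect_equal(v$star, hp$star)
  # the designed star is the reverse complement shifted by the overhang
  expect_equal(substr(v$star, 1, 22), substr(revcomp(mature), 3, 24))
})

test_that("hairpin validation rejects loop-straddling and unpaired reads", {
  set.seed(32)
  mature <- random_dna(24, gc = 0.45)
  hp <- make_stem_window(mature)
  # shift the claimed read so it straddles the loop
  w <- hp$window
  w$read_offset <- w$read_offset + 16L
  v <- validate_hairpin(w, 24)
  expect_false(v$accepted)
  expect_true(v$reason %in% c("loop_overlap", "self_pairing", "unpaired"))
  # a read placed in unstructured flank fails on pairing
  w2 <- list(sequence = random_dna(80, gc = 0.2), read_offset = 10L)
  v2 <- validate_hairpin(w2, 24)
  if (!v2$accepted) expect_true(nchar(v2$reason) > 0)
})

test_that("discovery recovers planted hairpins and only those", {
  params <- small_scenario_params()
  sim <- build_references(params, seed = 3)
  libs <- simulate_libraries(sim, seed = 3)
  ct <- build_library(libs$ct, name = "ct")$library
  hs <- build_library(libs$hs, name = "hs")$library
  nov <- discover_novel(list(ct = ct, hs = hs), sim$genome, sim$known,
                        seed = 3)
  found <- unique(nov$mature)
  truth <- sim$truth$novel$mature
  expect_gte(length(intersect(found, truth)), length(truth) - 1)
  expect_equal(setdiff(found, truth), character(0))   # precision 1
  expect_true(all(nov$randfold_p <= 0.1))
  expect_true(all(nov$class_one))
  # every reported candidate re-validates: re-folding the precursor
  # reproduces the stored energy and MFEI
  for (i in seq_len(nrow(nov))) {
    seqn <- substr(sim$genome[[nov$seqid[i]]], nov$start[i] + 1L,
                   nov$end[i])
    met <- hairpin_metrics(seqn)
    expect_equal(met$mfe, nov$mfe[i], tolerance = 1e-9)
    expect_equal(met$mfei, nov$mfei[i], tolerance = 1e-9)
  }
})

test_that("discovery excludes known matures and starless hairpins", {
  params <- sim_params(genome_length = 8000L, reads_per_library = 600L,
                       n_novel = 2L, n_background_loci = 3L,
                       repeat_tags_shared = 2L, repeat_tags_ct = 1L,
                       repeat_tags_hs = 1L, hotspot_tags_ct = 2L,
                       hotspot_tags_hs = 3L, n_cds = 2L, n_silenced = 1L,
                       bystander_tags = 2L)
  sim <- build_references(params, seed = 5)
  libs <- simulate_libraries(sim, seed = 5)
  ct <- build_library(libs$ct, name = "ct")$library
  # treat the first planted mature as a known reference: it must vanish
  known <- data.frame(full_name = "zma-miR999",
                      family = "miR999",
                      sequence = sim$truth$novel$mature[1],
                      stringsAsFactors = FALSE)
  nov <- discover_novel(list(ct = ct), sim$genome, known, seed = 5)
  expect_false(sim$truth$novel$mature[1] %in% nov$mature)
  # remove the star reads of the second hairpin: no class-I call
  star2 <- sim$truth$novel$star[2]
  ct2 <- srna_library(ct$tags[setdiff(names(ct$tags), star2)],
                      name = "ct")
  nov2 <- discover_novel(list(ct = ct2), sim$genome, known = NULL,
                         seed = 5)
  expect_false(sim$truth$novel$mature[2] %in% nov2$mature)
})
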