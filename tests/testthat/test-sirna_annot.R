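make_repeat_refs <- function(seed = 41) {
  set.seed(seed)
  data.frame(id = c("Copia_1", "Gypsy_1", "CACTA_1"),
             class = c("Copia", "Gypsy", "CACTA"),
             sequence = c(random_dna(500), random_dna(500),
                          random_dna(400)),
             stringsAsFactors = FALSE)
}

test_that("repeat FASTA headers parse the id#Class dialect", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">el1#Copia", "ACGTACGT", ">el2", "TTGGCCAA"), f)
  r <- read_repeat_fasta(f)
  expect_equal(r$id, c("el1", "el2"))
  expect_equal(r$class, c("Copia", "Unknown"))
})

test_that("tag alignment keeps only minimal-mismatch hits", {
  refs <- make_repeat_refs()
  exact <- substr(refs$sequence[1], 101, 124)
  h <- align_tags(exact, refs)
  expect_true(all(h$mismatches == 0))
  expect_equal(unique(h$class), "Copia")
  expect_true(any(h$pos == 100))
  # 2 mm from Copia, 1 mm from Gypsy: only the Gypsy hit survives
  g <- substr(refs$sequence[2], 201, 224)
  tag <- g
  substr(tag, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(g, 5, 5))[1]
  co <- substr(refs$sequence[1], 301, 324)
  refs2 <- refs
  # plant a 2-mm relative of the tag inside Copia
  twomm <- tag
  substr(twomm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, 10, 10))[1]
  substr(twomm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, 15, 15))[1]
  substr(refs2$sequence[1], 301, 324) <- twomm
  h2 <- align_tags(tag, refs2)
  expect_true(all(h2$mismatches == min(h2$mismatches)))
  expect_equal(unique(h2$class[h2$mismatches == 1]), "Gypsy")
  expect_false("Copia" %in% h2$class)
  # 4 mm from everything: no hit
  set.seed(99)
  h3 <- align_tags(random_dna(24), refs)
  expect_true(nrow(h3) == 0 || all(h3$mismatches <= 3))
})

test_that("alignment equals a brute-force Hamming scan", {
  set.seed(43)
  refs <- data.frame(id = c("r1", "r2"), class = c("A", "B"),
                     sequence = c(random_dna(300), random_dna(250)),
                     stringsAsFactors = FALSE)
  tags <- c(substr(refs$sequence[1], 31, 52),
            revcomp(substr(refs$sequence[2], 101, 124)),
            random_dna(20))
  got <- align_tags(tags, refs, max_mismatch = 3L)
  ora <- oracle_hamming_scan(tags, refs$sequence, 3)
  # oracle keeps all hits; apply the best-hit policy per tag
  keep <- unlist(lapply(split(seq_len(nrow(ora)), ora$tag), function(ix)
    ix[ora$mismatches[ix] == min(ora$mismatches[ix])]))
  ora <- ora[sort(keep), ]
  expect_equal(nrow(got), nrow(ora))
  got <- got[order(match(got$tag, tags), got$ref_id, got$pos, got$strand), ]
  ora <- ora[order(ora$tag, ora$ref, ora$pos, ora$strand), ]
  expect_equal(got$pos, ora$pos)
  expect_equal(got$mismatches, ora$mismatches)
  expect_equal(match(got$tag, tags), ora$tag)
})

test_that("repeat classification tallies shared and exclusive tags", {
  set.seed(44)
  refs <- make_repeat_refs()
  shared <- vapply(1:10, function(i) {
    s <- sample(450, 1); substr(refs$sequence[1], s, s + 23)
  }, character(1))
  ct_only <- vapply(1:5, function(i) {
    s <- sample(450, 1); substr(refs$sequence[2], s, s + 23)
  }, character(1))
  hs_only <- vapply(1:7, function(i) {
    s <- sample(350, 1); substr(refs$sequence[3], s, s + 23)
  }, character(1))
  shared <- unique(shared); ct_only <- unique(ct_only)
  hs_only <- unique(hs_only)
  h_ct <- align_tags(c(shared, ct_only), refs)
  h_hs <- align_tags(c(shared, hs_only), refs)
  cl <- classify_repeats(h_ct, h_hs)
  sh <- cl$shared
  expect_equal(sh$shared[sh$class == "Copia"], length(shared))
  expect_equal(sh$exclusive_ct[sh$class == "Gypsy"], length(ct_only))
  expect_equal(sh$exclusive_hs[sh$class == "CACTA"], length(hs_only))
  # classification is a partition: each tag has exactly one primary class
  expect_equal(sum(cl$class_counts$unique_ct),
               length(unique(c(shared, ct_only))))
  # 24-nt planting makes 24 the modal length
  ld <- cl$length_dist
  tot <- tapply(ld$count_ct + ld$count_hs, ld$length, sum)
  expect_equal(as.integer(names(which.max(tot))), 24L)
})

test_that("ties between classes are counted once and flagged", {
  refs <- data.frame(id = c("a1", "b1"), class = c("Aclass", "Bclass"),
                     sequence = c(paste0("AAAA", strrep("ACGT", 10)),
                                  paste0("TTTT", strrep("ACGT", 10))),
                     stringsAsFactors = FALSE)
  tag <- strrep("ACGT", 5)       # exact inside both references
  h <- align_tags(tag, refs)
  cl <- classify_repeats(h, h[0, ])
  expect_equal(sum(cl$class_counts$unique_ct), 1)  # counted once
  expect_equal(cl$class_counts$unique_ct[
    cl$class_counts$class == "Aclass"], 1)          # lexicographic primary
  expect_equal(sum(cl$class_counts$ambiguous_ct), 1)
})

test_that("per-CDS profiles use strict thresholds", {
  set.seed(45)
  cds <- data.frame(id = c("big", "edge", "sparse"),
                    sequence = c(random_dna(3000), random_dna(600),
                                 random_dna(600)),
                    stringsAsFactors = FALSE)
  draw <- function(seqn, n) {
    starts <- sample(nchar(seqn) - 24, n)
    unique(substr(rep(seqn, n), starts + 1, starts + 24))
  }
  big_tags <- character(0)
  while (length(big_tags) < 1001)
    big_tags <- unique(c(big_tags, draw(cds$sequence[1], 200)))
  big_tags <- big_tags[1:1001]
  edge51 <- character(0)
  while (length(edge51) < 51)
    edge51 <- unique(c(edge51, draw(cds$sequence[2], 20)))
  edge51 <- edge51[1:51]
  sparse50 <- character(0)
  while (length(sparse50) < 50)
    sparse50 <- unique(c(sparse50, draw(cds$sequence[3], 20)))
  sparse50 <- sparse50[1:50]
  ct <- srna_library(setNames(rep(1L, 1001 + 50), c(big_tags, sparse50)),
                     name = "ct")
  hs <- srna_library(setNames(rep(1L, 51), edge51), name = "hs")
  pr <- profile_cds(list(ct = ct, hs = hs), cds)
  expect_true(pr$big$selected[["ct"]])
  expect_true(pr$big$high_density[["ct"]])
  expect_true(pr$edge$selected[["hs"]])       # 51 > 50
  expect_false(pr$sparse$selected[["ct"]])    # 50 is not > 50
  expect_false(pr$edge$high_density[["hs"]])
  expect_equal(pr$big$unique[["ct"]], 1001L)
  expect_equal(length(pr$big$coverage$ct), 3000L)
  # empty tag set gives empty profiles
  e <- srna_library(name = "e")
  pr0 <- profile_cds(list(ct = e, hs = e), cds)
  expect_equal(pr0$big$unique[["ct"]], 0L)
})

test_that("hotspot calls find planted windows and label end bias", {
  set.seed(46)
  cds <- data.frame(id = "g1", sequence = random_dna(600),
                    stringsAsFactors = FALSE)
  hot <- vapply(1:40, function(i) {
    s <- sample(520:546, 1); substr(cds$sequence, s, s + 23)
  }, character(1))
  cold <- vapply(1:4, function(i) {
    s <- sample(100:200, 1); substr(cds$sequence, s, s + 23)
  }, character(1))
  lib <- srna_library(setNames(rep(1L, length(unique(c(hot, cold)))),
                               unique(c(hot, cold))), name = "ct")
  pr <- profile_cds(list(ct = lib, hs = srna_library(name = "hs")), cds)
  h <- hotspot(pr$g1)
  expect_true(h$start < 570 && h$end > 520)   # overlaps the planting
  expect_equal(h$end_bias, "3p")
  expect_gt(h$density, h$global_density)
  # uniform coverage: hotspot density equals global density, internal
  pr$g1$coverage$ct <- rep(2L, 600); pr$g1$coverage$hs <- rep(0L, 600)
  hu <- hotspot(pr$g1)
  expect_equal(hu$density, hu$global_density)
  # single tag: hotspot covers its window
  lib1 <- srna_library(setNames(1L, substr(cds$sequence, 301, 324)),
                       name = "x")
  pr1 <- profile_cds(list(ct = lib1, hs = srna_library(name = "hs")), cds)
  h1 <- hotspot(pr1$g1)
  expect_true(h1$start <= 300 && h1$end >= 310)
})

test_that("per-CDS Fisher verdict matches the study-scale example", {
  v <- cds_differential(721, 1545, 750691, 1396687)
  expect_lt(v$p_value, 0.05)
  expect_true(v$significant)
  expect_equal(v$direction, "hs")
  # equal proportions: not significant
  v2 <- cds_differential(50, 100, 10000, 20000)
  expect_false(v2$significant)
  v3 <- cds_differential(5, 5, 1000, 1000)
  expect_equal(v3$p_value, 1)
})
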