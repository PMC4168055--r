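test_that("adapter trimming handles full, prefix and absent adapters", {
  p <- preprocess_params()
  expect_equal(trim_adapter("ACGTACGTCTGTAGGCACCATCAATGG", p), "ACGTACGT")
  # 8-nt adapter prefix ending at the 3' end
  expect_equal(trim_adapter("ACGTACGTCTGTAGGC", p), "ACGTACGT")
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGT", p)))
  p2 <- preprocess_params(discard_no_adapter = FALSE)
  expect_equal(trim_adapter("ACGTACGTACGTACGT", p2), "ACGTACGTACGTACGT")
})

test_that("read filtering applies N, size, complexity, contaminants", {
  p <- preprocess_params(contaminant_refs = data.frame(
    id = "trna1", sequence = strrep("GATCCA", 20)))
  expect_equal(filter_read("ACGTACGTACGTACGTA", p), "size")     # 17 nt
  expect_equal(filter_read(strrep("A", 24), p), "low_complexity")
  tr <- substr(strrep("GATCCA", 20), 3, 26)                      # 24 nt
  expect_equal(filter_read(tr, p), "contaminant")
  one_mm <- paste0("T", substr(tr, 2, 24))
  expect_equal(filter_read(one_mm, p), "contaminant")
  expect_equal(filter_read("ACGTAGGTTCAAGTCCACGTTT", p), "keep")
  expect_equal(filter_read("ACGTAGGTTCANGTCCACGTTT", p), "N")
})

test_that("build_library bookkeeping matches a hand tally", {
  ad <- "CTGTAGGCACCATCAAT"
  keep1 <- "ACGTAGGTTCAAGTCCACGTTT"
  keep2 <- "TGCATCAGGATCCTAGGCATCGAT"
  reads <- c(paste0(keep1, ad), paste0(keep1, ad), paste0(keep1, ad),
             paste0(keep2, ad, "GG"),
             paste0("ACGTAGGTTCANGTCCACGTTT", ad),      # N
             paste0("ACGTACGTACGTACGTA", ad),           # size (17)
             paste0(strrep("A", 24), ad),               # low complexity
             "ACGTACGTACGTACGTACGTACGTACGTACGT",        # no adapter
             paste0(strrep("TC", 12), ad),              # keep
             paste0("ACGTACGTACGTACG", ad))             # size (15)
  res <- build_library(reads, name = "hand")
  s <- res$summary
  expect_equal(unname(s["raw_reads"]), 10L)
  expect_equal(unname(s["discarded_no_adapter"]), 1L)
  expect_equal(unname(s["discarded_N"]), 1L)
  expect_equal(unname(s["discarded_size"]), 2L)
  expect_equal(unname(s["discarded_low_complexity"]), 1L)
  expect_equal(unname(s["retained_redundant"]), 5L)
  expect_equal(unname(s["retained_nonredundant"]), 3L)
  expect_equal(unname(res$library$tags[keep1]), 3L)
  # every raw read is in exactly one category
  expect_equal(unname(s["raw_reads"]),
               sum(s[c("discarded_no_adapter", "discarded_N",
                       "discarded_size", "discarded_contaminant",
                       "discarded_low_complexity", "retained_redundant")]))
})

test_that("preprocessing an already-clean library is idempotent", {
  p <- preprocess_params(discard_no_adapter = FALSE)
  clean <- c("ACGTAGGTTCAAGTCCACGTTT", "TGCATCAGGATCCTAGGCATCGAT")
  res <- build_library(rep(clean, 2), p)
  res2 <- build_library(rep(names(res$library$tags),
                            res$library$tags), p)
  expect_equal(res2$library$tags, res$library$tags)
})

test_that("empty or fully-discarded input yields empty library", {
  expect_warning(res <- build_library(character(0)), "empty")
  expect_equal(res$library$total_redundant, 0L)
  expect_warning(res <- build_library("ACGTACGTACGTACGTACGTACGT"),
                 "empty")
  expect_equal(res$library$total_nonredundant, 0L)
})

test_that("size distribution fractions sum to one and match planting", {
  lib <- srna_library(setNames(c(9L, 1L),
                               c(strrep("AC", 12), "ACGTACGTACGTACGTACGTA")))
  sd <- size_distribution(lib)
  expect_equal(sum(sd$redundant_fraction), 1)
  expect_equal(sum(sd$nonredundant_fraction), 1)
  expect_equal(sd$redundant_fraction[sd$length == 24], 0.9)
  # generator scenario: planted 24-nt peak recovered within sampling error
  sc <- default_scenario()
  dist <- size_distribution(sc$ct$library)
  expect_lt(abs(dist$redundant_fraction[dist$length == 24] - 0.45), 0.02)
})

test_that("uniform counts give a flat distribution", {
  seqs <- vapply(18:28, function(l) strrep("A", l), character(1))
  # distinct sequences per length to avoid low-complexity interplay:
  # size_distribution works on any library, no filtering involved
  lib <- srna_library(setNames(rep(2L, 11), seqs))
  sd <- size_distribution(lib)
  expect_equal(sd$redundant_fraction, rep(1 / 11, 11))
})
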