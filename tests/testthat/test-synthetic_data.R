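test_that("generation is deterministic under a fixed seed", {
  p <- small_scenario_params()
  a <- build_references(p, seed = 8)
  b <- build_references(p, seed = 8)
  expect_identical(a$genome, b$genome)
  expect_identical(a$known, b$known)
  expect_identical(a$repeats, b$repeats)
  expect_identical(a$truth$novel, b$truth$novel)
  la <- simulate_libraries(a, seed = 8)
  lb <- simulate_libraries(b, seed = 8)
  expect_identical(la$ct, lb$ct)
  expect_identical(la$hs, lb$hs)
  ta <- simulate_tracks(a, seed = 8)
  tb <- simulate_tracks(b, seed = 8)
  expect_identical(ta$methylation, tb$methylation)
  expect_identical(ta$coverage_hs, tb$coverage_hs)
  # a different seed changes the data
  expect_false(identical(a$genome,
                         build_references(p, seed = 9)$genome))
})

test_that("planted hairpins validate by construction", {
  p <- small_scenario_params()
  sim <- build_references(p, seed = 2)
  for (i in seq_len(nrow(sim$truth$novel))) {
    tr <- sim$truth$novel[i, ]
    w_start <- max(0L, tr$start - 5L)
    w <- list(seqid = "chr1", start = w_start,
              end = w_start + 75L,
              sequence = substr(sim$genome[["chr1"]], w_start + 1L,
                                w_start + 75L),
              read_offset = tr$start - w_start)
    v <- validate_hairpin(w, tr$mature_length)
    expect_true(v$accepted, label = tr$id)
    expect_equal(v$star, tr$star, label = tr$id)
  }
})

test_that("library simulation plants counts at the configured ratios", {
  sc <- default_scenario()
  exp_tab <- sc$raw$expected
  p <- sc$sim$truth$params
  # star reads present for every hairpin in both built libraries
  stars <- sc$sim$truth$novel$star
  expect_true(all(stars %in% names(sc$ct$library$tags)))
  expect_true(all(stars %in% names(sc$hs$library$tags)))
  # star:mature read ratio near the configured 0.05
  mats <- sc$sim$truth$novel$mature
  ratio <- sum(sc$ct$library$tags[stars]) / sum(sc$ct$library$tags[mats])
  expect_lt(abs(ratio - p$star_ratio), 0.03)
  # every planted tag traces to the truth table
  expect_true(all(mats %in% exp_tab$tag))
  expect_true(all(sc$sim$truth$repeat_tags$tag %in% exp_tab$tag))
})

test_that("tracks elevate hotspot methylation and suppress coverage", {
  p <- small_scenario_params()
  sim <- build_references(p, seed = 4)
  tr <- simulate_tracks(sim, seed = 4)
  sil <- sim$truth$silenced_cds[1]
  hs_iv <- sim$truth$hotspot
  m_in <- region_methylation(tr$methylation, sil, hs_iv$start,
                             hs_iv$end, "CG")
  m_out <- region_methylation(tr$methylation, sil, 0, hs_iv$start, "CG")
  expect_lt(abs(m_in - (p$meth_baseline + p$meth_delta)), 0.1)
  expect_lt(abs(m_out - p$meth_baseline), 0.1)
  # CHH stays at baseline inside the hotspot
  m_chh <- region_methylation(tr$methylation, sil, hs_iv$start,
                              hs_iv$end, "CHH")
  if (!is.na(m_chh)) expect_lt(abs(m_chh - p$meth_baseline), 0.15)
  # coverage suppressed only in the silenced hotspot
  r <- region_expression(tr$coverage_ct, tr$coverage_hs, sil,
                         hs_iv$start, hs_iv$end, tr$total_ct,
                         tr$total_hs)
  expect_lt(r$log2_ratio, 0)
  other <- setdiff(sim$cds$id, sim$truth$silenced_cds)[1]
  r2 <- region_expression(tr$coverage_ct, tr$coverage_hs, other,
                          0, p$cds_length, tr$total_ct, tr$total_hs)
  expect_lt(abs(r2$log2_ratio), 0.3)
})

test_that("a zero-everything parameterisation yields background only", {
  p <- sim_params(genome_length = 5000L, reads_per_library = 500L,
                  n_novel = 0L, known_ratios = c(miR1 = 1),
                  known_prop = 0, n_background_loci = 5L,
                  repeat_tags_shared = 0L, repeat_tags_ct = 0L,
                  repeat_tags_hs = 0L, hotspot_tags_ct = 0L,
                  hotspot_tags_hs = 0L, bystander_tags = 0L,
                  n_cds = 2L, n_silenced = 1L)
  sim <- build_references(p, seed = 6)
  expect_equal(nrow(sim$truth$novel), 0)
  libs <- simulate_libraries(sim, seed = 6)
  expect_length(libs$ct, 500)
})
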