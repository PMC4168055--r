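# Independent brute-force oracles. These share no code path with the
# package implementations they check.

# -- folding: enumerate every pseudoknot-free structure (hairpin >= 3)
# and evaluate each with the loop-decomposition evaluator ----------------
.oracle_pairable <- function(a, b)
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")

oracle_enum_structures <- function(chars) {
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i + 1, j)                     # i unpaired
    for (k in (i + 4):j) {
      if (!.oracle_pairable(chars[i], chars[k])) next
      left <- rec(i + 1, k - 1)
      right <- if (k < j) rec(k + 1, j) else
        list(matrix(integer(0), ncol = 2))
      for (L in left) for (R in right)
        out[[length(out) + 1]] <- rbind(c(i, k), L, R)
    }
    out
  }
  rec(1, length(chars))
}

oracle_brute_mfe <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  structs <- oracle_enum_structures(chars)
  min(vapply(structs, function(p) {
    if (!nrow(p)) return(0)
    colnames(p) <- c("i", "j")
    structure_energy(seq, p[order(p[, 1]), , drop = FALSE])
  }, numeric(1)))
}

# -- Fisher: full enumeration over tables with the observed margins,
# probabilities from binomial coefficients ------------------------------
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(r1 + r2, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# -- alignment: all-positions Hamming scan in plain R -------------------
oracle_hamming_scan <- function(tags, refs, max_mm, both_strands = TRUE) {
  out <- list()
  for (t in seq_along(tags)) {
    for (strand in if (both_strands) c("+", "-") else "+") {
      q <- if (strand == "+") tags[t] else revcomp(tags[t])
      qc <- strsplit(q, "")[[1]]
      for (r in seq_along(refs)) {
        rc <- strsplit(refs[r], "")[[1]]
        if (length(rc) < length(qc)) next
        for (p in 0:(length(rc) - length(qc))) {
          mm <- sum(qc != rc[(p + 1):(p + length(qc))])
          if (mm <= max_mm)
            out[[length(out) + 1]] <- data.frame(
              tag = t, ref = r, pos = p, strand = strand,
              mismatches = mm)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(tag = integer(), ref = integer(), pos = integer(),
                      strand = character(), mismatches = integer()))
  do.call(rbind, out)
}

# -- target scoring: exhaustive gapped alignment with a 2-gap budget ----
oracle_align_score <- function(mirna, site,
                               seed_from = 2, seed_to = 13) {
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])
  w <- ifelse(seq_along(m) >= seed_from & seq_along(m) <= seed_to, 2, 1)
  subcost <- function(i, a, b) {
    wc <- paste0(a, b) %in% c("AT", "TA", "GC", "CG")
    gu <- paste0(a, b) %in% c("GT", "TG")
    (if (wc) 0 else if (gu) 0.5 else 1) * w[i]
  }
  rec <- function(i, j, gaps) {
    if (i == 0 && j == 0) return(0)
    if (abs(i - j) > gaps) return(Inf)
    best <- Inf
    if (i > 0 && j > 0)
      best <- min(best, rec(i - 1, j - 1, gaps) + subcost(i, m[i], t[j]))
    if (gaps > 0) {
      if (i > 0) best <- min(best, rec(i - 1, j, gaps - 1) + 2 * w[i])
      if (j > 0) best <- min(best, rec(i, j - 1, gaps - 1) +
                               2 * w[max(i, 1)])
    }
    best
  }
  rec(length(m), length(t), 2)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# designed hairpin: perfect stem with mature on the 5' arm; star by
# Dicer geometry extends 2 nt beyond the stem into the right flank
make_stem_window <- function(mature, loop = "AATTCGGAAT",
                             lflank = "GATTAC", rflank = "CCAATGGT") {
  seqn <- paste0(lflank, mature, loop, revcomp(mature), rflank)
  star_start0 <- nchar(lflank) + nchar(mature) + nchar(loop) + 2L
  list(window = list(seqid = "w", start = 0L, end = nchar(seqn),
                     sequence = seqn,
                     read_offset = nchar(lflank)),
       star = substr(seqn, star_start0 + 1L,
                     star_start0 + nchar(mature)))
}
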