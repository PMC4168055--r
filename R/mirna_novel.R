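#' Discovery parameters for novel miRNA candidates
#'
#' @param max_mismatch genome-mapping mismatches (default 0: candidate and
#'   star must be literal genome substrings for duplex logic).
#' @param max_gap single-linkage cluster gap (nt).
#' @param multimap_ceiling tags mapping to more loci are flagged
#'   repetitive and skipped as candidates.
#' @param window_lengths precursor window lengths tried around the
#'   candidate read.
#' @param max_unpaired maximum unpaired mature bases in the hairpin.
#' @param randfold_n shuffles for the randomization test.
#' @param randfold_cutoff maximum acceptable shuffle p-value.
#' @return object of class `novel_params`.
#' @export
novel_params <- function(max_mismatch = 0L, max_gap = 100L,
                         multimap_ceiling = 20L,
                         window_lengths = c(75L, 150L, 250L),
                         max_unpaired = 4L, randfold_n = 100L,
                         randfold_cutoff = 0.1) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 max_gap = as.integer(max_gap),
                 multimap_ceiling = as.integer(multimap_ceiling),
                 window_lengths = sort(as.integer(window_lengths)),
                 max_unpaired = as.integer(max_unpaired),
                 randfold_n = as.integer(randfold_n),
                 randfold_cutoff = randfold_cutoff),
            class = "novel_params")
}

# exact-match mapping via per-length substring hashing; returns the same
# columns as scan_tags (tag/ref indices, 0-based pos, strand, mismatches)
.exact_map <- function(tags, genome) {
  rc <- revcomp(tags)
  out <- list()
  for (r in seq_along(genome)) {
    g <- genome[[r]]
    gl <- nchar(g)
    for (L in sort(unique(nchar(tags)))) {
      if (L > gl) next
      idx_f <- which(nchar(tags) == L)
      starts <- seq_len(gl - L + 1L)
      subs <- substring(g, starts, starts + L - 1L)
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") tags[idx_f] else rc[idx_f]
        hit <- which(subs %in% qry)
        if (!length(hit)) next
        ti <- idx_f[match(subs[hit], qry)]
        out[[length(out) + 1L]] <- data.frame(
          tag = ti, ref = r, pos = hit - 1L, strand = strand,
          mismatches = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tag = integer(), ref = integer(), pos = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Map library tags to a genome
#'
#' Reports all occurrences of each tag on both strands. Tags exceeding the
#' multi-mapping ceiling are flagged repetitive.
#'
#' @param library an [srna_library()].
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatch allowed mismatches (default 0).
#' @param multimap_ceiling multi-mapping flag threshold.
#' @return list with `hits` (data.frame: `tag` sequence, `count`, `seqid`,
#'   `pos` 0-based, `strand`, `mismatches`, `repetitive`) and
#'   `n_loci` (named vector of hit counts per mapped tag).
#' @export
map_reads <- function(library, genome, max_mismatch = 0L,
                      multimap_ceiling = 20L) {
  stopifnot(inherits(library, "srna_library"))
  if (!length(genome) || any(nchar(genome) == 0)) stop("empty genome")
  tags <- names(library$tags)
  hits <- if (max_mismatch == 0L)
    .exact_map(tags, genome)
  else
    scan_tags(tags, unname(genome), max_mismatch = max_mismatch,
              both_strands = TRUE, best_only = TRUE)
  if (!nrow(hits))
    return(list(hits = data.frame(tag = character(), count = integer(),
                                  seqid = character(), pos = integer(),
                                  strand = character(),
                                  mismatches = integer(),
                                  repetitive = logical(),
                                  stringsAsFactors = FALSE),
                n_loci = integer(0)))
  n_loci <- table(hits$tag)
  out <- data.frame(tag = tags[hits$tag],
                    count = as.integer(library$tags[hits$tag]),
                    seqid = names(genome)[hits$ref],
                    pos = hits$pos, strand = hits$strand,
                    mismatches = hits$mismatches,
                    repetitive =
                      as.integer(n_loci[as.character(hits$tag)]) >
                      multimap_ceiling,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(hits = out,
       n_loci = setNames(as.integer(n_loci), tags[as.integer(names(n_loci))]))
}

#' Cluster mapped positions into small-RNA loci
#'
#' Single-linkage clustering along each chromosome, strand-insensitive:
#' positions closer than `max_gap` join one locus. The locus candidate
#' read is its most abundant member (ties broken by sequence).
#'
#' @param hits mapping data.frame from [map_reads()] (`$hits`).
#' @param max_gap maximum gap (nt) between member start positions.
#' @return list of loci; each locus is a list with `seqid`, `start`,
#'   `end` (0-based half-open over member footprints), `members`
#'   (data.frame) and `candidate` (tag sequence).
#' @export
cluster_loci <- function(hits, max_gap = 100L) {
  if (!nrow(hits)) return(list())
  hits <- hits[!hits$repetitive, , drop = FALSE]
  if (!nrow(hits)) return(list())
  out <- list()
  for (chr in unique(hits$seqid)) {
    h <- hits[hits$seqid == chr, , drop = FALSE]
    h <- h[order(h$pos), , drop = FALSE]
    gap_break <- c(FALSE, diff(h$pos) > max_gap)
    cl <- cumsum(gap_break)
    for (g in unique(cl)) {
      m <- h[cl == g, , drop = FALSE]
      best <- m[order(-m$count, m$tag), , drop = FALSE][1, ]
      out[[length(out) + 1L]] <- list(
        seqid = chr,
        start = min(m$pos),
        end = max(m$pos + nchar(m$tag)),
        members = m,
        candidate = best$tag)
    }
  }
  out
}

#' Propose precursor windows around a locus candidate read
#'
#' For each window length, emits windows that place the candidate read on
#' the left (5') arm and on the right (3') arm, clipped at chromosome
#' boundaries; all windows contain the full candidate read.
#'
#' @param locus a locus from [cluster_loci()].
#' @param genome named character vector of chromosome sequences.
#' @param window_lengths integer vector of window lengths.
#' @param pad offset keeping the read off the window edge (nt).
#' @return list of windows: each has `seqid`, `start`, `end` (0-based
#'   half-open), `sequence`, `read_offset` (0-based offset of the
#'   candidate read in the window).
#' @export
propose_precursors <- function(locus, genome,
                               window_lengths = c(75L, 150L, 250L),
                               pad = 5L) {
  cand <- locus$candidate
  rl <- nchar(cand)
  chr_seq <- genome[[locus$seqid]]
  chr_len <- nchar(chr_seq)
  # candidate read position: most abundant member's plus-strand placement
  m <- locus$members[locus$members$tag == cand, , drop = FALSE][1, ]
  rs <- m$pos
  out <- list()
  for (W in window_lengths) {
    if (W < rl) {
      warning("window length ", W, " smaller than candidate read; skipped")
      next
    }
    starts <- unique(c(max(0L, rs - pad),                       # 5' arm
                       max(0L, min(rs + rl + pad, chr_len) - W))) # 3' arm
    for (s in starts) {
      e <- min(s + W, chr_len)
      s <- max(0L, min(s, rs))            # never clip the read
      e <- max(e, rs + rl)
      if (e - s < rl) next
      out[[length(out) + 1L]] <- list(
        seqid = locus$seqid, start = as.integer(s), end = as.integer(e),
        sequence = substr(chr_seq, s + 1L, e),
        read_offset = as.integer(rs - s))
    }
  }
  # drop duplicate windows
  key <- vapply(out, function(w) paste(w$start, w$end), character(1))
  out[!duplicated(key)]
}

#' Validate a hairpin window and infer the miRNA* sequence
#'
#' Folds the window and accepts when the mature read lies entirely on one
#' arm of a hairpin (no loop straddling), at most `max_unpaired` mature
#' bases are unpaired, and the duplex partner (miRNA*) can be computed
#' from the pairings with a 2-nt 3' overhang (Dicer geometry).
#'
#' @param window a window from [propose_precursors()] (needs `sequence`
#'   and `read_offset`).
#' @param read_length length of the candidate mature read.
#' @param max_unpaired maximum unpaired mature bases.
#' @param params energy parameters for folding.
#' @return list with `accepted` flag; when accepted: `star` sequence,
#'   `star_start` (0-based in window), `arm` ("5p"/"3p"), `unpaired`,
#'   `structure` ([fold_mfe()] result); when rejected: `reason`.
#' @export
validate_hairpin <- function(window, read_length,
                             max_unpaired = 4L,
                             params = energy_parameters()) {
  fold <- fold_mfe(window$sequence, params)
  i0 <- window$read_offset + 1L                 # 1-based mature span
  i1 <- window$read_offset + read_length
  partner <- rep(NA_integer_, nchar(window$sequence))
  if (nrow(fold$pairs)) {
    partner[fold$pairs[, 1]] <- fold$pairs[, 2]
    partner[fold$pairs[, 2]] <- fold$pairs[, 1]
  }
  span <- i0:i1
  prt <- partner[span]
  paired <- which(!is.na(prt))
  unpaired <- read_length - length(paired)
  if (length(paired) == 0)
    return(list(accepted = FALSE, reason = "unpaired",
                unpaired = unpaired, structure = fold))
  if (unpaired > max_unpaired)
    return(list(accepted = FALSE, reason = "unpaired",
                unpaired = unpaired, structure = fold))
  # partners inside the mature span => mature folds on itself
  if (any(prt[paired] >= i0 & prt[paired] <= i1))
    return(list(accepted = FALSE, reason = "self_pairing",
                unpaired = unpaired, structure = fold))
  # all partners on one side (one arm, no loop straddle)
  if (!(all(prt[paired] > i1) || all(prt[paired] < i0)))
    return(list(accepted = FALSE, reason = "loop_overlap",
                unpaired = unpaired, structure = fold))
  arm <- if (all(prt[paired] > i1)) "5p" else "3p"
  # star span via duplex geometry with a 2-nt 3' overhang: partner
  # positions decrease as the mature index increases (antiparallel), so
  # extrapolate across unpaired mature edges and shift the whole partner
  # span by +2 (both strands of a Dicer duplex carry 2-nt 3' overhangs)
  a1 <- span[paired[1]]; a2 <- span[paired[length(paired)]]
  p_at_i0 <- partner[a1] + (a1 - i0)
  p_at_i1 <- partner[a2] - (i1 - a2)
  star_start <- p_at_i1 + 2L
  star_end <- p_at_i0 + 2L
  n <- nchar(window$sequence)
  star_start <- max(1L, min(star_start, n))
  star_end <- max(1L, min(star_end, n))
  if (star_end <= star_start)
    return(list(accepted = FALSE, reason = "no_star_span",
                unpaired = unpaired, structure = fold))
  star <- substr(window$sequence, star_start, star_end)
  list(accepted = TRUE, star = star,
       star_start = as.integer(star_start - 1L), arm = arm,
       unpaired = as.integer(unpaired), structure = fold)
}

#' Discover novel class-I miRNA candidates
#'
#' Full discovery path: map tags to the genome, cluster into loci, fold
#' candidate precursor windows, validate the miRNA/miRNA* duplex, apply
#' the dinucleotide-shuffle randomization test, and exclude matures
#' within 1 mismatch of a known reference. A candidate is class I iff its
#' star sequence is observed (count >= 1) in the same library as the
#' mature. Candidate windows are evaluated shortest-first and the first
#' accepted hairpin that passes the star and randomization gates is
#' kept, so the reported precursor is the shortest one explaining the
#' duplex. MFEI is recorded for every candidate but never used as a
#' filter.
#'
#' @param libraries named list of [srna_library()] objects (e.g.
#'   `list(CT = ..., Hs = ...)`).
#' @param genome named character vector of chromosome sequences.
#' @param known_refs mature reference data.frame ([read_mature_mirna()]);
#'   `NULL` disables the exclusion.
#' @param params a [novel_params()].
#' @param seed seed for the randomization tests.
#' @param energy energy parameters.
#' @return data.frame of candidates, one row per precursor: `id`,
#'   `seqid`, `start`, `end`, `precursor_length`, `mfe`, `gc_percent`,
#'   `amfe`, `mfei`, `randfold_p`, `mature`, `mature_length`, `star`,
#'   `arm`, `class_one`, `library` (comma-joined names of the libraries
#'   in which the duplex was observed), plus per-library RPM columns
#'   `rpm_<name>`; attribute `structures` holds the folded precursors.
#' @export
discover_novel <- function(libraries, genome, known_refs = NULL,
                           params = novel_params(), seed = 1L,
                           energy = energy_parameters()) {
  stopifnot(is.list(libraries), length(libraries) >= 1,
            !is.null(names(libraries)))
  rows <- list(); structures <- list()
  for (lib_name in names(libraries)) {
    lib <- libraries[[lib_name]]
    mapped <- map_reads(lib, genome, params$max_mismatch,
                        params$multimap_ceiling)
    loci <- cluster_loci(mapped$hits, params$max_gap)
    for (locus in loci) {
      cand <- locus$candidate
      rl <- nchar(cand)
      # exclusion: mature within 1 mismatch of a known mature
      if (!is.null(known_refs) && nrow(known_refs)) {
        tmp <- srna_library(setNames(1L, cand), name = "probe")
        if (nrow(match_known(tmp, known_refs, max_mismatch = 1L,
                             end_overhang = 2L))) next
      }
      windows <- propose_precursors(locus, genome, params$window_lengths)
      # shortest window first (ties: lower energy preferred below); the
      # first accepted hairpin passing the star and randomization gates
      # is kept, so the reported precursor is the shortest that explains
      # the duplex
      ord <- order(vapply(windows, function(w) nchar(w$sequence),
                          numeric(1)),
                   vapply(windows, function(w) w$start, numeric(1)))
      best <- NULL
      for (w in windows[ord]) {
        v <- validate_hairpin(w, rl, params$max_unpaired, energy)
        if (!v$accepted) next
        # class-I requirement: star observed in the same library
        star_count <- lib$tags[v$star]
        if (is.na(star_count)) next
        rt <- randomization_test(w$sequence, params$randfold_n,
                                 seed = seed + w$start, params = energy)
        if (rt$p_value > params$randfold_cutoff) next
        best <- list(window = w, verdict = v, rt = rt)
        break
      }
      if (is.null(best)) next
      w <- best$window; v <- best$verdict
      met <- hairpin_metrics(w$sequence, mfe = v$structure$energy)
      rpms <- vapply(libraries, function(L) {
        cnt <- L$tags[cand]
        if (is.na(cnt) || L$total_redundant == 0) 0
        else rpm(as.integer(cnt), L$total_redundant)
      }, numeric(1))
      row <- data.frame(
        seqid = w$seqid, start = w$start, end = w$end,
        precursor_length = nchar(w$sequence),
        mfe = met$mfe, gc_percent = met$gc_percent, amfe = met$amfe,
        mfei = met$mfei, randfold_p = best$rt$p_value,
        mature = cand, mature_length = rl,
        star = v$star, arm = v$arm, class_one = TRUE,
        library = lib_name, stringsAsFactors = FALSE)
      for (nm in names(rpms)) row[[paste0("rpm_", nm)]] <- rpms[[nm]]
      key <- paste(w$seqid, w$start, w$end, cand)
      if (!key %in% names(structures)) {
        rows[[key]] <- row
        structures[[key]] <- v$structure
      } else {
        # same precursor recovered from another library: record it
        libs_seen <- union(strsplit(rows[[key]]$library, ",")[[1]],
                           lib_name)
        rows[[key]]$library <- paste(sort(libs_seen), collapse = ",")
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    # one id per mature; letter suffix per distinct precursor (a, b, ...)
    out <- out[order(out$mature, out$seqid, out$start), , drop = FALSE]
    mat_ids <- match(out$mature, unique(out$mature))
    out$id <- sprintf("novel_miR_%02d", mat_ids)
    multi <- ave(seq_len(nrow(out)), out$mature, FUN = seq_along)
    nprec <- ave(seq_len(nrow(out)), out$mature, FUN = length)
    out$id <- ifelse(nprec > 1, paste0(out$id, letters[multi]), out$id)
    out <- out[, c("id", setdiff(names(out), "id"))]
    rownames(out) <- NULL
  }
  attr(out, "structures") <- structures
  out
}
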