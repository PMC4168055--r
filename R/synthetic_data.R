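#' Simulation parameters
#'
#' Defaults emulate the statistical structure of a two-condition maize
#' small-RNA experiment: a 24-nt-dominated length distribution (peak 0.45
#' at 24 nt), five conserved miRNA families with planted Hs/CT fold
#' ratios spanning the observed range (including the strong 13.24x and
#' 9.32x up-regulations and a 0.24x down-regulation), ten novel class-I
#' hairpin loci emitting mature and star reads (star:mature ratio 0.05),
#' repeat- and CDS-derived siRNA with positional hotspots, methylation
#' elevated at hotspots and transcript coverage suppressed there.
#'
#' @param genome_length background genome length (nt).
#' @param reads_per_library redundant reads simulated per condition.
#' @param read_length sequencer read length (nt).
#' @param adapter 3' adapter appended to every insert.
#' @param n_rate fraction of reads receiving one N substitution.
#' @param length_probs named probability vector over insert lengths for
#'   background/siRNA reads.
#' @param known_ratios named vector: family -> planted Hs/CT RPM ratio.
#' @param known_prop per-family expected read proportion in CT.
#' @param n_novel number of planted class-I hairpin loci.
#' @param novel_prop per-hairpin expected mature read proportion.
#' @param star_ratio star:mature expected read ratio.
#' @param loop_length hairpin loop length (nt).
#' @param n_background_loci,background_locus_length discrete background
#'   read-producing loci in the genome.
#' @param repeat_classes repeat class labels.
#' @param elements_per_class,element_length repeat reference geometry.
#' @param repeat_tags_shared,repeat_tags_ct,repeat_tags_hs planted
#'   repeat-derived unique tags per class (shared / CT-only / Hs-only).
#' @param repeat_tag_reads expected redundant reads per repeat tag.
#' @param n_cds,cds_length CDS reference geometry.
#' @param n_silenced number of CDSs carrying a siRNA hotspot.
#' @param hotspot_start,hotspot_end hotspot interval on silenced CDSs
#'   (0-based half-open; default 3'-biased).
#' @param hotspot_tags_ct,hotspot_tags_hs planted unique hotspot tags per
#'   silenced CDS and condition (CT tags are a subset of Hs tags).
#' @param hotspot_tag_reads expected redundant reads per hotspot tag.
#' @param bystander_tags unique tags planted on each non-silenced CDS.
#' @param meth_baseline,meth_delta,meth_site_spacing,meth_sd methylation
#'   track shape: baseline level, CG/CHG elevation inside hotspots, mean
#'   site spacing (nt), site-level noise SD.
#' @param coverage_depth,coverage_suppression mean per-base transcript
#'   coverage (CT) and the Hs/CT depth ratio inside silenced hotspots.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L,
                       reads_per_library = 50000L,
                       read_length = 36L,
                       adapter = "CTGTAGGCACCATCAAT",
                       n_rate = 0.002,
                       length_probs = c("18" = 0.02, "19" = 0.02,
                                        "20" = 0.04, "21" = 0.12,
                                        "22" = 0.14, "23" = 0.13,
                                        "24" = 0.45, "25" = 0.03,
                                        "26" = 0.02, "27" = 0.02,
                                        "28" = 0.01),
                       known_ratios = c(miR156 = 1.39, miR160 = 0.24,
                                        miR319 = 1.67, miR398 = 13.24,
                                        miR408 = 9.32),
                       known_prop = 0.004,
                       n_novel = 10L,
                       novel_prop = 0.002,
                       star_ratio = 0.05,
                       loop_length = 10L,
                       n_background_loci = 150L,
                       background_locus_length = 300L,
                       repeat_classes = c("CACTA", "Copia", "Gypsy",
                                          "Knob", "Mutator",
                                          "PIF_Harbinger", "hAT", "rRNA"),
                       elements_per_class = 2L,
                       element_length = 1000L,
                       repeat_tags_shared = 30L,
                       repeat_tags_ct = 15L,
                       repeat_tags_hs = 25L,
                       repeat_tag_reads = 8,
                       n_cds = 6L,
                       cds_length = 600L,
                       n_silenced = 2L,
                       hotspot_start = 520L,
                       hotspot_end = 570L,
                       hotspot_tags_ct = 60L,
                       hotspot_tags_hs = 120L,
                       hotspot_tag_reads = 4,
                       bystander_tags = 10L,
                       meth_baseline = 0.2,
                       meth_delta = 0.5,
                       meth_site_spacing = 4L,
                       meth_sd = 0.05,
                       coverage_depth = 3,
                       coverage_suppression = 0.75) {
  p <- as.list(environment())
  stopifnot(abs(sum(p$length_probs) - 1) < 1e-9,
            p$star_ratio > 0, p$star_ratio < 1,
            p$hotspot_end <= p$cds_length,
            p$hotspot_tags_ct <= p$hotspot_tags_hs)
  structure(p, class = "sim_params")
}

.rand_seq <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.rand_tag_len <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

#' Build synthetic references with planted truth
#'
#' Generates the genome (background loci + embedded hairpin precursors),
#' the known-mature miRNA reference (two members per family, one
#' substitution apart), the repeat reference with class labels, and the
#' CDS reference, together with a `SimulationTruth` record of everything
#' planted. Hairpins are designed stems (mature arm + loop + exact
#' reverse-complement star arm) with the star defined by Dicer geometry
#' (partner span shifted by the 2-nt 3' overhang), so they validate by
#' construction under any reasonable nearest-neighbor model.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed (deterministic outputs given a seed).
#' @return list of class `sim_truth` with elements `genome` (named
#'   character), `known` (data.frame reference), `repeats`, `cds`
#'   (data.frames), and `truth` (planted loci, tags, hotspots, track
#'   parameters).
#' @export
build_references <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  p <- params
  # --- novel class-I hairpins -------------------------------------------
  mature_lens <- sample(c(24L, 21L, 22L), p$n_novel, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
  hairpins <- lapply(seq_len(p$n_novel), function(i) {
    Lm <- mature_lens[i]
    mature <- .rand_seq(Lm)
    loop <- .rand_seq(p$loop_length, gc = 0.3)
    list(mature = mature, loop = loop,
         precursor_core = paste0(mature, loop, revcomp(mature)))
  })
  # --- genome: background loci and hairpins on one chromosome -----------
  spacing <- 200L
  pieces <- character(0); cursor <- 0L
  bg_loci <- data.frame(start = integer(0), end = integer(0))
  hp_pos <- integer(p$n_novel)
  order_slots <- sample(rep(c("bg", "hp"),
                            c(p$n_background_loci, p$n_novel)))
  hp_i <- 0L
  for (slot in order_slots) {
    pieces <- c(pieces, .rand_seq(spacing)); cursor <- cursor + spacing
    if (slot == "bg") {
      bg_loci <- rbind(bg_loci, data.frame(
        start = cursor, end = cursor + p$background_locus_length))
      pieces <- c(pieces, .rand_seq(p$background_locus_length))
      cursor <- cursor + p$background_locus_length
    } else {
      hp_i <- hp_i + 1L
      hp_pos[hp_i] <- cursor
      core <- hairpins[[hp_i]]$precursor_core
      pieces <- c(pieces, core)
      cursor <- cursor + nchar(core)
    }
  }
  pieces <- c(pieces, .rand_seq(max(spacing,
                                    p$genome_length - cursor)))
  genome <- c(chr1 = paste(pieces, collapse = ""))
  # planted hairpin records (genome coordinates, 0-based)
  novel_empty <- data.frame(id = character(), mature = character(),
                            star = character(), start = integer(),
                            end = integer(), mature_length = integer(),
                            stringsAsFactors = FALSE)
  novel <- do.call(rbind, lapply(seq_len(p$n_novel), function(i) {
    h <- hairpins[[i]]
    Lm <- nchar(h$mature)
    g <- hp_pos[i]
    core_len <- nchar(h$precursor_core)
    # star: partner span of the mature shifted +2 (2-nt 3' overhang);
    # the last 2 star bases fall in the flank right of the stem
    star_start <- g + Lm + p$loop_length + 2L
    star <- substr(genome[["chr1"]], star_start + 1L, star_start + Lm)
    data.frame(id = sprintf("hairpin%02d", i), mature = h$mature,
               star = star, start = g, end = g + core_len,
               mature_length = Lm, stringsAsFactors = FALSE)
  }))
  if (is.null(novel)) novel <- novel_empty
  # --- known mature reference (two members per family) ------------------
  fams <- names(p$known_ratios)
  known <- do.call(rbind, lapply(fams, function(f) {
    a <- .rand_seq(21L)
    pos <- sample(21L, 1)
    base <- substr(a, pos, pos)
    b <- a
    substr(b, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    data.frame(full_name = paste0("zma-", f, c("a", "b")),
               family = f, sequence = c(a, b), stringsAsFactors = FALSE)
  }))
  # --- repeat reference -------------------------------------------------
  reps <- do.call(rbind, lapply(p$repeat_classes, function(cl) {
    data.frame(id = paste0(cl, "_", seq_len(p$elements_per_class)),
               class = cl,
               sequence = vapply(seq_len(p$elements_per_class),
                                 function(i) .rand_seq(p$element_length),
                                 character(1)),
               stringsAsFactors = FALSE)
  }))
  # --- CDS reference ----------------------------------------------------
  cds <- data.frame(id = sprintf("CDS%02d_T01", seq_len(p$n_cds)),
                    sequence = vapply(seq_len(p$n_cds), function(i)
                      .rand_seq(p$cds_length), character(1)),
                    stringsAsFactors = FALSE)
  silenced <- cds$id[seq_len(p$n_silenced)]
  # --- planted siRNA tags ----------------------------------------------
  draw_sub <- function(parent, len) {
    s <- sample(nchar(parent) - len + 1L, 1)
    substr(parent, s, s + len - 1L)
  }
  repeat_tags <- do.call(rbind, lapply(p$repeat_classes, function(cl) {
    el <- reps$sequence[reps$class == cl]
    n_tot <- p$repeat_tags_shared + p$repeat_tags_ct + p$repeat_tags_hs
    if (n_tot == 0L) return(NULL)
    lens <- .rand_tag_len(n_tot, p$length_probs)
    tag <- vapply(lens, function(l) draw_sub(sample(el, 1), l),
                  character(1))
    data.frame(tag = tag, class = cl,
               presence = rep(c("both", "ct", "hs"),
                              c(p$repeat_tags_shared, p$repeat_tags_ct,
                                p$repeat_tags_hs)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(repeat_tags))
    repeat_tags <- data.frame(tag = character(), class = character(),
                              presence = character(),
                              stringsAsFactors = FALSE)
  repeat_tags <- repeat_tags[!duplicated(repeat_tags$tag), ]
  cds_tags <- do.call(rbind, lapply(seq_len(p$n_cds), function(i) {
    id <- cds$id[i]; s <- cds$sequence[i]
    if (id %in% silenced) {
      lens <- .rand_tag_len(p$hotspot_tags_hs, p$length_probs)
      tag <- vapply(lens, function(l) {
        st <- sample(p$hotspot_start:(p$hotspot_end - l), 1)
        substr(s, st + 1L, st + l)
      }, character(1))
      presence <- rep(c("both", "hs"),
                      c(p$hotspot_tags_ct,
                        p$hotspot_tags_hs - p$hotspot_tags_ct))
    } else {
      lens <- .rand_tag_len(p$bystander_tags, p$length_probs)
      tag <- vapply(lens, function(l) draw_sub(s, l), character(1))
      presence <- rep("both", p$bystander_tags)
    }
    if (!length(tag)) return(NULL)
    data.frame(tag = tag, cds = id, presence = presence,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cds_tags))
    cds_tags <- data.frame(tag = character(), cds = character(),
                           presence = character(),
                           stringsAsFactors = FALSE)
  cds_tags <- cds_tags[!duplicated(cds_tags$tag), ]
  truth <- list(params = p, seed = seed,
                background_loci = bg_loci,
                novel = novel,
                known = known,
                known_ratios = p$known_ratios,
                repeat_tags = repeat_tags,
                cds_tags = cds_tags,
                silenced_cds = silenced,
                hotspot = list(start = p$hotspot_start,
                               end = p$hotspot_end))
  structure(list(genome = genome, known = known, repeats = reps,
                 cds = cds, truth = truth),
            class = "sim_truth")
}

# expected per-tag read proportions for one condition
.planted_proportions <- function(truth, condition) {
  p <- truth$params
  rows <- list()
  add <- function(tag, prop) {
    if (!length(tag)) return(invisible())
    rows[[length(rows) + 1L]] <<-
      data.frame(tag = tag, prop = prop, stringsAsFactors = FALSE)
  }
  # known families: reads split evenly over the two members
  for (f in names(p$known_ratios)) {
    mult <- if (condition == "hs") p$known_ratios[[f]] else 1
    seqs <- truth$known$sequence[truth$known$family == f]
    add(seqs, rep(p$known_prop * mult / length(seqs), length(seqs)))
  }
  # novel hairpins: mature + star at star_ratio (ratio 1 across conditions)
  add(truth$novel$mature, rep(p$novel_prop, nrow(truth$novel)))
  add(truth$novel$star, rep(p$novel_prop * p$star_ratio,
                            nrow(truth$novel)))
  # repeat- and CDS-derived siRNA tags
  rt <- truth$repeat_tags
  sel <- rt$presence == "both" | rt$presence == condition
  add(rt$tag[sel], rep(p$repeat_tag_reads / p$reads_per_library,
                       sum(sel)))
  ct <- truth$cds_tags
  sel <- ct$presence == "both" | ct$presence == condition
  add(ct$tag[sel], rep(p$hotspot_tag_reads / p$reads_per_library,
                       sum(sel)))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(tag = character(), prop = numeric(),
                     stringsAsFactors = FALSE)
  df[!duplicated(df$tag), ]
}

#' Simulate two-condition read libraries
#'
#' Per-locus read counts are drawn multinomially with the planted
#' condition ratios; the remaining mass is background reads drawn from
#' the genome's background loci with the configured length distribution.
#' Every read carries the 3' adapter (truncated at the read length,
#' padded with random bases when shorter) and receives one N
#' substitution at rate `n_rate`.
#'
#' @param sim a `sim_truth` from [build_references()].
#' @param seed RNG seed.
#' @return list with `ct` and `hs` (character vectors of raw reads) and
#'   `expected` (data.frame of per-tag expected proportions per
#'   condition).
#' @export
simulate_libraries <- function(sim, seed = 1L) {
  set.seed(seed + 1L)
  truth <- sim$truth; p <- truth$params
  genome <- sim$genome[["chr1"]]
  make_lib <- function(condition) {
    planted <- .planted_proportions(truth, condition)
    stopifnot(sum(planted$prop) < 0.9)
    n_planted <- as.integer(rmultinom(1, p$reads_per_library,
                                      c(planted$prop,
                                        1 - sum(planted$prop))))
    inserts <- rep(c(planted$tag, "BG"),
                   n_planted)
    n_bg <- sum(inserts == "BG")
    if (n_bg) {
      loci <- truth$background_loci[
        sample(nrow(truth$background_loci), n_bg, replace = TRUE), ]
      lens <- .rand_tag_len(n_bg, p$length_probs)
      starts <- loci$start +
        floor(runif(n_bg) * (p$background_locus_length - lens))
      inserts[inserts == "BG"] <-
        substring(genome, starts + 1L, starts + lens)
    }
    # adapter, fixed read length, N injection
    reads <- paste0(inserts, p$adapter)
    short <- nchar(reads) < p$read_length
    if (any(short))
      reads[short] <- vapply(which(short), function(i)
        paste0(reads[i], .rand_seq(p$read_length - nchar(reads[i]))),
        character(1))
    reads <- substr(reads, 1L, p$read_length)
    hit <- which(runif(length(reads)) < p$n_rate)
    for (i in hit) {
      pos <- sample(p$read_length, 1)
      substr(reads[i], pos, pos) <- "N"
    }
    sample(reads)
  }
  expected <- merge(
    setNames(.planted_proportions(truth, "ct"), c("tag", "prop_ct")),
    setNames(.planted_proportions(truth, "hs"), c("tag", "prop_hs")),
    by = "tag", all = TRUE)
  expected[is.na(expected)] <- 0
  list(ct = make_lib("ct"), hs = make_lib("hs"), expected = expected)
}

#' Simulate methylation and transcript-coverage tracks
#'
#' Tracks live on CDS coordinates. Methylation sites sit on a regular
#' grid (`meth_site_spacing`) with cycling contexts, so every context is
#' represented in any region wider than three grid steps; CG and CHG
#' levels are elevated by `meth_delta` inside silenced-CDS hotspots.
#' Transcript coverage is
#' Poisson around `coverage_depth`; the inoculated condition is
#' suppressed by `coverage_suppression` inside silenced hotspots.
#'
#' @param sim a `sim_truth` from [build_references()].
#' @param seed RNG seed.
#' @return list with `methylation` (data.frame seqid/position/context/
#'   level), `coverage_ct`, `coverage_hs` (data.frames
#'   seqid/position/depth), `total_ct`, `total_hs` (track depth sums).
#' @export
simulate_tracks <- function(sim, seed = 1L) {
  set.seed(seed + 2L)
  truth <- sim$truth; p <- truth$params
  meth <- list(); cov_ct <- list(); cov_hs <- list()
  for (i in seq_len(nrow(sim$cds))) {
    id <- sim$cds$id[i]; L <- nchar(sim$cds$sequence[i])
    silenced <- id %in% truth$silenced_cds
    # regular site grid with cycling contexts: every context is present
    # in any window wider than 3 x spacing, so regional context means
    # are always defined
    pos <- seq(0L, L - 1L, by = p$meth_site_spacing)
    ctx <- rep(c("CG", "CHG", "CHH"), length.out = length(pos))
    base <- rep(p$meth_baseline, length(pos))
    if (silenced) {
      inside <- pos >= truth$hotspot$start & pos < truth$hotspot$end
      base[inside & ctx %in% c("CG", "CHG")] <-
        p$meth_baseline + p$meth_delta
    }
    lev <- pmin(1, pmax(0, rnorm(length(pos), base, p$meth_sd)))
    meth[[id]] <- data.frame(seqid = id, position = pos, context = ctx,
                             level = lev, stringsAsFactors = FALSE)
    d_ct <- rpois(L, p$coverage_depth)
    lambda_hs <- rep(p$coverage_depth, L)
    if (silenced) {
      idx <- (truth$hotspot$start + 1L):truth$hotspot$end
      lambda_hs[idx] <- p$coverage_depth * p$coverage_suppression
    }
    d_hs <- rpois(L, lambda_hs)
    cov_ct[[id]] <- data.frame(seqid = id, position = 0:(L - 1L),
                               depth = d_ct, stringsAsFactors = FALSE)
    cov_hs[[id]] <- data.frame(seqid = id, position = 0:(L - 1L),
                               depth = d_hs, stringsAsFactors = FALSE)
  }
  methylation <- do.call(rbind, meth); rownames(methylation) <- NULL
  coverage_ct <- do.call(rbind, cov_ct); rownames(coverage_ct) <- NULL
  coverage_hs <- do.call(rbind, cov_hs); rownames(coverage_hs) <- NULL
  list(methylation = methylation, coverage_ct = coverage_ct,
       coverage_hs = coverage_hs,
       total_ct = sum(coverage_ct$depth),
       total_hs = sum(coverage_hs$depth))
}

#' Write a full synthetic dataset to disk
#'
#' Convenience wrapper: builds references, simulates libraries and
#' tracks, and writes genome/known/repeat/CDS FASTA, two FASTQ
#' libraries, and methylation/coverage TSVs into `outdir`.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param outdir output directory (created if missing).
#' @return invisibly, the `sim_truth` object with an added `files`
#'   element naming every written file.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L,
                             outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- build_references(params, seed)
  libs <- simulate_libraries(sim, seed)
  tracks <- simulate_tracks(sim, seed)
  f <- function(x) file.path(outdir, x)
  write_fasta(names(sim$genome), unname(sim$genome), f("genome.fa"))
  write_fasta(sim$known$full_name, sim$known$sequence, f("known_mature.fa"))
  write_fasta(paste0(sim$repeats$id, "#", sim$repeats$class),
              sim$repeats$sequence, f("repeats.fa"))
  write_fasta(sim$cds$id, sim$cds$sequence, f("cds.fa"))
  write_fastq_raw <- function(reads, path) {
    con <- file(path, "w"); on.exit(close(con))
    qual <- strrep("I", nchar(reads[1]))
    writeLines(rbind(paste0("@read", seq_along(reads)), reads,
                     "+", qual), con)
  }
  write_fastq_raw(libs$ct, f("ct.fastq"))
  write_fastq_raw(libs$hs, f("hs.fastq"))
  write.table(tracks$methylation, f("methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(tracks$coverage_ct, f("coverage_ct.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(tracks$coverage_hs, f("coverage_hs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  sim$files <- vapply(c("genome.fa", "known_mature.fa", "repeats.fa",
                        "cds.fa", "ct.fastq", "hs.fastq",
                        "methylation.tsv", "coverage_ct.tsv",
                        "coverage_hs.tsv"), f, character(1))
  invisible(sim)
}
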