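# pairing category of a miRNA base against a target base (both 5'->3'
# alphabets; the target base is the one physically opposite the miRNA base)
.pair_class <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "wc", ifelse(gu, "gu", "mm"))
}

#' Seed-weighted complementarity expectation score
#'
#' Optimal gapped alignment of a miRNA against a candidate target site
#' under the standard plant-target penalty scheme: mismatch 1.0, G:U
#' wobble 0.5, gap 2.0, all penalties doubled at miRNA positions 2-13
#' (1-based from the 5' end). The expectation is the total penalty; 0
#' means every position pairs Watson-Crick.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA alphabet), 18-26 nt.
#' @param site target site sequence, 5'->3', typically the miRNA length.
#' @param seed_from,seed_to doubled-penalty region (miRNA positions).
#' @param max_gaps total gap budget of the alignment (default 2; target
#'   alignments in this scheme are near-ungapped).
#' @return list with `expectation` and `alignment` (three strings: miRNA
#'   5'->3', pairing symbols `|` WC / `o` wobble / space otherwise, site
#'   3'->5').
#' @export
expectation_score <- function(mirna, site, seed_from = 2L, seed_to = 13L,
                              max_gaps = 2L) {
  .check_dna(c(mirna, site), "target scoring input")
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])       # antiparallel: site 3'->5'
  n <- length(m); q <- length(t)
  G <- max_gaps + 1L
  w <- ifelse(seq_len(n) >= seed_from & seq_len(n) <= seed_to, 2, 1)
  # D[i+1, j+1, g+1]: best cost aligning m[1..i] vs t[1..j] with g gaps
  D <- array(Inf, c(n + 1, q + 1, G))
  D[1, 1, ] <- 0
  for (g in seq_len(G) - 1L) {
    if (g == 0) next
    if (g <= n) D[g + 1, 1, g + 1] <- sum(2 * w[seq_len(g)])
    if (g <= q) D[1, g + 1, g + 1] <- 2 * g * w[1]
  }
  for (i in seq_len(n)) {
    cls <- .pair_class(m[i], t)
    sub <- ifelse(cls == "wc", 0, ifelse(cls == "gu", 0.5, 1)) * w[i]
    for (j in seq_len(q)) {
      for (g in seq_len(G) - 1L) {
        best <- D[i, j, g + 1] + sub[j]
        if (g > 0) {
          best <- min(best,
                      D[i, j + 1, g] + 2 * w[i],       # m[i] unpaired
                      D[i + 1, j, g] + 2 * w[i])       # t[j] bulged
        }
        D[i + 1, j + 1, g + 1] <- best
      }
    }
  }
  total <- min(D[n + 1, q + 1, ])
  # traceback from the smallest gap layer attaining the optimum
  g <- which(abs(D[n + 1, q + 1, ] - total) < 1e-9)[1] - 1L
  i <- n; j <- q
  am <- as <- sym <- character(0)
  pos <- integer(0)                       # miRNA position per column
  while (i > 0 || j > 0) {
    cur <- D[i + 1, j + 1, g + 1]
    if (i > 0 && j > 0) {
      cls <- .pair_class(m[i], t[j])
      sub <- c(wc = 0, gu = 0.5, mm = 1)[[cls]] * w[i]
      if (abs(cur - (D[i, j, g + 1] + sub)) < 1e-9) {
        am <- c(m[i], am); as <- c(t[j], as)
        sym <- c(c(wc = "|", gu = "o", mm = " ")[[cls]], sym)
        pos <- c(i, pos); i <- i - 1; j <- j - 1
        next
      }
    }
    if (g > 0 && i > 0 &&
        abs(cur - (D[i, j + 1, g] + 2 * w[i])) < 1e-9) {
      am <- c(m[i], am); as <- c("-", as); sym <- c(" ", sym)
      pos <- c(i, pos); i <- i - 1; g <- g - 1L
    } else {
      am <- c("-", am); as <- c(t[j], as); sym <- c(" ", sym)
      pos <- c(max(i, 1L), pos); j <- j - 1; g <- max(0L, g - 1L)
    }
  }
  list(expectation = total,
       alignment = list(mirna = paste(am, collapse = ""),
                        symbols = paste(sym, collapse = ""),
                        site = paste(as, collapse = ""),
                        mirna_position = pos))
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window of each transcript with [expectation_score()],
#' reports sites below the cutoff (strict `<`), merges overlapping sites
#' to the best-scoring one, and classifies inhibition: translational iff
#' at least one mismatch or gap falls at miRNA positions
#' `central_from`-`central_to` (default 9-11), cleavage otherwise.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum expectation (strict; default 3.0).
#' @param central_from,central_to central-mismatch region for
#'   translational inhibition.
#' @return data.frame with columns `mirna`, `transcript`, `start`, `end`
#'   (0-based half-open on the transcript), `expectation`, `inhibition`,
#'   `alignment_mirna`, `alignment_symbols`, `alignment_site`.
#' @export
scan_transcripts <- function(mirna, transcripts, cutoff = 3.0,
                             central_from = 9L, central_to = 11L) {
  stopifnot(!is.null(names(transcripts)))
  n <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  out <- list()
  for (tx in names(transcripts)) {
    s <- transcripts[[tx]]
    L <- nchar(s)
    if (L < n) next
    chars <- strsplit(s, "")[[1]]
    # vectorised ungapped screen: miRNA position i faces window base
    # (start + n - i), windows indexed by 0-based start
    starts <- 0:(L - n)
    pen <- numeric(length(starts))
    w <- ifelse(seq_len(n) >= 2 & seq_len(n) <= 13, 2, 1)
    for (i in seq_len(n)) {
      tb <- chars[starts + n - i + 1L]
      cls <- .pair_class(m[i], tb)
      pen <- pen + ifelse(cls == "wc", 0, ifelse(cls == "gu", 0.5, 1)) * w[i]
    }
    cand <- starts[pen < cutoff + 4]      # gapped rescue margin
    hits <- list()
    for (st in cand) {
      site <- substr(s, st + 1L, st + n)
      sc <- expectation_score(mirna, site)
      if (sc$expectation >= cutoff) next
      al <- sc$alignment
      bad <- al$mirna_position[strsplit(al$symbols, "")[[1]] == " "]
      inhibition <- if (any(bad >= central_from & bad <= central_to))
        "translational" else "cleavage"
      hits[[length(hits) + 1L]] <- data.frame(
        mirna = mirna, transcript = tx, start = st, end = st + n,
        expectation = sc$expectation, inhibition = inhibition,
        alignment_mirna = al$mirna, alignment_symbols = al$symbols,
        alignment_site = al$site, stringsAsFactors = FALSE)
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    # merge overlapping sites to the best-scoring one
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, h$start[-1] >= cummax(h$end)[-nrow(h)]))
    keep <- unlist(lapply(split(seq_len(nrow(h)), grp), function(idx) {
      idx[which.min(h$expectation[idx])]
    }))
    out[[tx]] <- h[sort(keep), , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), inhibition = character(),
                      alignment_mirna = character(),
                      alignment_symbols = character(),
                      alignment_site = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
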