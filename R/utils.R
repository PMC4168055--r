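#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# normalize a sequence vector: uppercase, RNA U -> DNA T
.normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# validate sequences are over {A,C,G,T}; returns invisibly or stops
.check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad))
    stop(sprintf("%s contains non-%s symbols (first offender: element %d)",
                 what, if (allow_n) "ACGTN" else "ACGT", bad[1]), call. = FALSE)
  invisible(x)
}

# Hamming distance between two equal-length strings
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 0-based half-open genomic interval as a plain list; internal plumbing
genomic_interval <- function(seqid, start, end, strand = "+") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  list(seqid = as.character(seqid), start = as.integer(start),
       end = as.integer(end), strand = strand)
}

# extract interval sequence from a named character vector genome;
# reverse strand intervals are stored on the forward strand and
# retrieval reverse-complements
interval_sequence <- function(genome, iv) {
  seqs <- genome[[iv$seqid]]
  if (is.null(seqs)) stop("unknown seqid: ", iv$seqid)
  s <- substr(seqs, iv$start + 1L, iv$end)
  if (iv$strand == "-") s <- revcomp(s)
  s
}
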