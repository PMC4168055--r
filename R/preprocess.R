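#' Preprocessing parameters
#'
#' Defaults follow the standard small-RNA library protocol for maize
#' two-condition experiments: the Illumina 3' adapter
#' `CTGTAGGCACCATCAAT`, an 18-28 nt size window, and filtering of reads
#' containing N, low-complexity reads and t/rRNA-like contaminants.
#'
#' @param adapter3 3' adapter sequence searched in each read.
#' @param min_len,max_len retained insert size window (nt).
#' @param min_adapter_prefix minimum length of an adapter prefix ending at
#'   the read 3' end that still counts as an adapter occurrence.
#' @param contaminant_refs data.frame with columns `id`, `sequence`
#'   (t/rRNA references); reads within 1 mismatch of any reference
#'   subsequence are discarded.
#' @param low_complexity_threshold discard when the most frequent
#'   mononucleotide makes up at least this fraction of the read.
#' @param discard_no_adapter discard reads without a detectable adapter
#'   (insert presumed longer than the read).
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter3 = "CTGTAGGCACCATCAAT",
                              min_len = 18L, max_len = 28L,
                              min_adapter_prefix = 8L,
                              contaminant_refs = NULL,
                              low_complexity_threshold = 0.8,
                              discard_no_adapter = TRUE) {
  stopifnot(min_len > 0, min_len <= max_len,
            min_adapter_prefix <= nchar(adapter3),
            low_complexity_threshold > 0, low_complexity_threshold <= 1)
  structure(list(adapter3 = .normalize_seq(adapter3),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_adapter_prefix = as.integer(min_adapter_prefix),
                 contaminant_refs = contaminant_refs,
                 low_complexity_threshold = low_complexity_threshold,
                 discard_no_adapter = discard_no_adapter),
            class = "preprocess_params")
}

#' Trim the 3' adapter from read sequences
#'
#' The read is truncated at the leftmost occurrence of the full adapter, or
#' of an adapter prefix of length >= `min_adapter_prefix` ending at the
#' read's 3' end. Reads without a detectable adapter are returned as `NA`
#' when `discard_no_adapter` is set, otherwise untrimmed.
#'
#' @param reads character vector of uppercase read sequences (N allowed).
#' @param params a [preprocess_params()].
#' @return character vector; `NA` marks removed reads.
#' @export
trim_adapter <- function(reads, params = preprocess_params()) {
  ad <- params$adapter3
  out <- character(length(reads))
  full <- regexpr(ad, reads, fixed = TRUE)
  for (i in seq_along(reads)) {
    r <- reads[i]
    if (full[i] > 0) {
      out[i] <- substr(r, 1L, full[i] - 1L)
      next
    }
    # adapter prefix ending exactly at the 3' end
    n <- nchar(r)
    found <- NA_integer_
    for (k in seq(min(n, nchar(ad) - 1L), params$min_adapter_prefix)) {
      if (k < 1) break
      if (substr(r, n - k + 1L, n) == substr(ad, 1L, k)) { found <- k; break }
    }
    if (!is.na(found)) {
      out[i] <- substr(r, 1L, n - found)
    } else {
      out[i] <- if (params$discard_no_adapter) NA_character_ else r
    }
  }
  out
}

# dominant mononucleotide fraction
.dominant_frac <- function(seqs) {
  n <- nchar(seqs)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE))
  }, numeric(length(seqs)))
  if (length(seqs) == 1L) counts <- matrix(counts, nrow = 1)
  apply(counts, 1, max) / pmax(n, 1L)
}

#' Filter a trimmed read
#'
#' Applies, in order: N content, size window, low complexity (dominant
#' mononucleotide fraction), and contaminant match (within 1 mismatch of a
#' subsequence of any contaminant reference).
#'
#' @param seqs character vector of adapter-trimmed sequences.
#' @param params a [preprocess_params()].
#' @return character vector of reasons: `"keep"`, `"N"`, `"size"`,
#'   `"low_complexity"` or `"contaminant"`.
#' @export
filter_read <- function(seqs, params = preprocess_params()) {
  out <- rep("keep", length(seqs))
  out[grepl("N", seqs, fixed = TRUE)] <- "N"
  len <- nchar(seqs)
  out[out == "keep" & (len < params$min_len | len > params$max_len)] <- "size"
  idx <- which(out == "keep")
  if (length(idx)) {
    lc <- .dominant_frac(seqs[idx]) >= params$low_complexity_threshold
    out[idx[lc]] <- "low_complexity"
  }
  refs <- params$contaminant_refs
  if (!is.null(refs) && nrow(refs)) {
    idx <- which(out == "keep")
    if (length(idx)) {
      hits <- scan_tags(seqs[idx], refs$sequence, max_mismatch = 1L,
                        both_strands = FALSE, best_only = TRUE)
      out[idx[unique(hits$tag)]] <- "contaminant"
    }
  }
  out
}

#' Build a filtered non-redundant library from raw reads
#'
#' Runs adapter trimming and filtering, collapses retained reads to a
#' non-redundant tag library, and returns exact bookkeeping: every raw read
#' lands in exactly one summary category.
#'
#' @param reads character vector of raw read sequences.
#' @param params a [preprocess_params()].
#' @param name library name.
#' @return list with elements `library` ([srna_library()]) and `summary`
#'   (named integer vector of category counts).
#' @export
build_library <- function(reads, params = preprocess_params(),
                          name = "library") {
  reads <- .normalize_seq(reads)
  trimmed <- trim_adapter(reads, params)
  no_adapter <- is.na(trimmed)
  reasons <- rep("discarded_no_adapter", length(reads))
  keepmask <- !no_adapter
  if (any(keepmask)) {
    verdict <- filter_read(trimmed[keepmask], params)
    reasons[keepmask] <- c(keep = "retained", N = "discarded_N",
                           size = "discarded_size",
                           low_complexity = "discarded_low_complexity",
                           contaminant = "discarded_contaminant")[verdict]
  }
  retained <- trimmed[reasons == "retained"]
  lib <- srna_library(retained, name = name)
  if (lib$total_nonredundant == 0L)
    warning("all reads discarded; library '", name, "' is empty")
  summary <- c(raw_reads = length(reads),
               discarded_no_adapter = sum(reasons == "discarded_no_adapter"),
               discarded_N = sum(reasons == "discarded_N"),
               discarded_size = sum(reasons == "discarded_size"),
               discarded_contaminant = sum(reasons == "discarded_contaminant"),
               discarded_low_complexity =
                 sum(reasons == "discarded_low_complexity"),
               retained_redundant = lib$total_redundant,
               retained_nonredundant = lib$total_nonredundant)
  list(library = lib, summary = summary)
}

#' Read-length distribution of a library
#'
#' @param library an [srna_library()].
#' @return data.frame with columns `length`, `redundant_fraction`,
#'   `nonredundant_fraction`; each fraction column sums to 1.
#' @export
size_distribution <- function(library) {
  stopifnot(inherits(library, "srna_library"))
  if (!length(library$tags))
    return(data.frame(length = integer(), redundant_fraction = numeric(),
                      nonredundant_fraction = numeric()))
  len <- nchar(names(library$tags))
  red <- tapply(as.numeric(library$tags), len, sum)
  nred <- tapply(rep(1, length(len)), len, sum)
  data.frame(length = as.integer(names(red)),
             redundant_fraction = as.numeric(red) / sum(red),
             nonredundant_fraction = as.numeric(nred) / sum(nred),
             row.names = NULL)
}
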