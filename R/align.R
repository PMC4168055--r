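#' Ungapped mismatch scan of tags against reference sequences
#'
#' Shared alignment primitive (Bowtie-like, substitution-only): every
#' placement of each tag inside each reference is scored by Hamming
#' distance; placements within `max_mismatch` are reported. With
#' `best_only` each tag keeps only its minimal-mismatch placements
#' (best-hit policy). Minus-strand hits report the position where the
#' reverse complement of the tag matches the reference.
#'
#' @param tags character vector of tag sequences.
#' @param refs character vector of reference sequences.
#' @param max_mismatch maximum Hamming distance.
#' @param both_strands also scan the reverse complement of each tag.
#' @param best_only keep only minimal-mismatch hits per tag.
#' @return data.frame with columns `tag` (index into `tags`), `ref`
#'   (index into `refs`), `pos` (0-based start on the reference),
#'   `strand`, `mismatches`.
#' @export
scan_tags <- function(tags, refs, max_mismatch = 0L, both_strands = TRUE,
                      best_only = TRUE) {
  if (!length(tags) || !length(refs))
    return(data.frame(tag = integer(), ref = integer(), pos = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  .check_dna(tags, "scan tags")
  .scan_tags_cpp(as.character(tags), as.character(refs),
                 as.integer(max_mismatch), both_strands, best_only)
}
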