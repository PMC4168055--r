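#' Read a mature-miRNA reference FASTA
#'
#' miRBase-style mature FASTA with ids like `zma-miR156a-5p`. Sequences
#' are normalised to uppercase DNA.
#'
#' @param path FASTA path.
#' @return data.frame with columns `full_name`, `family`, `sequence`.
#' @export
read_mature_mirna <- function(path) {
  fa <- read_fasta(path)
  data.frame(full_name = fa$id, family = collapse_family(fa$id),
             sequence = fa$sequence, stringsAsFactors = FALSE)
}

#' Collapse a mature-miRNA name to its family
#'
#' Strips the species prefix (three-letter code + dash), the arm suffix
#' (-5p/-3p) and trailing letter/number variant designators, normalising
#' "miR" capitalisation: `zma-miR156a-5p` -> `miR156`.
#'
#' @param full_name character vector of mature names.
#' @return character vector of family names.
#' @export
collapse_family <- function(full_name) {
  x <- sub("^[A-Za-z]{3,4}-", "", full_name)       # species prefix
  x <- sub("-(5p|3p)$", "", x)                     # arm suffix
  x <- sub("^(mir|miR|MIR)", "miR", x, ignore.case = TRUE)
  # trailing variant letters, then optional sub-variant numbers: miR156a-1
  x <- sub("-[0-9]+$", "", x)
  x <- sub("^(miR[0-9]+)[a-z]*$", "\\1", x)
  x
}

#' Match library tags against known mature miRNAs
#'
#' A tag matches a reference if the Hamming distance at equal length is at
#' most `max_mismatch`, or if the shorter sequence aligns within the
#' longer with at most `max_mismatch` mismatches and the length difference
#' is at most `end_overhang` nucleotides (isomiR end tolerance). Each tag
#' is assigned to its best (fewest-mismatch) family; a tag tied between
#' different families is reported once per tied family and flagged
#' ambiguous.
#'
#' @param library an [srna_library()].
#' @param refs mature reference data.frame from [read_mature_mirna()].
#' @param max_mismatch maximum mismatches (default 1).
#' @param end_overhang maximum length difference (default 2; 0 restricts
#'   to equal-length matching).
#' @return data.frame with columns `tag`, `count`, `family`, `ref`,
#'   `mismatches`, `ambiguous`.
#' @export
match_known <- function(library, refs, max_mismatch = 1L,
                        end_overhang = 2L) {
  stopifnot(inherits(library, "srna_library"), nrow(refs) > 0)
  tags <- names(library$tags)
  if (!length(tags))
    return(data.frame(tag = character(), count = integer(),
                      family = character(), ref = character(),
                      mismatches = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  tl <- nchar(tags); rl <- nchar(refs$sequence)
  # tag within ref (tag shorter or equal)
  h1 <- scan_tags(tags, refs$sequence, max_mismatch = max_mismatch,
                  both_strands = FALSE, best_only = FALSE)
  # ref within tag (tag longer)
  h2 <- scan_tags(refs$sequence, tags, max_mismatch = max_mismatch,
                  both_strands = FALSE, best_only = FALSE)
  hits <- rbind(
    data.frame(tag = h1$tag, ref = h1$ref, mismatches = h1$mismatches),
    data.frame(tag = h2$ref, ref = h2$tag, mismatches = h2$mismatches))
  if (!nrow(hits))
    return(data.frame(tag = character(), count = integer(),
                      family = character(), ref = character(),
                      mismatches = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  ldiff <- abs(tl[hits$tag] - rl[hits$ref])
  hits <- hits[ldiff <= end_overhang, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(tag = character(), count = integer(),
                      family = character(), ref = character(),
                      mismatches = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  # best (fewest-mismatch) assignment per tag
  hits <- hits[order(hits$tag, hits$mismatches), , drop = FALSE]
  best_mm <- tapply(hits$mismatches, hits$tag, min)
  hits <- hits[hits$mismatches == best_mm[as.character(hits$tag)], ,
               drop = FALSE]
  hits$family <- refs$family[hits$ref]
  # one row per (tag, family); pick the first ref name as representative
  key <- paste(hits$tag, hits$family)
  hits <- hits[!duplicated(key), , drop = FALSE]
  nfam <- table(hits$tag)
  hits$ambiguous <- as.integer(nfam[as.character(hits$tag)]) > 1L
  data.frame(tag = tags[hits$tag],
             count = as.integer(library$tags[hits$tag]),
             family = hits$family,
             ref = refs$full_name[hits$ref],
             mismatches = hits$mismatches,
             ambiguous = hits$ambiguous,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-family abundance profiles across two libraries
#'
#' Family abundance is the sum of the redundant counts of the member tags
#' matched to that family, each tag counted once per family. Families
#' absent from one library carry count 0 there.
#'
#' @param ct_library,hs_library control and inoculated
#'   [srna_library()] objects.
#' @param refs mature reference data.frame from [read_mature_mirna()].
#' @param max_mismatch,end_overhang matching parameters, see
#'   [match_known()].
#' @return data.frame with columns `unit` (family), `count_ct`,
#'   `count_hs`, `rpm_ct`, `rpm_hs`.
#' @export
profile_families <- function(ct_library, hs_library, refs,
                             max_mismatch = 1L, end_overhang = 2L) {
  tally <- function(lib) {
    m <- match_known(lib, refs, max_mismatch, end_overhang)
    if (!nrow(m)) return(integer(0))
    tapply(m$count, m$family, sum)
  }
  ct <- tally(ct_library); hs <- tally(hs_library)
  fams <- sort(unique(c(names(ct), names(hs))))
  if (!length(fams))
    return(data.frame(unit = character(), count_ct = integer(),
                      count_hs = integer(), rpm_ct = numeric(),
                      rpm_hs = numeric(), stringsAsFactors = FALSE))
  count_ct <- as.integer(ifelse(fams %in% names(ct), ct[fams], 0L))
  count_hs <- as.integer(ifelse(fams %in% names(hs), hs[fams], 0L))
  data.frame(unit = fams, count_ct = count_ct, count_hs = count_hs,
             rpm_ct = if (ct_library$total_redundant > 0)
               rpm(count_ct, ct_library$total_redundant) else 0,
             rpm_hs = if (hs_library$total_redundant > 0)
               rpm(count_hs, hs_library$total_redundant) else 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
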