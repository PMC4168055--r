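#' Read a FASTA file into (id, sequence) records
#'
#' Ingestion is tolerant of mixed case, RNA alphabet (U is normalised to T)
#' and arbitrary line wrapping. Record ids are the first whitespace-delimited
#' token of the header.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id` and `sequence` (uppercase DNA).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- .normalize_seq(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty))
    stop("FASTA record with empty sequence: ", ids[empty[1]])
  .check_dna(seqs, what = paste0("FASTA file ", path), allow_n = TRUE)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids character vector of record ids.
#' @param seqs character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(ids, seqs, path, width = 70L) {
  stopifnot(length(ids) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line records. Sequences are uppercased with U normalised to T.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    warning("empty FASTQ file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0)
    stop(sprintf("truncated FASTQ record at record %d in %s",
                 length(lines) %/% 4 + 1L, path))
  m <- matrix(lines, nrow = 4)
  if (any(!startsWith(m[1, ], "@")))
    stop("malformed FASTQ header at record ",
         which(!startsWith(m[1, ]))[1])
  ids <- sub("\\s.*$", "", sub("^@", "", m[1, ]))
  seqs <- .normalize_seq(m[2, ])
  qual <- m[4, ]
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop("quality length differs from sequence length for read: ", ids[bad[1]])
  data.frame(id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Construct a non-redundant small-RNA library
#'
#' A library is a named tag -> count map for one condition, with redundant
#' (sum of counts) and non-redundant (number of distinct tags) totals that
#' are always recomputed from the tags.
#'
#' @param tags named integer vector (names are tag sequences) or a character
#'   vector of (redundant) sequences to be tabulated.
#' @param name library name (condition label).
#' @return object of class `srna_library` with elements `name`, `tags`,
#'   `total_redundant`, `total_nonredundant`.
#' @export
srna_library <- function(tags = integer(), name = "library") {
  if (is.character(tags)) {
    tab <- table(tags)
    tags <- setNames(as.integer(tab), names(tab))
  }
  if (length(tags)) {
    stopifnot(!is.null(names(tags)), all(tags >= 1), !anyDuplicated(names(tags)))
    .check_dna(names(tags), "library tag")
    storage.mode(tags) <- "integer"
    tags <- tags[order(-tags, names(tags))]  # descending count, then sequence
  }
  structure(list(name = name, tags = tags,
                 total_redundant = sum(tags),
                 total_nonredundant = length(tags)),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s': %d non-redundant tags, %d redundant reads\n",
              x$name, x$total_nonredundant, x$total_redundant))
  if (length(x$tags)) {
    show <- head(x$tags, 5)
    cat(paste(sprintf("  %s  %d", names(show), show), collapse = "\n"), "\n")
    if (length(x$tags) > 5) cat(sprintf("  ... %d more\n", length(x$tags) - 5))
  }
  invisible(x)
}

#' Write / read a tag count table
#'
#' TSV with a header and rows `sequence<TAB>count`, ordered by descending
#' count then lexicographic sequence, so that write/read round-trips to an
#' identical library.
#'
#' @param library an [srna_library()].
#' @param path output (input) path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns an `srna_library`.
#' @export
write_count_table <- function(library, path) {
  stopifnot(inherits(library, "srna_library"))
  df <- data.frame(sequence = names(library$tags),
                   count = as.integer(library$tags))
  if (nrow(df)) df <- df[order(-df$count, df$sequence), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param name library name given to the result.
#' @export
read_count_table <- function(path, name = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(df)))
    stop("count table must have columns 'sequence' and 'count'")
  if (anyDuplicated(df$sequence))
    stop("duplicate sequence in count table: ",
         df$sequence[duplicated(df$sequence)][1])
  if (nrow(df) && any(df$count < 1))
    stop("non-positive count in count table")
  srna_library(setNames(as.integer(df$count), df$sequence), name = name)
}

#' Read a per-cytosine methylation track
#'
#' bedGraph-like TSV with columns seqid, position (0-based), context
#' (CG/CHG/CHH) and level in \[0, 1\].
#'
#' @param path input path.
#' @return data.frame with columns `seqid`, `position`, `context`, `level`.
#' @export
read_methylation_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n <- length(readLines(path, warn = FALSE))
  if (n == 0) {
    warning("empty methylation track: ", path)
    return(data.frame(seqid = character(), position = integer(),
                      context = character(), level = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("seqid", "position", "context", "level"))
  bad <- which(!(df$context %in% c("CG", "CHG", "CHH")))
  if (length(bad))
    stop(sprintf("unknown methylation context '%s' at line %d",
                 df$context[bad[1]], bad[1]))
  bad <- which(df$level < 0 | df$level > 1 | is.na(df$level))
  if (length(bad))
    stop(sprintf("methylation level outside [0,1] at line %d", bad[1]))
  df$position <- as.integer(df$position)
  df
}

#' Read a per-base coverage track
#'
#' TSV with columns seqid, position (0-based) and depth.
#'
#' @param path input path.
#' @return data.frame with columns `seqid`, `position`, `depth`.
#' @export
read_coverage_track <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("seqid", "position", "depth"))
  if (nrow(df) && any(df$depth < 0)) stop("negative coverage depth")
  df$position <- as.integer(df$position)
  df
}

#' Write hotspot calls to a BED file
#'
#' BED stays 0-based half-open; the score column carries the hotspot
#' density.
#'
#' @param hotspots list of `hotspot_call` objects (see [hotspot()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(hotspots, path) {
  rows <- vapply(hotspots, function(h)
    sprintf("%s\t%d\t%d\t%s\t%.3f\t.", h$id, h$start, h$end,
            paste0("hotspot_", h$end_bias), h$density), character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write novel miRNA candidates to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' closed GFF3 convention. Each precursor becomes a
#' `miRNA_primary_transcript` feature with the mature sequence in its
#' attributes.
#'
#' @param novel candidate data.frame from [discover_novel()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(novel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(novel))) {
    writeLines(sprintf(
      "%s\tsrnapipe\tmiRNA_primary_transcript\t%d\t%d\t.\t+\t.\tID=%s;mature=%s;star=%s",
      novel$seqid[i], novel$start[i] + 1L, novel$end[i], novel$id[i],
      novel$mature[i], novel$star[i]), con)
  }
  invisible(path)
}

#' Write a structure in Vienna two-line layout
#'
#' Sequence line followed by the dot-bracket line with the energy in
#' parentheses.
#'
#' @param structure an `rna_structure` from [fold_mfe()].
#' @param path output path (or `""` for stdout).
#' @return invisibly, `path`.
#' @export
write_vienna <- function(structure, path = "") {
  lines <- c(structure$sequence,
             sprintf("%s (%.2f)", structure$dotbracket, structure$energy))
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(path)
}
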