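#' Reference catalogues for the maize inoculation study system
#'
#' Two small plain-text catalogues ship with the package and serve as
#' fixed inputs for downstream arithmetic and summary statistics:
#'
#' * `conserved_family_catalog()` - the differential-abundance table of
#'   the 25 conserved miRNA families detected in mock (CT) versus
#'   H. seropedicae-inoculated (Hs) maize libraries: RPM per condition
#'   ("-" = family absent), log2(Hs/CT) and Bonferroni-adjusted Fisher
#'   p-value.
#' * `novel_candidate_catalog()` - the 18 class-I novel miRNA precursors
#'   (15 distinct mature sequences) with hairpin length, MFE, MFEI,
#'   randomization-test p-value, mature sequence/length and per-library
#'   RPM.
#'
#' Absent values ("-") are returned as `NA`.
#'
#' @return data.frame (see above).
#' @export
conserved_family_catalog <- function() {
  path <- system.file("extdata", "conserved_family_catalog.tsv",
                      package = "srnapipe")
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
  df
}

#' @rdname conserved_family_catalog
#' @export
novel_candidate_catalog <- function() {
  path <- system.file("extdata", "novel_candidate_catalog.tsv",
                      package = "srnapipe")
  read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
}
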