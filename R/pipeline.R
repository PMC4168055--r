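#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates preprocess -> known-miRNA profiling -> novel discovery ->
#' differential abundance -> target prediction -> siRNA classification ->
#' CDS profiling/hotspots -> methylation/coverage integration. The
#' configuration is a nested list (or path to a YAML file with the same
#' structure):
#'
#' * `libraries$ct`, `libraries$hs`: FASTQ paths (required)
#' * `genome`, `known_mature`, `repeats`, `cds`: FASTA paths (required)
#' * `methylation`, `coverage_ct`, `coverage_hs`: track TSVs (optional)
#' * `preprocess`: arguments for [preprocess_params()]
#' * `novel`: arguments for [novel_params()]
#' * `alpha` (default 0.05), `seed` (default 1), `outdir` (optional; when
#'   set, every stage's output is persisted there together with a run
#'   log of all parameter values)
#'
#' @param config nested list or YAML path.
#' @return a `pipeline_result` list with elements `summary`, `libraries`,
#'   `family_diff`, `novel`, `targets`, `repeat_classes`, `cds_profiles`,
#'   `hotspots`, `integration`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("libraries", "genome", "known_mature", "repeats", "cds")
  missing <- setdiff(required, names(config))
  if (!("libraries" %in% missing)) {
    if (is.null(config$libraries$ct)) missing <- c(missing, "libraries$ct")
    if (is.null(config$libraries$hs)) missing <- c(missing, "libraries$hs")
  }
  if (length(missing))
    stop("pipeline config is missing required field(s): ",
         paste(missing, collapse = ", "))
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L
  pp <- do.call(preprocess_params, config$preprocess %||% list())
  np <- do.call(novel_params, config$novel %||% list())
  outdir <- config$outdir
  persist <- !is.null(outdir)
  if (persist) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # --- preprocess -------------------------------------------------------
  libs <- list()
  summaries <- list()
  for (nm in c("ct", "hs")) {
    reads <- read_fastq(config$libraries[[nm]])$sequence
    built <- build_library(reads, pp, name = nm)
    libs[[nm]] <- built$library
    summaries[[nm]] <- built$summary
    if (persist)
      write_count_table(built$library,
                        file.path(outdir, paste0("library_", nm, ".tsv")))
  }
  genome_df <- read_fasta(config$genome)
  genome <- setNames(genome_df$sequence, genome_df$id)
  known <- read_mature_mirna(config$known_mature)
  reps <- read_repeat_fasta(config$repeats)
  cds_df <- read_fasta(config$cds)

  # --- known miRNA profiling + differential abundance -------------------
  fam_profiles <- profile_families(libs$ct, libs$hs, known)
  fam_diff <- differential_table(fam_profiles,
                                 libs$ct$total_redundant,
                                 libs$hs$total_redundant, alpha)

  # --- novel class-I discovery ------------------------------------------
  novel <- discover_novel(libs, genome, known, np, seed = seed)

  # --- target prediction for novel matures ------------------------------
  transcripts <- setNames(cds_df$sequence, cds_df$id)
  targets <- if (nrow(novel)) {
    res <- lapply(unique(novel$mature), scan_transcripts,
                  transcripts = transcripts)
    do.call(rbind, res)
  } else data.frame()

  # --- siRNA pool: everything not assigned to known or novel miRNA ------
  mirna_tags <- unique(c(
    match_known(libs$ct, known)$tag, match_known(libs$hs, known)$tag,
    if (nrow(novel)) c(novel$mature, novel$star)))
  sirna <- lapply(libs, function(lib) {
    keep <- setdiff(names(lib$tags), mirna_tags)
    srna_library(lib$tags[keep], name = paste0(lib$name, "_sirna"))
  })
  hits_ct <- align_tags(names(sirna$ct$tags), reps, max_mismatch = 3L)
  hits_hs <- align_tags(names(sirna$hs$tags), reps, max_mismatch = 3L)
  repeat_classes <- classify_repeats(hits_ct, hits_hs)
  cds_profiles <- profile_cds(sirna, cds_df)

  # --- hotspots + integration -------------------------------------------
  selected <- Filter(function(pr) any(pr$selected), cds_profiles)
  hotspots <- lapply(selected, hotspot)
  integration <- NULL
  if (!is.null(config$methylation) && !is.null(config$coverage_ct) &&
      !is.null(config$coverage_hs) && length(hotspots)) {
    meth <- read_methylation_track(config$methylation)
    cov_ct <- read_coverage_track(config$coverage_ct)
    cov_hs <- read_coverage_track(config$coverage_hs)
    integration <- lapply(hotspots, function(h) {
      colocalize(h, meth, cov_ct, cov_hs,
                 total_ct = sum(cov_ct$depth),
                 total_hs = sum(cov_hs$depth),
                 cds_length = nchar(transcripts[[h$id]]))
    })
  }

  n_novel <- function(lib) {
    if (!nrow(novel)) return(0L)
    hit <- vapply(strsplit(novel$library, ","), function(x) lib %in% x,
                  logical(1))
    length(unique(novel$mature[hit]))
  }
  summary <- data.frame(
    description = c("Filtered reads", "miRNA", "Conserved miRNA",
                    "Novel miRNA", "siRNA candidate"),
    ct = c(libs$ct$total_redundant,
           sum(fam_profiles$count_ct) + n_novel("ct"),
           sum(fam_profiles$count_ct), n_novel("ct"),
           sirna$ct$total_redundant),
    hs = c(libs$hs$total_redundant,
           sum(fam_profiles$count_hs) + n_novel("hs"),
           sum(fam_profiles$count_hs), n_novel("hs"),
           sirna$hs$total_redundant),
    stringsAsFactors = FALSE)

  result <- structure(
    list(summary = summary, libraries = libs,
         preprocess_summaries = summaries,
         family_diff = fam_diff, novel = novel, targets = targets,
         repeat_classes = repeat_classes, cds_profiles = cds_profiles,
         hotspots = hotspots, integration = integration,
         config = list(alpha = alpha, seed = seed, preprocess = unclass(pp),
                       novel = unclass(np))),
    class = "pipeline_result")
  if (persist) {
    render_report(result, outdir)
    log_path <- file.path(outdir, "run_log.txt")
    writeLines(c(sprintf("seed: %s", seed), sprintf("alpha: %s", alpha),
                 utils::capture.output(utils::str(result$config))),
               log_path)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the pipeline report tables
#'
#' Emits the result bundle as TSV tables: classification summary
#' (filtered reads / miRNA / conserved / novel / siRNA per library),
#' family differential table (family, RPM per condition with "-" for
#' absent, log2 ratio, p-value), novel-candidate table (precursor
#' metrics and per-library RPM), repeat-class tallies and per-CDS
#' profiles.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param outdir directory for the TSV files (`NULL` returns the tables
#'   without writing).
#' @return named list of data.frames, invisibly when writing.
#' @export
render_report <- function(result, outdir = NULL) {
  fd <- result$family_diff
  fam_tab <- data.frame(
    miRNA = fd$unit,
    CT = ifelse(fd$count_ct == 0, "-", sprintf("%.2f", fd$rpm_ct)),
    Hs = ifelse(fd$count_hs == 0, "-", sprintf("%.2f", fd$rpm_hs)),
    log2_Hs_CT = ifelse(is.na(fd$log2fc), "-", sprintf("%.2f", fd$log2fc)),
    p_value = sprintf("%.6f", fd$p_adj),
    status = fd$status, stringsAsFactors = FALSE)
  nv <- result$novel
  novel_tab <- if (nrow(nv))
    data.frame(id = nv$id, precursor_length = nv$precursor_length,
               MFE = round(nv$mfe, 1), MFEI = round(nv$mfei, 2),
               randfold_p = signif(nv$randfold_p, 6),
               sequence = nv$mature, length = nv$mature_length,
               rpm_CT = round(nv$rpm_ct, 2), rpm_Hs = round(nv$rpm_hs, 2),
               stringsAsFactors = FALSE)
  else data.frame()
  cds_tab <- do.call(rbind, lapply(result$cds_profiles, function(pr)
    data.frame(cds = pr$id, unique_ct = pr$unique[["ct"]],
               unique_hs = pr$unique[["hs"]],
               rpm_ct = round(pr$rpm[["ct"]], 2),
               rpm_hs = round(pr$rpm[["hs"]], 2),
               selected_ct = pr$selected[["ct"]],
               selected_hs = pr$selected[["hs"]],
               high_density = any(pr$high_density),
               stringsAsFactors = FALSE)))
  rownames(cds_tab) <- NULL
  tables <- list(summary = result$summary,
                 family_differential = fam_tab,
                 novel_candidates = novel_tab,
                 repeat_classes = result$repeat_classes$class_counts,
                 repeat_shared = result$repeat_classes$shared,
                 cds_profiles = cds_tab)
  if (is.null(outdir)) return(tables)
  for (nm in names(tables))
    write.table(tables[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tables)
}
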