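#' Read a repeat reference FASTA with class labels
#'
#' Supports the Repbase header dialect `id#Class`; a missing `#` yields
#' class `"Unknown"`.
#'
#' @param path FASTA path.
#' @return data.frame with columns `id`, `class`, `sequence`.
#' @export
read_repeat_fasta <- function(path) {
  fa <- read_fasta(path)
  has <- grepl("#", fa$id, fixed = TRUE)
  data.frame(id = sub("#.*$", "", fa$id),
             class = ifelse(has, sub("^.*#", "", fa$id), "Unknown"),
             sequence = fa$sequence, stringsAsFactors = FALSE)
}

#' Align siRNA tags against references (best-hit policy)
#'
#' Ungapped substitution-only alignment of each tag against both strands
#' of every reference, keeping only hits at the minimal mismatch count
#' for that tag (at most `max_mismatch`).
#'
#' @param tags character vector of tag sequences.
#' @param refs data.frame with columns `id`, `sequence` and optionally
#'   `class`.
#' @param max_mismatch maximum mismatches (default 3).
#' @return data.frame with columns `tag`, `ref_id`, `class`, `pos`,
#'   `strand`, `mismatches`.
#' @export
align_tags <- function(tags, refs, max_mismatch = 3L) {
  hits <- scan_tags(tags, refs$sequence, max_mismatch = max_mismatch,
                    both_strands = TRUE, best_only = TRUE)
  cls <- if ("class" %in% names(refs)) refs$class else
    rep("Unknown", nrow(refs))
  data.frame(tag = tags[hits$tag],
             ref_id = refs$id[hits$ref],
             class = cls[hits$ref],
             pos = hits$pos, strand = hits$strand,
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify repeat-derived siRNA per library
#'
#' Each tag contributes once, to the class of its best hit; tags whose
#' best hits tie between classes are counted once under the
#' lexicographically smallest class (deterministic primary) and flagged
#' ambiguous. Shared/exclusive sets are computed over classified tags
#' across the two libraries, and a per-class length histogram is built
#' from unique tags.
#'
#' @param hits_ct,hits_hs [align_tags()] results for the control and
#'   inoculated libraries.
#' @return list with `class_counts` (data.frame: class, unique tags and
#'   ambiguous-tie count per library), `assignments` (per-library named
#'   class vectors), `shared` (data.frame per class: shared,
#'   exclusive_ct, exclusive_hs), and `length_dist` (data.frame: class,
#'   length, count per library).
#' @export
classify_repeats <- function(hits_ct, hits_hs) {
  assign_primary <- function(hits) {
    if (!nrow(hits)) return(list(class = character(0), amb = logical(0)))
    cl <- tapply(hits$class, hits$tag, function(x) sort(unique(x)))
    primary <- vapply(cl, `[`, character(1), 1)
    amb <- vapply(cl, length, integer(1)) > 1L
    list(class = primary, amb = amb)
  }
  a_ct <- assign_primary(hits_ct); a_hs <- assign_primary(hits_hs)
  classes <- sort(unique(c(a_ct$class, a_hs$class)))
  class_counts <- data.frame(
    class = classes,
    unique_ct = vapply(classes, function(cl) sum(a_ct$class == cl),
                       integer(1)),
    unique_hs = vapply(classes, function(cl) sum(a_hs$class == cl),
                       integer(1)),
    ambiguous_ct = vapply(classes, function(cl)
      sum(a_ct$amb[a_ct$class == cl]), integer(1)),
    ambiguous_hs = vapply(classes, function(cl)
      sum(a_hs$amb[a_hs$class == cl]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  shared <- do.call(rbind, lapply(classes, function(cl) {
    t_ct <- names(a_ct$class)[a_ct$class == cl]
    t_hs <- names(a_hs$class)[a_hs$class == cl]
    data.frame(class = cl,
               shared = length(intersect(t_ct, t_hs)),
               exclusive_ct = length(setdiff(t_ct, t_hs)),
               exclusive_hs = length(setdiff(t_hs, t_ct)),
               stringsAsFactors = FALSE)
  }))
  ld <- do.call(rbind, lapply(classes, function(cl) {
    t_ct <- names(a_ct$class)[a_ct$class == cl]
    t_hs <- names(a_hs$class)[a_hs$class == cl]
    lens <- sort(unique(nchar(c(t_ct, t_hs))))
    data.frame(class = cl, length = lens,
               count_ct = vapply(lens, function(l)
                 sum(nchar(t_ct) == l), integer(1)),
               count_hs = vapply(lens, function(l)
                 sum(nchar(t_hs) == l), integer(1)),
               stringsAsFactors = FALSE)
  }))
  list(class_counts = class_counts,
       assignments = list(ct = a_ct, hs = a_hs),
       shared = shared, length_dist = ld)
}

#' Per-CDS siRNA profiles with density thresholds
#'
#' Aligns each library's tags against the CDS set and builds, per CDS and
#' library: the unique-siRNA count, redundant RPM, and a per-position
#' unique-coverage vector. Selection uses a strictly-greater unique-count
#' threshold; very dense CDSs are flagged separately.
#'
#' @param libs named list of two [srna_library()] objects
#'   (`ct` and `hs`).
#' @param cds data.frame with columns `id`, `sequence`.
#' @param max_mismatch alignment mismatches (default 3).
#' @param min_unique strict selection threshold on unique siRNA count
#'   (default 50).
#' @param high_density strict flag threshold (default 1000).
#' @return list of per-CDS profiles (class `cds_profile`): each has `id`,
#'   `length`, `unique` (named per-library), `rpm` (named), `coverage`
#'   (list of per-library integer vectors), `selected` (named logical,
#'   unique > min_unique in that library), `high_density`.
#' @export
profile_cds <- function(libs, cds, max_mismatch = 3L, min_unique = 50L,
                        high_density = 1000L) {
  stopifnot(all(c("ct", "hs") %in% names(libs)))
  per_lib <- lapply(libs, function(lib) {
    tags <- names(lib$tags)
    if (!length(tags)) return(NULL)
    align_tags(tags, cds, max_mismatch = max_mismatch)
  })
  out <- lapply(seq_len(nrow(cds)), function(i) {
    id <- cds$id[i]; L <- nchar(cds$sequence[i])
    unique_n <- c(ct = 0L, hs = 0L); rpm_v <- c(ct = 0, hs = 0)
    cov <- list(ct = integer(L), hs = integer(L))
    for (nm in c("ct", "hs")) {
      h <- per_lib[[nm]]
      if (is.null(h)) next
      h <- h[h$ref_id == id, , drop = FALSE]
      if (!nrow(h)) next
      utags <- unique(h$tag)
      unique_n[nm] <- length(utags)
      lib <- libs[[nm]]
      red <- sum(as.numeric(lib$tags[utags]))
      if (lib$total_redundant > 0) rpm_v[nm] <- rpm(red, lib$total_redundant)
      # unique coverage: each distinct tag adds 1 over its best placements
      first <- h[!duplicated(h$tag), , drop = FALSE]
      for (k in seq_len(nrow(first))) {
        idx <- (first$pos[k] + 1L):min(first$pos[k] + nchar(first$tag[k]), L)
        cov[[nm]][idx] <- cov[[nm]][idx] + 1L
      }
    }
    structure(list(id = id, length = L, unique = unique_n, rpm = rpm_v,
                   coverage = cov,
                   selected = unique_n > min_unique,
                   high_density = unique_n > high_density),
              class = "cds_profile")
  })
  names(out) <- cds$id
  out
}

#' Call the siRNA hotspot of a CDS profile
#'
#' Maximal-density window over the unique-coverage vector (sliding
#' window, fixed step); the end-bias label is 5'/3' when the hotspot
#' midpoint falls within the terminal 20% of the CDS, internal otherwise.
#'
#' @param profile a `cds_profile` from [profile_cds()].
#' @param library which coverage vector to use (`"hs"` or `"ct"` or
#'   `"sum"` for both).
#' @param window,step window length and step (nt).
#' @return object of class `hotspot_call`: list with `id`, `start`,
#'   `end` (0-based half-open), `density` (mean unique coverage inside),
#'   `global_density`, `end_bias` ("5p"/"3p"/"internal").
#' @export
hotspot <- function(profile, library = "sum", window = 50L, step = 10L) {
  cov <- if (library == "sum") profile$coverage$ct + profile$coverage$hs
         else profile$coverage[[library]]
  L <- profile$length
  window <- min(window, L)
  starts <- unique(c(seq(0L, L - window, by = step), L - window))
  dens <- vapply(starts, function(s)
    mean(cov[(s + 1L):(s + window)]), numeric(1))
  best <- starts[which.max(dens)]
  mid <- best + window / 2
  end_bias <- if (mid <= 0.2 * L) "5p" else if (mid >= 0.8 * L) "3p"
              else "internal"
  structure(list(id = profile$id, start = as.integer(best),
                 end = as.integer(best + window),
                 density = max(dens), global_density = mean(cov),
                 end_bias = end_bias),
            class = "hotspot_call")
}

#' @export
print.hotspot_call <- function(x, ...) {
  cat(sprintf(
    "hotspot on %s: [%d, %d) density %.2f (global %.2f), %s-biased\n",
    x$id, x$start, x$end, x$density, x$global_density, x$end_bias))
  invisible(x)
}

#' Fisher verdict on per-CDS unique siRNA counts
#'
#' Two-sided Fisher exact test of the unique-siRNA counts of one CDS
#' against the libraries' non-redundant totals.
#'
#' @param unique_ct,unique_hs unique siRNA counts on the CDS.
#' @param total_ct,total_hs non-redundant library totals.
#' @param alpha significance level.
#' @return list with `p_value`, `significant`, `direction`
#'   (`"hs"`/`"ct"`/`"none"`: condition with the higher proportion).
#' @export
cds_differential <- function(unique_ct, unique_hs, total_ct, total_hs,
                             alpha = 0.05) {
  p <- fisher_exact_two_sided(unique_hs, total_hs - unique_hs,
                              unique_ct, total_ct - unique_ct)
  prop_hs <- unique_hs / total_hs; prop_ct <- unique_ct / total_ct
  list(p_value = p, significant = p < alpha,
       direction = if (p >= alpha || prop_hs == prop_ct) "none"
                   else if (prop_hs > prop_ct) "hs" else "ct")
}
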