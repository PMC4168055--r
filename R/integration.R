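#' Mean methylation level of a region, by context
#'
#' Unweighted mean of the per-site levels of one context within a 0-based
#' half-open interval of the track.
#'
#' @param track methylation data.frame from [read_methylation_track()].
#' @param seqid reference name.
#' @param start,end interval (0-based half-open).
#' @param context one of CG/CHG/CHH.
#' @return mean level, or `NA` (with attribute `absent = TRUE`) when the
#'   region holds no site of that context.
#' @export
region_methylation <- function(track, seqid, start, end, context) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  sel <- track$seqid == seqid & track$position >= start &
    track$position < end & track$context == context
  if (!any(sel)) {
    out <- NA_real_
    attr(out, "absent") <- TRUE
    return(out)
  }
  mean(track$level[sel])
}

#' Normalized transcript abundance of a region in two conditions
#'
#' Sums per-base coverage inside the interval, normalizes per million by
#' each library total, and reports the log2(Hs/CT) ratio (NA when a
#' condition has zero signal; see [log2fc()]).
#'
#' @param coverage_ct,coverage_hs coverage data.frames
#'   ([read_coverage_track()]).
#' @param seqid,start,end interval (0-based half-open).
#' @param total_ct,total_hs library totals used as denominators.
#' @return list with `rpm_ct`, `rpm_hs`, `log2_ratio`, `exclusive`
#'   (TRUE when exactly one condition has signal).
#' @export
region_expression <- function(coverage_ct, coverage_hs, seqid, start, end,
                              total_ct, total_hs) {
  grab <- function(cov) {
    sel <- cov$seqid == seqid & cov$position >= start & cov$position < end
    sum(cov$depth[sel])
  }
  s_ct <- grab(coverage_ct); s_hs <- grab(coverage_hs)
  rpm_ct <- rpm(s_ct, total_ct); rpm_hs <- rpm(s_hs, total_hs)
  list(rpm_ct = rpm_ct, rpm_hs = rpm_hs,
       log2_ratio = log2fc(rpm_hs, rpm_ct),
       exclusive = xor(s_ct > 0, s_hs > 0))
}

#' Co-locate a siRNA hotspot with methylation and transcript coverage
#'
#' Compares per-context methylation means inside the hotspot against
#' flanking regions of equal length immediately up/downstream (within the
#' CDS), and the transcript Hs/CT log2 ratio inside the hotspot. The
#' verdict is "concordant" iff CG and CHG hotspot means both exceed their
#' flank means AND the transcript ratio is negative; otherwise
#' "discordant" with the failing clause named.
#'
#' @param hs a `hotspot_call` from [hotspot()].
#' @param track methylation data.frame.
#' @param coverage_ct,coverage_hs coverage data.frames.
#' @param total_ct,total_hs coverage library totals.
#' @param cds_length length of the CDS (flanks are clipped to
#'   `[0, cds_length)`).
#' @return object of class `region_report`: list with `interval`,
#'   `methylation` (hotspot/flank means per context), `expression`
#'   ([region_expression()] result), `verdict`, `failed` (character
#'   vector of failing clauses, empty when concordant).
#' @export
colocalize <- function(hs, track, coverage_ct, coverage_hs,
                       total_ct, total_hs, cds_length) {
  w <- hs$end - hs$start
  fl_start <- max(0L, hs$start - w); fl_end <- min(cds_length, hs$end + w)
  meth <- list()
  for (ctx in c("CG", "CHG", "CHH")) {
    inside <- region_methylation(track, hs$id, hs$start, hs$end, ctx)
    left <- if (fl_start < hs$start)
      region_methylation(track, hs$id, fl_start, hs$start, ctx) else NA
    right <- if (fl_end > hs$end)
      region_methylation(track, hs$id, hs$end, fl_end, ctx) else NA
    flank <- mean(c(left, right), na.rm = TRUE)
    meth[[ctx]] <- c(hotspot = as.numeric(inside), flank = flank)
  }
  expr <- region_expression(coverage_ct, coverage_hs, hs$id,
                            hs$start, hs$end, total_ct, total_hs)
  failed <- character(0)
  meth_ok <- !is.na(meth$CG["hotspot"]) && !is.na(meth$CHG["hotspot"]) &&
    !is.nan(meth$CG["flank"]) && !is.nan(meth$CHG["flank"]) &&
    meth$CG["hotspot"] > meth$CG["flank"] &&
    meth$CHG["hotspot"] > meth$CHG["flank"]
  if (!isTRUE(meth_ok)) failed <- c(failed, "methylation")
  expr_ok <- !is.na(expr$log2_ratio) && expr$log2_ratio < 0
  if (!isTRUE(expr_ok)) failed <- c(failed, "expression")
  structure(list(interval = list(seqid = hs$id, start = hs$start,
                                 end = hs$end),
                 methylation = meth, expression = expr,
                 verdict = if (length(failed)) "discordant" else "concordant",
                 failed = failed),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("region [%d, %d) on %s: %s\n", x$interval$start,
              x$interval$end, x$interval$seqid, x$verdict))
  for (ctx in names(x$methylation))
    cat(sprintf("  %-3s hotspot %.3f vs flank %.3f\n", ctx,
                x$methylation[[ctx]]["hotspot"],
                x$methylation[[ctx]]["flank"]))
  cat(sprintf("  transcript log2(Hs/CT) = %.3f\n",
              x$expression$log2_ratio))
  if (length(x$failed))
    cat("  failing clause(s):", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
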