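#' Reads-per-million normalization
#'
#' @param count raw read count(s).
#' @param total library total (filtered redundant reads).
#' @return `count / total * 1e6`.
#' @export
rpm <- function(count, total) {
  stopifnot(total > 0, all(count >= 0))
  count / total * 1e6
}

#' Log2 fold change of normalized abundances
#'
#' Returns `log2(rpm_hs / rpm_ct)`; `NA` when either abundance is 0
#' (condition-exclusive unit, rendered "-" on output).
#'
#' @param rpm_hs,rpm_ct normalized abundances in the inoculated (Hs) and
#'   control (CT) conditions.
#' @return numeric (vectorised), `NA` where undefined.
#' @export
log2fc <- function(rpm_hs, rpm_ct) {
  out <- ifelse(rpm_hs > 0 & rpm_ct > 0, log2(rpm_hs / rpm_ct), NA_real_)
  unname(out)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by minimum-likelihood summation: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' 1e-12 relative tolerance for ties).
#'
#' @param a,b,c,d cell counts of the 2x2 table `rbind(c(a, b), c(c, d))`;
#'   for library comparisons use
#'   `(count_hs, total_hs - count_hs, count_ct, total_ct - count_ct)`.
#' @return the two-sided p-value; tables with a zero margin return 1.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d
  c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  # support of the (1,1) cell given margins
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  k <- lo:hi
  # dhyper over the column margin keeps the support small for unit counts
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- probs[k == a]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' Differential abundance table for profiled units
#'
#' For each unit (miRNA family or tag) computes RPM in both conditions,
#' log2(Hs/CT), a two-sided Fisher exact p-value on
#' `(count, total - count)` per condition, Bonferroni adjustment over the
#' number of units actually tested, and a regulation status.
#'
#' @param profiles data.frame with columns `unit`, `count_ct`, `count_hs`.
#' @param total_ct,total_hs library totals used as RPM denominators.
#' @param alpha significance level for the status call.
#' @return data.frame with columns `unit`, `count_ct`, `count_hs`,
#'   `rpm_ct`, `rpm_hs`, `log2fc`, `p_raw`, `p_adj`, `status` where
#'   status is one of up/down/unchanged/ct_only/hs_only.
#' @export
differential_table <- function(profiles, total_ct, total_hs, alpha = 0.05) {
  stopifnot(all(c("unit", "count_ct", "count_hs") %in% names(profiles)))
  n <- nrow(profiles)
  if (n == 0)
    return(data.frame(unit = character(), count_ct = integer(),
                      count_hs = integer(), rpm_ct = numeric(),
                      rpm_hs = numeric(), log2fc = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  rpm_ct <- rpm(profiles$count_ct, total_ct)
  rpm_hs <- rpm(profiles$count_hs, total_hs)
  lfc <- log2fc(rpm_hs, rpm_ct)
  p_raw <- mapply(function(hs, ct)
    fisher_exact_two_sided(hs, total_hs - hs, ct, total_ct - ct),
    profiles$count_hs, profiles$count_ct)
  p_adj <- pmin(1, p_raw * n)   # Bonferroni over units tested
  status <- ifelse(profiles$count_ct == 0 & profiles$count_hs > 0, "hs_only",
            ifelse(profiles$count_hs == 0 & profiles$count_ct > 0, "ct_only",
            ifelse(!is.na(lfc) & lfc > 0 & p_adj < alpha, "up",
            ifelse(!is.na(lfc) & lfc < 0 & p_adj < alpha, "down",
                   "unchanged"))))
  data.frame(unit = profiles$unit, count_ct = profiles$count_ct,
             count_hs = profiles$count_hs, rpm_ct = rpm_ct, rpm_hs = rpm_hs,
             log2fc = lfc, p_raw = p_raw, p_adj = p_adj, status = status,
             stringsAsFactors = FALSE)
}
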