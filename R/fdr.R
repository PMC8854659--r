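## Benjamini-Hochberg step-up FDR and element calling. bh_fdr is a direct
## implementation of the step-up formula (tests cross-check it against an
## independent reference).

#' Benjamini-Hochberg q-values
#'
#' `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`, clipped to 1; returned in
#' the order of the input.
#'
#' @param pvals vector of p-values, all in `(0, 1]`.
#' @return q-values in `[0, 1]`, same order as `pvals`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(m * pvals[o] / (m:1)))
  q[order(o)]
}

#' Call accelerated regions at an FDR threshold
#'
#' Strict inequality: an element is called iff `q_fdr < q_threshold`.
#' Output is sorted by q, then genomic position.
#'
#' @param results data.frame with at least `q_fdr` and, if present, `chrom`
#'   and `start` columns (as produced by [test_elements()]).
#' @param q_threshold FDR threshold (default 0.05; the study's AR call).
#' @return the subset of rows called, re-sorted.
#' @export
call_ars <- function(results, q_threshold = 0.05) {
  stopifnot(is.data.frame(results), "q_fdr" %in% names(results))
  hit <- results[!is.na(results$q_fdr) & results$q_fdr < q_threshold, , drop = FALSE]
  ord <- if (all(c("chrom", "start") %in% names(hit)))
    order(hit$q_fdr, hit$chrom, hit$start)
  else order(hit$q_fdr)
  hit[ord, , drop = FALSE]
}

#' Candidate accelerated regions at a relaxed threshold
#'
#' Same rule as [call_ars()] with the study's genome-wide-significance
#' candidate threshold (default q < 0.1).
#'
#' @inheritParams call_ars
#' @export
candidate_ars <- function(results, q_threshold = 0.1) {
  call_ars(results, q_threshold)
}
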