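## Run the acceleration LRT over a set of attached tiles: per-stratum
## simulated nulls, per-tile constrained fits, smoothed empirical p-values,
## and genome-wide BH correction.

#' Test attached tiles for subtree acceleration
#'
#' Tiles are grouped into (species-presence set, length) strata; each
#' stratum gets one simulated null distribution of `n_sims` neutral
#' elements (seeded deterministically from the master seed and the stratum
#' key, so results do not depend on processing order). Every tile is fitted
#' under both hypotheses, given a smoothed empirical p-value against its
#' stratum null, and BH-corrected across all tested tiles.
#'
#' @param model a `neutral_model`.
#' @param tiles output of [attach_alignments()] (or its `tiles` component).
#' @param subtree tested leaf set (proper subset of the model's leaves).
#' @param n_sims simulations per stratum null (default 100000; desk-scale
#'   runs use a few thousand).
#' @param seed master seed.
#' @return list with `results` (data.frame in [write_results_tsv()] column
#'   order plus `stratum`), `nulls` (per-stratum `null_dist`), and
#'   `flagged` (ids excluded for optimizer failure).
#' @export
test_elements <- function(model, tiles, subtree, n_sims = 100000L, seed = 1L) {
  if (is.list(tiles) && !is.null(tiles$tiles)) tiles <- tiles$tiles
  if (!length(tiles))
    return(list(results = empty_results(), nulls = list(), flagged = character(0)))
  keys <- vapply(tiles, function(t) stratum_key(t$presence, t$end - t$start), "")
  groups <- split(seq_along(tiles), keys)
  rows <- vector("list", length(tiles))
  nulls <- list()
  flagged <- character(0)
  for (key in sort(names(groups))) {
    idx <- groups[[key]]
    t1 <- tiles[[idx[1]]]
    pres <- t1$presence
    L <- t1$end - t1$start
    pm <- prune_to_species(model, pres)
    sub <- intersect(subtree, pres)
    mask <- subtree_edges(pm$tree, sub)
    label <- attr(mask, "label")
    nd <- build_null_distribution(model, pres, L, subtree, n_sims,
                                  derive_seed(seed, key))
    nulls[[key]] <- nd
    for (i in idx) {
      t <- tiles[[i]]
      enc <- encode_alignment(pm, t$seqs[pres])
      f <- tryCatch(fit_element_cpp(pm, enc, mask), error = function(e) NULL)
      if (is.null(f) || !is.finite(f$lnL_null) || !is.finite(f$lnL_alt)) {
        flagged <- c(flagged, t$element_id)
        next
      }
      lrt <- max(0, 2 * (f$lnL_alt - f$lnL_null))
      rows[[i]] <- data.frame(
        element_id = t$element_id, chrom = t$chrom, start = t$start,
        end = t$end, branch_label = label, lnL_null = f$lnL_null,
        lnL_alt = f$lnL_alt, s_hat = f$s_alt, rho_hat = f$rho, lrt = lrt,
        p_emp = empirical_p(lrt, nd, key), q_fdr = NA_real_,
        stratum = key, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) res <- empty_results()
  if (nrow(res)) {
    res$q_fdr <- bh_fdr(res$p_emp)
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  list(results = res, nulls = nulls, flagged = flagged)
}

empty_results <- function() {
  df <- data.frame(element_id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   branch_label = character(0), lnL_null = numeric(0),
                   lnL_alt = numeric(0), s_hat = numeric(0),
                   rho_hat = numeric(0), lrt = numeric(0),
                   p_emp = numeric(0), q_fdr = numeric(0),
                   stratum = character(0), stringsAsFactors = FALSE)
  df
}

#' Write called accelerated regions as a BED file
#'
#' Name is the element id; score is `-10 * log10(q)` capped at 1000.
#'
#' @param ars data.frame of called regions (from [call_ars()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ar_bed <- function(ars, file) {
  score <- pmin(1000, round(-10 * log10(pmax(ars$q_fdr, 1e-100))))
  write_bed(data.frame(chrom = ars$chrom, start = ars$start, end = ars$end,
                       name = ars$element_id, score = score,
                       stringsAsFactors = FALSE), file)
}
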