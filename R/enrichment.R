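## Gene-list FDR-shift test: do the q-values of elements annotated to a
## gene list sit lower (stronger acceleration) than the genome-wide element
## q-value distribution? One-sided unpaired Welch t-test; positive t means
## the list mean is below the background mean.

#' Collect q-values of elements annotated to a gene list
#'
#' Every element assigned (within `flank` of a coding span) to at least one
#' list gene contributes its q exactly once. List genes absent from the
#' gene models are skipped with a warning.
#'
#' @param results per-element results data.frame (needs `element_id`,
#'   `chrom`, `start`, `end`, `q_fdr`).
#' @param gene_list character vector of gene ids.
#' @param genes gene models data.frame from [read_genes()].
#' @param flank assignment flank in bp (default 10000).
#' @return named numeric vector of q-values (names = element ids).
#' @export
elements_for_gene_list <- function(results, gene_list, genes, flank = 10000L) {
  missing <- setdiff(gene_list, genes$gene_id)
  if (length(missing))
    warning("gene(s) in list absent from gene models, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  sub <- genes[genes$gene_id %in% gene_list, , drop = FALSE]
  if (!nrow(sub)) return(setNames(numeric(0), character(0)))
  asn <- map_elements_to_genes(results, sub, flank)
  ids <- unique(asn$element_id)
  q <- results$q_fdr[match(ids, results$element_id)]
  setNames(q, ids)
}

#' One-sided Welch shift test of list vs background q-values
#'
#' `t = (mean(background) - mean(list)) / SE_Welch` with
#' Welch-Satterthwaite degrees of freedom; the one-sided p is the upper
#' tail (alternative: list mean lower, i.e. list-wide acceleration).
#'
#' @param q_list q-values of list-annotated elements (n >= 2).
#' @param q_background genome-wide q-values (n >= 2; by default includes
#'   the list elements, as the background is "all elements").
#' @param name label for the list.
#' @return object of class `enrichment_result`: `name`, `n_list`,
#'   `n_background`, `mean_q_list`, `mean_q_background`, `t`, `df`,
#'   `p` (one-sided).
#' @export
fdr_shift_test <- function(q_list, q_background, name = "list") {
  n1 <- length(q_list); n2 <- length(q_background)
  if (n1 < 2 || n2 < 2)
    stop("both samples need at least 2 elements (got ", n1, ", ", n2, ")",
         call. = FALSE)
  v1 <- var(q_list); v2 <- var(q_background)
  if (v1 == 0 && v2 == 0)
    stop("zero variance in both samples; shift test undefined", call. = FALSE)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(q_background) - mean(q_list)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  structure(list(name = name, n_list = n1, n_background = n2,
                 mean_q_list = mean(q_list), mean_q_background = mean(q_background),
                 t = t, df = df, p = pt(t, df, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "FDR-shift test '%s': n=%d vs background n=%d\n  mean q %.4f vs %.4f; t = %.3f, df = %.2f, one-sided p = %.4g\n",
    x$name, x$n_list, x$n_background, x$mean_q_list, x$mean_q_background,
    x$t, x$df, x$p))
  invisible(x)
}

#' Write enrichment results as a one-row-per-list TSV
#'
#' @param results list of `enrichment_result` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_enrichment_tsv <- function(results, file) {
  df <- do.call(rbind, lapply(results, function(x)
    data.frame(list_name = x$name, n_list = x$n_list,
               n_background = x$n_background, mean_q_list = x$mean_q_list,
               mean_q_background = x$mean_q_background, t = x$t, df = x$df,
               p_one_sided = x$p, stringsAsFactors = FALSE)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
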