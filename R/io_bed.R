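## BED / BED12 / GFF3 ingestion (via rtracklayer) and the results TSV.
## Everything is 0-based half-open internally; GFF3's 1-based inclusive
## coordinates are converted at this boundary only.

#' Read a BED file of genomic intervals
#'
#' @param file path to a BED file (3+ columns).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name` (row index as a string if absent).
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  nm <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
        else as.character(seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}

#' Write intervals as BED (optionally with scores)
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns (0-based half-open).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bed <- function(df, file) {
  cols <- list(df$chrom, as.integer(df$start), as.integer(df$end))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name))
    if (!is.null(df$score)) cols <- c(cols, list(as.integer(round(df$score))))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), file)
  invisible(file)
}

#' Read gene models with their coding spans
#'
#' The coding span is the genomic interval from the first to the last coding
#' base (introns included): BED12 `thickStart`/`thickEnd`, or the union span
#' of all `CDS` features of a gene in GFF3. GFF3 genes with no CDS are
#' skipped with a warning.
#'
#' @param file path to a BED12 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed12"`, or `"gff3"`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (coding span,
#'   0-based half-open), `strand`.
#' @export
read_genes <- function(file, format = c("auto", "bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3" else "bed12"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(file, format = "bed")
    if (is.null(gr$thick))
      stop("BED12 gene file lacks thickStart/thickEnd columns", call. = FALSE)
    ids <- as.character(gr$name)
    if (anyDuplicated(ids))
      stop("duplicate gene ids in ", file, call. = FALSE)
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = IRanges::start(gr$thick) - 1L,
                      end = IRanges::end(gr$thick),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(file, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    ## resolve each CDS to a gene id: gene_id attr, else Parent (through one
    ## mRNA/transcript level if needed), else its own ID
    ids_all <- if (!is.null(meta$ID)) as.character(meta$ID) else rep(NA, length(gr))
    parent_of <- function(i) {
      p <- meta$Parent[[i]]
      if (length(p)) as.character(p[1]) else NA_character_
    }
    cds <- which(meta$type == "CDS")
    if (!length(cds)) stop("no CDS features in ", file, call. = FALSE)
    gid <- character(length(cds))
    for (k in seq_along(cds)) {
      i <- cds[k]
      g <- if (!is.null(meta$gene_id)) as.character(meta$gene_id[i]) else NA
      if (is.na(g) || !nzchar(g)) {
        g <- parent_of(i)
        if (!is.na(g)) {
          j <- match(g, ids_all)
          if (!is.na(j) && as.character(meta$type[j]) %in% c("mRNA", "transcript")) {
            gp <- parent_of(j)
            if (!is.na(gp)) g <- gp
          }
        }
      }
      if (is.na(g) || !nzchar(g)) g <- ids_all[i]
      gid[k] <- g
    }
    sp <- split(seq_along(cds), gid)
    out <- do.call(rbind, lapply(names(sp), function(g) {
      ii <- cds[sp[[g]]]
      data.frame(gene_id = g,
                 chrom = as.character(GenomicRanges::seqnames(gr))[ii[1]],
                 start = min(GenomicRanges::start(gr)[ii]) - 1L,
                 end = max(GenomicRanges::end(gr)[ii]),
                 strand = as.character(GenomicRanges::strand(gr))[ii[1]],
                 stringsAsFactors = FALSE)
    }))
    genes_declared <- if (!is.null(meta$type)) ids_all[meta$type == "gene"] else character(0)
    nocds <- setdiff(genes_declared[!is.na(genes_declared)], out$gene_id)
    if (length(nocds))
      warning("gene(s) with no CDS skipped: ", paste(nocds, collapse = ", "),
              call. = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a gene list (one symbol per line)
#'
#' @param file path; blank lines and `#` comments are ignored.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

RESULT_COLS <- c("element_id", "chrom", "start", "end", "branch_label",
                 "lnL_null", "lnL_alt", "s_hat", "rho_hat", "lrt",
                 "p_emp", "q_fdr")

#' Write per-element acceleration results as TSV
#'
#' Stable column set: element id, coordinates, branch-set label, both
#' log-likelihoods, fitted scales, LRT, empirical p, and BH q. Numbers are
#' written with full precision so write/read round-trips are exact.
#'
#' @param results data.frame as produced by [test_elements()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_results_tsv <- function(results, file) {
  stopifnot(all(RESULT_COLS %in% names(results)))
  out <- results[, RESULT_COLS, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("start", "end")
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a results TSV written by [write_results_tsv()]
#' @param file path.
#' @return data.frame with the documented columns.
#' @export
read_results_tsv <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(element_id = "character", chrom = "character",
                            branch_label = "character"))
}
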