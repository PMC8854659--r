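## Element-to-gene assignment within a symmetric flank of each gene's
## coding span, and the run summaries built on it. Assignment is
## many-to-many: an element may map to 0, 1, or several genes.

#' Assign elements to genes within a flank of the coding span
#'
#' An assignment is emitted iff the gap between the element and the gene's
#' coding span is at most `flank` bp (0 when they overlap). Strand-agnostic
#' and symmetric. Elements on chromosomes absent from the gene set are
#' simply unassigned.
#'
#' @param elements data.frame with `chrom`, `start`, `end` and an id column
#'   (`element_id` or `name`); 0-based half-open.
#' @param genes data.frame from [read_genes()] (`gene_id`, `chrom`,
#'   `start`, `end` coding spans).
#' @param flank maximum gap in bp (default 10000).
#' @return data.frame with `element_id`, `gene_id`, `distance` (signed:
#'   0 when overlapping, positive when the element lies right of the span,
#'   negative when left; `abs(distance) <= flank`).
#' @export
map_elements_to_genes <- function(elements, genes, flank = 10000L) {
  ids <- elements$element_id
  if (is.null(ids)) ids <- elements$name
  if (is.null(ids)) ids <- as.character(seq_len(nrow(elements)))
  if (!nrow(elements) || !nrow(genes))
    return(data.frame(element_id = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  el <- GenomicRanges::GRanges(elements$chrom,
                               IRanges::IRanges(elements$start + 1L, elements$end))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(el, gn, maxgap = flank, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  es <- elements$start[qi]; ee <- elements$end[qi]
  gs <- genes$start[si]; ge <- genes$end[si]
  dist <- ifelse(es >= ge, es - ge, ifelse(ee <= gs, ee - gs, 0L))
  keep <- abs(dist) <= flank           # enforce the strict gap rule exactly
  data.frame(element_id = ids[qi][keep], gene_id = genes$gene_id[si][keep],
             distance = as.integer(dist[keep]), stringsAsFactors = FALSE)
}

#' Unique gene ids among assignments
#'
#' @param assignments data.frame from [map_elements_to_genes()].
#' @return list with `genes` (sorted unique ids) and `n`.
#' @export
unique_genes <- function(assignments) {
  g <- sort(unique(assignments$gene_id))
  list(genes = g, n = length(g))
}

#' Overlap between two AR call sets over the same element universe
#'
#' `shared` counts elements called in both runs; the display percentage is
#' `100 * shared / (n_a + n_b)` rounded to the nearest integer (each run's
#' calls contribute to the denominator, the shared set is counted once),
#' with the exact fraction also reported.
#'
#' @param run_a,run_b character vectors of called element ids, or
#'   data.frames with an `element_id` column.
#' @param universe optional character vector of all testable element ids;
#'   if given, calls outside it raise an error (guards against comparing
#'   runs from different tilings).
#' @return list with `shared`, `percent` (integer display value),
#'   `percent_exact`, `n_a`, `n_b`.
#' @export
overlap_between_runs <- function(run_a, run_b, universe = NULL) {
  a <- if (is.data.frame(run_a)) run_a$element_id else run_a
  b <- if (is.data.frame(run_b)) run_b$element_id else run_b
  if (!is.null(universe)) {
    out <- setdiff(c(a, b), universe)
    if (length(out))
      stop("calls outside the shared element universe: ",
           paste(head(out, 5), collapse = ", "), call. = FALSE)
  }
  shared <- length(intersect(a, b))
  denom <- length(a) + length(b)
  pexact <- if (denom > 0) 100 * shared / denom else 0
  list(shared = shared, percent = as.integer(round(pexact)),
       percent_exact = pexact, n_a = length(a), n_b = length(b))
}
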