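## Regularize conserved elements into fixed-width tiles and attach
## per-tile sub-alignments. Tiling lays W-bp windows from each (merged)
## element's start and drops the terminal remainder, so every tested unit
## has identical length and one simulated null is reusable per stratum.

#' Split conserved elements into fixed-width tiles
#'
#' Overlapping input elements are merged first; tiles of exactly `W` bp are
#' laid from each merged element's start and a terminal remainder shorter
#' than `W` is dropped. No tile crosses a merged-element boundary; splitting
#' already-`W`-width tiles is idempotent.
#'
#' @param elements data.frame with `chrom`, `start`, `end` and optional
#'   `name` (0-based half-open).
#' @param W tile width in reference bp (default 50).
#' @return data.frame with `element_id` (`<parent>.<ordinal>`), `chrom`,
#'   `start`, `end`, `parent_id`, sorted by (chrom, start).
#' @export
split_elements <- function(elements, W = 50L) {
  stopifnot(W >= 1)
  W <- as.integer(W)
  if (is.null(elements$name)) elements$name <- as.character(seq_len(nrow(elements)))
  out <- vector("list", 0L)
  for (chrom in sort(unique(elements$chrom))) {
    e <- elements[elements$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = e$start + 1L, end = e$end)  # 1-based closed
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      m_start <- IRanges::start(red)[k] - 1L     # back to 0-based
      m_end <- IRanges::end(red)[k]
      parent <- paste(e$name[revmap[[k]]], collapse = "|")
      n_tiles <- (m_end - m_start) %/% W
      if (n_tiles == 0L) next
      starts <- m_start + W * (seq_len(n_tiles) - 1L)
      out[[length(out) + 1L]] <- data.frame(
        element_id = paste0(parent, ".", seq_len(n_tiles)),
        chrom = chrom, start = starts, end = starts + W,
        parent_id = parent, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      parent_id = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## per-block extraction cache: pre-split texts only for blocks whose
## reference row contains gaps; gapless blocks are sliced with substr
index_maf_blocks <- function(blocks, ref) {
  lapply(blocks, function(b) {
    sp <- maf_species(b)
    ri <- which(sp == ref)
    if (length(ri) != 1L) return(NULL)
    rrow <- b$rows[ri, ]
    gapless <- !grepl("-", rrow$text, fixed = TRUE)
    list(sp = sp, chrom = sub("^[^.]*\\.", "", rrow$src),
         has_chrom = grepl(".", rrow$src, fixed = TRUE),
         b_start = rrow$start, b_end = rrow$start + rrow$size,
         texts = b$rows$text, gapless = gapless, block = b)
  })
}

extract_tile <- function(bi, tile, species, ref) {
  W <- tile$end - tile$start
  for (ix in bi) {
    if (is.null(ix)) next
    if (ix$has_chrom && ix$chrom != tile$chrom) next
    if (ix$b_start <= tile$start && ix$b_end >= tile$end) {
      if (ix$gapless) {
        a <- tile$start - ix$b_start + 1L
        seqs <- substr(ix$texts, a, a + W - 1L)
        names(seqs) <- ix$sp
        seqs <- seqs[!duplicated(names(seqs))]
        out <- setNames(rep(strrep("-", W), length(species)), species)
        common <- intersect(species, names(seqs))
        out[common] <- seqs[common]
        attr(out, "covered") <- W
        attr(out, "no_data") <- FALSE
        return(out)
      }
      break
    }
  }
  ## general path: interval spanning blocks, gapped reference, or no coverage
  extract_interval_alignment(lapply(bi[!vapply(bi, is.null, TRUE)], `[[`, "block"),
                             tile, species, ref)
}

#' Attach per-tile alignments from a MAF file
#'
#' Extracts each tile's reference-anchored sub-alignment, records its
#' species-presence set (species with at least one non-missing base), and
#' excludes tiles with fewer than `min_species` species present or with no
#' species of the tested subtree; exclusions are counted, not errors.
#'
#' @param tiles data.frame from [split_elements()].
#' @param maf path to a MAF file or a list of `maf_block`.
#' @param model the `neutral_model` (defines the species universe).
#' @param ref reference species name.
#' @param min_species minimum species present to retain a tile (default 3).
#' @param subtree optional tested leaf set; tiles with none of these species
#'   present are also excluded.
#' @return list with `tiles` (list of split elements: `element_id`, `chrom`,
#'   `start`, `end`, `seqs`, `presence`), `n_excluded`, and `excluded_ids`.
#' @export
attach_alignments <- function(tiles, maf, model, ref, min_species = 3L,
                              subtree = NULL) {
  stopifnot(min_species >= 2L)
  blocks <- if (is.character(maf)) read_maf(maf) else maf
  species <- model_leaves(model)
  bi <- index_maf_blocks(blocks, ref)
  kept <- vector("list", nrow(tiles))
  n_kept <- 0L
  excluded <- character(0)
  for (i in seq_len(nrow(tiles))) {
    tile <- tiles[i, ]
    seqs <- extract_tile(bi, tile, species, ref)
    pres <- species[vapply(seqs, function(s) grepl("[ACGTacgt]", s), TRUE)]
    drop <- length(pres) < min_species ||
      (!is.null(subtree) && !length(intersect(subtree, pres)))
    if (drop) {
      excluded <- c(excluded, tile$element_id)
    } else {
      n_kept <- n_kept + 1L
      kept[[n_kept]] <- list(element_id = tile$element_id, chrom = tile$chrom,
                             start = tile$start, end = tile$end,
                             seqs = seqs, presence = pres)
    }
  }
  list(tiles = kept[seq_len(n_kept)], n_excluded = length(excluded),
       excluded_ids = excluded)
}
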