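## MAF (Multiple Alignment Format) reading/writing and per-interval
## sub-alignment extraction. Blocks hold per-species rows (src, start,
## ungapped size, strand, srcSize, aligned text); the species name is the
## src up to the first '.'. Reading is streamed block-by-block so a file is
## never held in memory at once.

maf_block <- function(rows, score = NA_real_) {
  texts <- rows$text
  if (length(unique(nchar(texts))) > 1L)
    stop("MAF block rows have unequal aligned lengths", call. = FALSE)
  structure(list(score = score, rows = rows), class = "maf_block")
}

maf_species <- function(block) sub("\\..*$", "", block$rows$src)

parse_maf_s_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) != 7L) stop("malformed MAF 's' line: ", line, call. = FALSE)
  data.frame(src = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
             strand = f[5], srcSize = as.numeric(f[6]), text = f[7],
             stringsAsFactors = FALSE)
}

validate_maf_block <- function(block, index) {
  ungapped <- nchar(gsub("-", "", block$rows$text, fixed = TRUE))
  bad <- which(ungapped != block$rows$size)
  if (length(bad))
    stop(sprintf("MAF block %d: declared size %d != ungapped length %d for %s",
                 index, as.integer(block$rows$size[bad[1]]),
                 ungapped[bad[1]], block$rows$src[bad[1]]), call. = FALSE)
  block
}

#' Stream over the blocks of a MAF file
#'
#' Reads the file in line chunks and invokes `fun(block, index)` for each
#' alignment block; only one block is materialized at a time.
#'
#' @param file path to a MAF file (must begin with `##maf`).
#' @param fun callback taking a `maf_block` and its 1-based index.
#' @param chunk_lines lines per read (resource-use knob, not semantics).
#' @return number of blocks processed, invisibly.
#' @export
maf_apply <- function(file, fun, chunk_lines = 10000L) {
  con <- file(file, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first) || !startsWith(first, "##maf"))
    stop("not a MAF file (missing ##maf header): ", file, call. = FALSE)
  idx <- 0L
  cur_rows <- NULL
  cur_score <- NA_real_
  flush_block <- function() {
    if (!is.null(cur_rows)) {
      idx <<- idx + 1L
      fun(validate_maf_block(maf_block(do.call(rbind, cur_rows), cur_score), idx), idx)
      cur_rows <<- NULL
    }
  }
  repeat {
    lines <- readLines(con, n = chunk_lines)
    if (!length(lines)) break
    for (line in lines) {
      if (startsWith(line, "a")) {
        flush_block()
        sc <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1]]
        cur_score <- if (length(sc) == 2) as.numeric(sc[2]) else NA_real_
        cur_rows <- list()
      } else if (startsWith(line, "s")) {
        if (is.null(cur_rows)) stop("MAF 's' line outside a block", call. = FALSE)
        cur_rows[[length(cur_rows) + 1L]] <- parse_maf_s_line(line)
      }
      ## 'i', 'e', 'q' and comment lines are ignored
    }
  }
  flush_block()
  invisible(idx)
}

#' Read all blocks of a MAF file into a list
#'
#' Convenience wrapper over [maf_apply()] for desk-scale files.
#'
#' @param file path to a MAF file.
#' @return list of `maf_block` objects in file order.
#' @export
read_maf <- function(file) {
  blocks <- list()
  maf_apply(file, function(b, i) blocks[[i]] <<- b)
  blocks
}

#' Write MAF blocks to a file
#'
#' @param blocks list of `maf_block` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_maf <- function(blocks, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in blocks) {
    writeLines(if (is.na(b$score)) "a" else sprintf("a score=%g", b$score), con)
    r <- b$rows
    writeLines(sprintf("s %s %d %d %s %d %s", r$src, as.integer(r$start),
                       as.integer(r$size), r$strand, as.integer(r$srcSize),
                       r$text), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Extract a reference-anchored sub-alignment for one interval
#'
#' Returns one sequence per requested species covering exactly
#' `end - start` reference positions; alignment columns where the reference
#' has a gap are dropped, species absent from the covering block(s) are
#' filled with `-`, and reference positions covered by no block are filled
#' with `-` for every species. An interval with zero coverage is flagged
#' with attribute `no_data = TRUE`.
#'
#' @param blocks list of `maf_block` sorted by reference start.
#' @param interval list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open, reference coordinates).
#' @param species character vector of species to return.
#' @param ref reference species name (matched against src before the '.').
#' @return named character vector over `species`, each of length
#'   `end - start`, with attributes `covered` (reference bp covered) and
#'   `no_data`.
#' @export
extract_interval_alignment <- function(blocks, interval, species, ref) {
  start <- as.numeric(interval$start); end <- as.numeric(interval$end)
  chrom <- as.character(interval$chrom)
  W <- as.integer(end - start)
  out <- matrix("-", nrow = length(species), ncol = W,
                dimnames = list(species, NULL))
  covered <- rep(FALSE, W)
  for (b in blocks) {
    sp <- maf_species(b)
    ri <- which(sp == ref)
    if (length(ri) != 1L) next
    rrow <- b$rows[ri, ]
    rchrom <- sub("^[^.]*\\.", "", rrow$src)
    if (nzchar(rchrom) && rchrom != rrow$src && rchrom != chrom) next
    if (rrow$strand != "+")
      stop("reference strand must be '+' in MAF block", call. = FALSE)
    b_start <- rrow$start; b_end <- rrow$start + rrow$size
    if (b_end <= start || b_start >= end) next
    refchars <- strsplit(rrow$text, "", fixed = TRUE)[[1]]
    nongap <- refchars != "-"
    refpos <- b_start + cumsum(nongap) - 1L          # ref coord per column
    keep <- nongap & refpos >= start & refpos < end
    tgt <- refpos[keep] - start + 1L                 # 1-based output columns
    new <- !covered[tgt]                             # first block wins overlaps
    if (!any(new)) next
    colsel <- which(keep)[new]
    tgt <- tgt[new]
    for (si in seq_along(species)) {
      bi <- which(sp == species[si])
      if (length(bi) != 1L) next
      chars <- strsplit(b$rows$text[bi], "", fixed = TRUE)[[1]]
      out[si, tgt] <- chars[colsel]
    }
    covered[tgt] <- TRUE
  }
  res <- apply(out, 1L, paste, collapse = "")
  ## apply() on a 0-column matrix degenerates; guard
  if (W == 0L) res <- setNames(rep("", length(species)), species)
  attr(res, "covered") <- sum(covered)
  attr(res, "no_data") <- !any(covered)
  res
}
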