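test_that("split_elements tiles from element starts and drops remainders", {
  e <- data.frame(chrom = "chr1", start = 100L, end = 260L, name = "el1")
  t <- split_elements(e, 50)
  expect_equal(t$start, c(100L, 150L, 200L))
  expect_equal(t$end, c(150L, 200L, 250L))
  expect_equal(t$element_id, paste0("el1.", 1:3))

  short <- data.frame(chrom = "chr1", start = 0L, end = 49L, name = "s")
  expect_equal(nrow(split_elements(short, 50)), 0L)
})

test_that("splitting is idempotent and never crosses element boundaries", {
  e <- data.frame(chrom = "chr1", start = c(0L, 300L), end = c(150L, 475L),
                  name = c("a", "b"))
  t1 <- split_elements(e, 50)
  t2 <- split_elements(data.frame(chrom = t1$chrom, start = t1$start,
                                  end = t1$end, name = t1$element_id), 50)
  expect_equal(t2$start, t1$start)
  expect_equal(t2$end, t1$end)
  # no tile crosses an input boundary
  for (i in seq_len(nrow(t1))) {
    within <- any(e$start <= t1$start[i] & t1$end[i] <= e$end)
    expect_true(within)
  }
})

test_that("overlapping elements merge before tiling; width arithmetic holds", {
  e <- data.frame(chrom = "chr1", start = c(0L, 40L), end = c(60L, 160L),
                  name = c("x", "y"))
  t <- split_elements(e, 50)   # merged span [0,160) -> 3 tiles
  expect_equal(nrow(t), 3L)
  expect_equal(t$parent_id[1], "x|y")

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    start <- sort(sample(0:5000, n)) * 3L
    w <- sample(10:220, n, replace = TRUE)
    e <- data.frame(chrom = "chr1", start = start, end = start + w,
                    name = paste0("e", seq_len(n)))
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    expected <- sum(IRanges::width(ir) %/% 50L)
    expect_equal(nrow(split_elements(e, 50)), expected)
  }
})

test_that("attach_alignments extracts, filters, and counts exclusions", {
  d <- small_scenario(3)
  model <- read_mod(file.path(d, "neutral.mod"))
  tiles <- split_elements(read_bed(file.path(d, "conserved.bed")), 50)
  att <- attach_alignments(tiles, file.path(d, "aln.maf"), model, "human",
                           min_species = 3, subtree = "wedSeal")
  expect_equal(length(att$tiles) + att$n_excluded, nrow(tiles))
  truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  # presence sets match the generator's bookkeeping for retained tiles
  tmap <- setNames(truth$species_present, truth$element_id)
  for (t in att$tiles[seq_len(min(25, length(att$tiles)))]) {
    expect_setequal(t$presence, strsplit(tmap[[t$element_id]], ",")[[1]])
    expect_equal(nchar(t$seqs[[1]]), 50L)
  }
  # a min_species above the species count excludes everything
  att12 <- attach_alignments(tiles[1:4, ], file.path(d, "aln.maf"), model,
                             "human", min_species = 13)
  expect_equal(att12$n_excluded, 4L)
  expect_length(att12$tiles, 0L)
})

test_that("attached tile alignments reproduce the simulated MAF exactly", {
  d <- small_scenario(3)
  model <- read_mod(file.path(d, "neutral.mod"))
  blocks <- read_maf(file.path(d, "aln.maf"))
  tiles <- split_elements(read_bed(file.path(d, "conserved.bed")), 50)
  att <- attach_alignments(tiles, blocks, model, "human")
  t <- att$tiles[[1]]
  # independent extraction straight from the covering block's text
  b <- Filter(function(b) {
    ri <- which(arscan:::maf_species(b) == "human")
    length(ri) == 1 && b$rows$start[ri] <= t$start &&
      b$rows$start[ri] + b$rows$size[ri] >= t$end
  }, blocks)[[1]]
  ri <- which(arscan:::maf_species(b) == "human")
  off <- t$start - b$rows$start[ri]
  for (sp in t$presence) {
    si <- which(arscan:::maf_species(b) == sp)
    expect_equal(unname(t$seqs[sp]),
                 substr(b$rows$text[si], off + 1, off + 50))
  }
})
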