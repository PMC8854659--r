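genes_fix <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                        start = c(50000L, 120000L), end = c(60000L, 130000L),
                        strand = "+", stringsAsFactors = FALSE)

test_that("assignment honors the strict 10 kb gap rule", {
  el <- data.frame(element_id = c("up5k", "at10k", "at10001", "inside",
                                  "otherchr"),
                   chrom = c(rep("chr1", 4), "chr9"),
                   start = c(45000L - 50L, 50000L - 10000L - 50L,
                             50000L - 10001L - 50L, 55000L, 55000L),
                   stringsAsFactors = FALSE)
  el$end <- el$start + 50L
  asn <- map_elements_to_genes(el, genes_fix, flank = 10000)
  expect_setequal(asn$element_id, c("up5k", "at10k", "inside"))
  expect_equal(asn$distance[asn$element_id == "inside"], 0L)
  expect_equal(asn$distance[asn$element_id == "at10k"], -10000L)
  expect_equal(asn$distance[asn$element_id == "up5k"], -5000L)
})

test_that("elements between two close genes map to both", {
  g2 <- data.frame(gene_id = c("L", "R"), chrom = "chr1",
                   start = c(1000L, 20000L), end = c(10000L, 30000L))
  el <- data.frame(element_id = "mid", chrom = "chr1", start = 14000L,
                   end = 14050L)
  asn <- map_elements_to_genes(el, g2, flank = 10000)
  expect_setequal(asn$gene_id, c("L", "R"))
  expect_equal(sort(asn$distance), c(-5950L, 4000L))
})

test_that("assignment is translation-invariant and flank-monotone", {
  set.seed(99)
  el <- data.frame(element_id = paste0("e", 1:40), chrom = "chr1",
                   start = sample(0:190000, 40))
  el$end <- el$start + 50L
  a1 <- map_elements_to_genes(el, genes_fix, flank = 10000)
  shift <- 7777L
  el2 <- transform(el, start = start + shift, end = end + shift)
  g2 <- transform(genes_fix, start = start + shift, end = end + shift)
  a2 <- map_elements_to_genes(el2, g2, flank = 10000)
  expect_equal(a2[order(a2$element_id, a2$gene_id), ],
               a1[order(a1$element_id, a1$gene_id), ], ignore_attr = TRUE)
  a3 <- map_elements_to_genes(el, genes_fix, flank = 20000)
  key <- function(a) paste(a$element_id, a$gene_id)
  expect_true(all(key(a1) %in% key(a3)))
})

test_that("unique_genes deduplicates deterministically", {
  asn <- data.frame(element_id = c("e1", "e2", "e3"),
                    gene_id = c("g1", "g1", "g2"), distance = 0L)
  u <- unique_genes(asn)
  expect_equal(u$genes, c("g1", "g2"))
  expect_equal(u$n, 2L)
  empty <- unique_genes(data.frame(element_id = character(0),
                                   gene_id = character(0)))
  expect_equal(empty$n, 0L)
})

test_that("overlap_between_runs reproduces the published arithmetic", {
  a <- paste0("e", 1:10)
  same <- overlap_between_runs(a, a)
  expect_equal(same$percent, 50L)          # forced by the denominator
  expect_equal(overlap_between_runs(a[1:5], a[6:10])$shared, 0L)

  # printed study counts: 1471 and 577 calls sharing 264 -> "13%"
  run_a <- paste0("e", 1:1471)
  run_b <- paste0("e", c(1:264, 2001:2313))
  ov <- overlap_between_runs(run_a, run_b)
  expect_equal(ov$shared, 264L)
  expect_equal(ov$percent, 13L)
  expect_equal(ov$percent_exact, 100 * 264 / 2048)

  expect_error(overlap_between_runs(c("e1", "zz"), "e1", universe = paste0("e", 1:5)),
               "universe")
})
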