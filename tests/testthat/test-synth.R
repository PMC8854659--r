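test_that("make_tree places the target cherry and reference deterministically", {
  tr <- make_tree(4, seed = 11)
  expect_setequal(c("wedSeal", "walrus", "human") %in% tr$tip.label, TRUE)
  mrca <- ape::getMRCA(tr, c("wedSeal", "walrus"))
  kids <- tr$edge[tr$edge[, 1] == mrca, 2]
  expect_setequal(tr$tip.label[kids], c("wedSeal", "walrus"))  # sisters
  expect_identical(write_newick(make_tree(9, seed = 3)),
                   write_newick(make_tree(9, seed = 3)))
})

test_that("make_tree depth is calibrated on average", {
  depths <- vapply(1:100, function(s) {
    tr <- make_tree(10, seed = s, depth = 0.75)
    mean(ape::node.depth.edgelength(tr)[1:10])
  }, numeric(1))
  expect_gt(mean(depths), 0.75 * 0.8)
  expect_lt(mean(depths), 0.75 * 1.2)
})

test_that("generate_scenario emits a consistent miniature study", {
  d <- small_scenario(3)
  truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(truth), 200L)
  expect_true(all(truth$end - truth$start == 50L))
  # tiles match the BED after splitting
  tiles <- split_elements(read_bed(file.path(d, "conserved.bed")), 50)
  expect_equal(truth$element_id, tiles$element_id)
  expect_equal(truth$start, tiles$start)
  # planted rate is the configured fraction up to binomial noise
  expect_gt(mean(truth$accelerated), 0.005)
  expect_lt(mean(truth$accelerated), 0.15)
  # gene lists exist and are disjoint
  la <- readLines(file.path(d, "lists", "listA.txt"))
  lb <- readLines(file.path(d, "lists", "listB.txt"))
  expect_length(intersect(la, lb), 0L)
  genes <- read_genes(file.path(d, "genes.bed12"))
  expect_true(all(c(la, lb) %in% genes$gene_id))
  # model is readable and covers the MAF species
  model <- read_mod(file.path(d, "neutral.mod"))
  blocks <- read_maf(file.path(d, "aln.maf"))
  for (b in blocks)
    expect_true(all(arscan:::maf_species(b) %in% model_leaves(model)))
})

test_that("scenario generation is deterministic and honors f = 0", {
  cf <- scenario_config(n_tiles = 60, n_windows = 2, window_length = 40000L,
                        n_genes = 6, n_list_a = 2, n_list_b = 2,
                        frac_accel = 0, seed = 5)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- generate_scenario(cf, d1)
  s2 <- generate_scenario(cf, d2)
  expect_equal(sum(s1$truth$accelerated), 0L)
  for (k in c("mod", "maf", "bed", "truth"))
    expect_identical(readLines(s1$files[[k]]), readLines(s2$files[[k]]))
})

test_that("with multiplier 1 the planted rate is uniform near list genes", {
  rates <- matrix(0, nrow = 12, ncol = 2)
  for (s in 1:12) {
    cf <- scenario_config(n_tiles = 150, n_windows = 2,
                          window_length = 60000L, n_genes = 8, n_list_a = 3,
                          n_list_b = 3, frac_accel = 0.2, multiplier = 1,
                          seed = 6000 + s)
    sc <- generate_scenario(cf, file.path(tempdir(), paste0("mult1_", s)))
    tr <- sc$truth
    rates[s, ] <- c(mean(tr$accelerated[tr$in_list_a == 1]),
                    mean(tr$accelerated[tr$in_list_a == 0]))
  }
  # pooled rates equal within binomial noise
  expect_lt(abs(mean(rates[, 1]) - mean(rates[, 2])), 0.05)
})

test_that("scenario config round-trips through its JSON file", {
  d <- small_scenario(3)
  cf <- read_scenario_config(file.path(d, "scenario.json"))
  expect_s3_class(cf, "scenario_config")
  expect_equal(cf$n_tiles, 200)
  expect_equal(cf$target, "wedSeal")
  expect_equal(cf$subtree, c("wedSeal", "walrus"))
})
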