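# Core acceleration test machinery. Heavier statistical checks (calibration,
# power curves, end-to-end precision/recall) live in test-acceptance.R.

fake_null <- function(lrt, key = "k") {
  structure(list(key = key, lrt = sort(lrt), n_sims = length(lrt)),
            class = "null_dist")
}

test_that("empirical_p implements the smoothed counting rule", {
  nd <- fake_null(c(rep(0, 40), seq(0.1, 5.9, length.out = 59)))  # n = 99
  # 5 of 99 sims at or above 5.45 -> (1+5)/100
  expect_equal(empirical_p(5.45, nd), 0.06)
  # the minimum statistic has p exactly 1
  expect_equal(empirical_p(0, nd), 1)
  # above every simulated value: smoothing floor 1/(n+1)
  expect_equal(empirical_p(100, nd), 1 / 100)
  nd5 <- fake_null(rep(0, 99999))
  expect_equal(empirical_p(1e-9, nd5), 1 / 100000)
  expect_error(empirical_p(1, nd, key = "other"), "stratum mismatch")
})

test_that("bh_fdr matches the hand-executed step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:300, 1))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("fit_null maximizes and flags unusable elements", {
  m <- rand_model(8, 91)
  aln <- simulate_element(m, 2000, seed = 12)
  f <- fit_null(m, aln)
  expect_gte(f$lnL, element_log_likelihood(m, aln) - 1e-8)
  gap <- setNames(rep(strrep("-", 10), 8), model_leaves(m))
  expect_null(fit_null(m, gap))
})

test_that("fit_alt is one-sided, nested, and errors on the full leaf set", {
  m <- rand_model(8, 92)
  expect_error(fit_alt(m, simulate_element(m, 50, seed = 1),
                       model_leaves(m)), "proper subset")
  # under the null, a large share of fits sit on the rho = 1 boundary
  n0 <- 0
  for (i in 1:40) {
    a <- accel_lrt(m, simulate_element(m, 50, seed = 3000 + i), "t1")
    expect_gte(a$lnL_alt, a$lnL_null - 1e-8)
    expect_gte(a$rho_hat, 1)
    if (a$rho_hat == 1) {
      expect_lt(a$lrt, 1e-8)
      n0 <- n0 + 1
    }
  }
  expect_gte(n0 / 40, 0.4)
})

test_that("planted subtree acceleration is recovered", {
  m <- rand_model(10, 93)
  rhos <- vapply(1:12, function(i) {
    aln <- simulate_element(m, 500, scale_config(1, 8, "t1"), seed = 400 + i)
    accel_lrt(m, aln, "t1")$rho_hat
  }, numeric(1))
  expect_gte(median(rhos), 5)
  expect_lte(median(rhos), 12)
})

test_that("build_null_distribution is deterministic, nonnegative, zero-heavy", {
  m <- rand_model(6, 94)
  nd <- build_null_distribution(m, model_leaves(m), 50L, "t1", 150, seed = 5)
  expect_s3_class(nd, "null_dist")
  expect_length(nd$lrt, 150L)
  expect_true(all(nd$lrt >= 0))
  expect_gte(mean(nd$lrt == 0), 0.25)
  nd2 <- build_null_distribution(m, model_leaves(m), 50L, "t1", 150, seed = 5)
  expect_identical(nd$lrt, nd2$lrt)
  expect_error(build_null_distribution(m, model_leaves(m), 50L, "t1", 50, 1),
               "n_sims")
  expect_error(build_null_distribution(m, setdiff(model_leaves(m), "t1"),
                                       50L, "t1", 100, 1), "no subtree species")
})

test_that("call_ars uses strict thresholds and nested calls", {
  res <- data.frame(element_id = paste0("e", 1:5), chrom = "chr1",
                    start = (0:4) * 50L, end = (1:5) * 50L,
                    q_fdr = c(0.05, 0.049, 0.2, 0.09, 0.007))
  called <- call_ars(res, 0.05)
  expect_setequal(called$element_id, c("e2", "e5"))
  expect_equal(called$element_id[1], "e5")  # sorted by q
  cand <- candidate_ars(res, 0.1)
  expect_true(all(called$element_id %in% cand$element_id))
  expect_setequal(cand$element_id, c("e1", "e2", "e4", "e5"))
})

test_that("test_elements is independent of tile processing order", {
  d <- small_scenario(3)
  model <- read_mod(file.path(d, "neutral.mod"))
  tiles <- split_elements(read_bed(file.path(d, "conserved.bed")), 50)[1:30, ]
  att <- attach_alignments(tiles, file.path(d, "aln.maf"), model, "human",
                           subtree = "wedSeal")
  r1 <- test_elements(model, att, "wedSeal", n_sims = 150, seed = 7)
  att_rev <- att
  att_rev$tiles <- rev(att$tiles)
  r2 <- test_elements(model, att_rev, "wedSeal", n_sims = 150, seed = 7)
  expect_equal(r2$results, r1$results)
  expect_true(all(r1$results$p_emp > 0 & r1$results$p_emp <= 1))
  expect_true(all(r1$results$lrt >= 0))
  expect_true(all(r1$results$lrt[r1$results$rho_hat == 1] < 1e-8))
})

test_that("derive_seed is deterministic, key-sensitive, and in range", {
  s1 <- derive_seed(1L, "a,b,c:50")
  expect_identical(s1, derive_seed(1L, "a,b,c:50"))
  expect_false(s1 == derive_seed(1L, "a,b,d:50"))
  expect_false(s1 == derive_seed(2L, "a,b,c:50"))
  for (m in c(0L, 1L, 1000L, 2147483646L))
    expect_true(derive_seed(m, "k") >= 1 && derive_seed(m, "k") < 2^31)
})
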