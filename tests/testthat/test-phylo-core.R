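test_that("parse_newick reads simple trees and reports malformations", {
  t2 <- parse_newick("(A:0.1,B:0.2);")
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(sum(t2$edge.length), 0.3)

  t3 <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);")
  expect_equal(ape::Ntip(t3), 3L)
  expect_equal(t3$Nnode, 2L)  # root plus one internal node

  expect_error(parse_newick("((A:0.1,B:0.2);"), "position")
  expect_error(parse_newick("(A:0.1,B:0.2)"), "position.*;|;.*position")
  expect_error(parse_newick("(A:0.1,A:0.2);"), "duplicate")
})

test_that("newick round-trip preserves topology and branch lengths", {
  for (seed in 1:100) {
    phy <- rand_tree(sample(3:12, 1), seed)
    back <- parse_newick(write_newick(phy))
    expect_true(ape::all.equal.phylo(phy, back, tolerance = 1e-9),
                info = paste("seed", seed))
  }
})

test_that("transition_matrix honors exp(Qt) structure", {
  m <- rand_rev(3)
  expect_equal(transition_matrix(m, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
  P <- transition_matrix(m, 1e3)
  for (i in 1:4) expect_equal(unname(P[i, ]), unname(m$pi), tolerance = 1e-6)
  expect_error(transition_matrix(m, -0.1), ">= 0")

  # JC69 closed form: diagonal (1 + 3 exp(-4t/3)) / 4
  jc <- jc_model()
  for (t in c(0.05, 0.3, 1.2)) {
    P <- transition_matrix(jc, t)
    expect_equal(unname(diag(P)), rep((1 + 3 * exp(-4 * t / 3)) / 4, 4),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  }

  # semigroup property P(a+b) = P(a) P(b)
  expect_equal(transition_matrix(m, 0.7),
               transition_matrix(m, 0.3) %*% transition_matrix(m, 0.4),
               tolerance = 1e-12)
})

test_that("rev_model validates inputs and satisfies detailed balance", {
  m <- rev_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))
  F <- m$pi * m$Q
  expect_equal(F, t(F), tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
  expect_error(rev_model(rep(1, 6), c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
  expect_error(rev_model(c(-1, 1, 1, 1, 1, 1), rep(0.25, 4)), ">= 0")
})

test_that("column likelihood matches direct cases", {
  one <- neutral_model(parse_newick("(A:0.1);"), rand_rev(5))
  expect_equal(column_log_likelihood(one, c(A = "G")),
               log(unname(one$subst$pi["G"])), tolerance = 1e-12)

  zl <- neutral_model(parse_newick("(A:0.0,B:0.0);"), rand_rev(6))
  expect_equal(column_log_likelihood(zl, c(A = "C", B = "C")),
               log(unname(zl$subst$pi["C"])), tolerance = 1e-9)
  expect_identical(column_log_likelihood(zl, c(A = "C", B = "T")), -Inf)

  m <- rand_model(4, 11)
  for (seed in 1:10) {
    col <- rand_column(m, seed, p_missing = 0.2)
    expect_equal(column_log_likelihood(m, col), brute_loglik(m, col),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
  expect_error(column_log_likelihood(m, c(zz = "A")), "unknown leaf")
  expect_error(column_log_likelihood(m, setNames(c("A", "X", "A", "A"),
                                                 model_leaves(m))),
               "non-nucleotide")
})

test_that("element likelihood is additive over columns and scale-consistent", {
  m <- rand_model(5, 21)
  aln <- simulate_element(m, 20, seed = 2)
  expect_identical(element_log_likelihood(m, setNames(rep("", 5),
                                                      model_leaves(m))), 0)
  expect_equal(element_log_likelihood(m, aln, scale_config(1.3, 1, "t1")),
               element_log_likelihood(m, aln, scale_config(1.3)),
               tolerance = 1e-12)
  percol <- sum(vapply(seq_len(20), function(i) {
    col <- vapply(aln, function(s) substr(s, i, i), "")
    column_log_likelihood(m, col)
  }, numeric(1)))
  expect_equal(element_log_likelihood(m, aln), percol, tolerance = 1e-9)
  bad <- aln; bad[1] <- substr(bad[1], 1, 10)
  expect_error(element_log_likelihood(m, bad), "ragged")
})

test_that("likelihood with rho on a subtree matches the oracle", {
  m <- rand_model(5, 31)
  sub <- arscan:::clade_tips(arscan:::tree_tables(m$tree),
                             ape::Ntip(m$tree) + 2L)
  skip_if(length(sub) >= length(model_leaves(m)))
  for (seed in 1:8) {
    col <- rand_column(m, 100 + seed)
    expect_equal(column_log_likelihood(m, col, scale_config(0.8, 5, sub)),
                 brute_loglik(m, col, 0.8, 5, sub), tolerance = 1e-10)
  }
})

test_that("simulate_element honors degenerate and deterministic contracts", {
  frozen <- neutral_model(parse_newick("((A:0,B:0):0,(C:0,D:0):0);"),
                          rand_rev(8))
  aln <- simulate_element(frozen, 30, seed = 4)
  expect_true(all(aln == aln[[1]]))
  m <- rand_model(6, 41)
  expect_identical(simulate_element(m, 50, seed = 9),
                   simulate_element(m, 50, seed = 9))
  expect_false(identical(simulate_element(m, 50, seed = 9),
                         simulate_element(m, 50, seed = 10)))
})

test_that("two distant leaves decouple to the equilibrium product", {
  m <- neutral_model(parse_newick("(A:40,B:40);"), rand_rev(12))
  cols <- arscan:::simulate_columns(m, 100000, seed = 13)
  tab <- table(factor(cols[1, ], levels = 0:3),
               factor(cols[2, ], levels = 0:3))
  expected <- outer(m$subst$pi, m$subst$pi) * sum(tab)
  chisq <- sum((tab - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.99, df = 15))
})

test_that("prune_to_species sums suppressed branches and preserves likelihoods", {
  m3 <- neutral_model(parse_newick("((A:0.1,B:0.1):0.05,C:0.2);"), jc_model())
  expect_identical(prune_to_species(m3, c("A", "B", "C")), m3)
  p <- prune_to_species(m3, c("A", "C"))
  expect_setequal(model_leaves(p), c("A", "C"))
  lens <- setNames(p$tree$edge.length, p$tree$tip.label[p$tree$edge[, 2]])
  expect_equal(lens[["A"]], 0.15)
  expect_equal(lens[["C"]], 0.2)
  expect_error(prune_to_species(m3, "nope"), "no requested species")

  for (seed in 1:10) {
    m <- rand_model(6, 500 + seed)
    keep <- sample(model_leaves(m), 4)
    pm <- prune_to_species(m, keep)
    col <- rand_column(m, seed)
    colm <- col; colm[setdiff(names(col), keep)] <- "-"
    expect_equal(element_log_likelihood(pm, col[keep]),
                 element_log_likelihood(m, colm),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  for (seed in 1:10) {
    m <- rand_model(5, 700 + seed)
    col <- rand_column(m, seed)
    base <- column_log_likelihood(m, col)
    # slide the root along its two child edges: transfer length d from one
    # root edge to the other; reversibility makes the likelihood invariant
    phy <- m$tree
    tt <- arscan:::tree_tables(phy)
    redge <- which(phy$edge[, 1] == tt$root)
    d <- min(phy$edge.length[redge[1]], 0.03)
    phy2 <- phy
    phy2$edge.length[redge[1]] <- phy$edge.length[redge[1]] - d
    phy2$edge.length[redge[2]] <- phy$edge.length[redge[2]] + d
    m2 <- neutral_model(phy2, m$subst)
    expect_equal(column_log_likelihood(m2, col), base, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("column likelihoods are normalized over all complete columns", {
  for (n in 3:4) {
    m <- rand_model(n, 900 + n)
    tips <- model_leaves(m)
    grid <- expand.grid(rep(list(c("A", "C", "G", "T")), n),
                        stringsAsFactors = FALSE)
    tot <- sum(apply(grid, 1, function(ch)
      exp(column_log_likelihood(m, setNames(unname(ch), tips)))))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("a single global scale is recovered from simulated data", {
  m <- rand_model(8, 77)
  for (s_true in c(0.6, 1, 1.7)) {
    aln <- simulate_element(m, 10000, scale_config(s = s_true), seed = 55)
    f <- fit_null(m, aln)
    expect_gt(f$s, s_true * 0.95)
    expect_lt(f$s, s_true * 1.05)
  }
})
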