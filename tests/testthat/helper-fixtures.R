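# Shared fixtures: random models, an exhaustive-enumeration likelihood
# oracle, and small on-disk format fixtures built in code.

rand_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length * runif(1, 0.5, 2)
  phy
}

rand_rev <- function(seed) {
  set.seed(seed)
  g <- rgamma(4, 2, 1)
  pi <- 0.6 * g / sum(g) + 0.1
  rev_model(exp(rnorm(6, 0, 0.4)), pi)
}

rand_model <- function(n, seed) neutral_model(rand_tree(n, seed), rand_rev(seed + 1000))

# Independent oracle: sum over all internal-state assignments of products of
# pi and P(t) entries. Only feasible for small trees; deliberately shares no
# code with the pruning kernel beyond transition_matrix.
brute_loglik <- function(model, column, s = 1, rho = 1, subtree = NULL) {
  tt <- arscan:::tree_tables(model$tree)
  mask <- if (is.null(subtree)) rep(FALSE, length(tt$parent))
          else subtree_edges(model$tree, subtree)
  Ps <- lapply(seq_along(tt$parent), function(e)
    transition_matrix(model$subst, tt$len[e] * s * if (mask[e]) rho else 1))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  nint <- tt$nnode - tt$ntip
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  tot <- 0
  leafstate <- vapply(tt$tips, function(nm) {
    ch <- column[[nm]]
    if (is.null(ch) || ch %in% c("-", "N", "?", ".")) 0L else code[[ch]]
  }, integer(1))
  for (r in seq_len(nrow(grid))) {
    st <- c(leafstate, grid[r, ])
    pr <- model$subst$pi[[st[tt$root]]]
    for (e in seq_along(tt$parent)) {
      cs <- st[tt$child[e]]
      # skipping an edge into a missing tip marginalizes it exactly,
      # because every row of P(t) sums to 1
      if (cs == 0L) next
      pr <- pr * Ps[[e]][st[tt$parent[e]], cs]
    }
    tot <- tot + pr
  }
  log(tot)
}

rand_column <- function(model, seed, p_missing = 0) {
  set.seed(seed)
  tips <- model_leaves(model)
  ch <- sample(c("A", "C", "G", "T"), length(tips), replace = TRUE)
  if (p_missing > 0) ch[runif(length(tips)) < p_missing] <- "-"
  setNames(ch, tips)
}

# small 2-block MAF fixture with a known reference layout
write_fixture_maf <- function(path, gapped = FALSE) {
  ref2 <- if (gapped) "AA--CCGG" else "AACCGGTT"
  sz2 <- if (gapped) 6 else 8
  lines <- c(
    "##maf version=1",
    "a score=1",
    "s human.chr1 10 8 + 1000 ACGTACGT",
    "s wedSeal 0 8 + 8 ACGTACGA",
    "s walrus 0 8 + 8 ACGTACGC",
    "",
    "a score=2",
    sprintf("s human.chr1 18 %d + 1000 %s", sz2, ref2),
    sprintf("s wedSeal 0 %d + %d %s", nchar(ref2), nchar(ref2),
            gsub("-", "T", ref2)),
    "")
  writeLines(lines, path)
  path
}

small_scenario <- function(seed = 1, n_tiles = 200) {
  d <- file.path(tempdir(), paste0("scen_", seed, "_", n_tiles))
  if (!file.exists(file.path(d, "truth.tsv"))) {
    cf <- scenario_config(n_tiles = n_tiles, n_windows = 4,
                          window_length = 60000L, n_genes = 12, n_list_a = 4,
                          n_list_b = 4, seed = seed)
    generate_scenario(cf, d)
  }
  d
}
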