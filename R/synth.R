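## Seeded generator for a complete miniature study: a placental-like tree
## with a designated target leaf ("wedSeal") and 2-leaf target subtree
## ("wedSeal" + "walrus"), a REV neutral model, a reference-anchored MAF
## alignment, conserved elements, gene models, enriched/neutral gene lists,
## and a per-tile truth table. Everything is deterministic per master seed.

#' Scenario configuration for the synthetic generator
#'
#' Defaults are the desk-scale stated world: 12 species, 2000 tiles of
#' 50 bp, 5% of tiles accelerated at rho = 8 on the target-leaf branch,
#' list-A genes capturing accelerated tiles at 5x the background rate, 5%
#' per-block missing-species rate.
#'
#' @param n_species number of leaves (>= 4).
#' @param target target leaf name.
#' @param subtree 2-leaf target subtree (target + sister).
#' @param ref reference species (always present in MAF blocks).
#' @param n_tiles exact number of 50-bp tiles the conserved elements split
#'   into.
#' @param tile_width tile width in bp.
#' @param n_windows number of MAF blocks (missingness is drawn per block).
#' @param window_length genomic length of each window, bp.
#' @param frac_accel fraction of tiles planted with acceleration.
#' @param rho_true planted subtree scale (>= 1).
#' @param branch_set `"leaf"` (accelerate the target leaf) or `"subtree"`.
#' @param multiplier list-A enrichment multiplier (>= 1).
#' @param missing_rate per-species per-block missing probability (the
#'   reference is never dropped).
#' @param n_genes number of gene models.
#' @param n_list_a,n_list_b sizes of the enriched and neutral gene lists.
#' @param gene_span_range min/max coding-span length, bp.
#' @param tree_depth mean root-to-tip length, expected substitutions/site.
#' @param seed master seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_species = 12L, target = "wedSeal",
                            subtree = c("wedSeal", "walrus"), ref = "human",
                            n_tiles = 2000L, tile_width = 50L,
                            n_windows = 10L, window_length = 200000L,
                            frac_accel = 0.05, rho_true = 8,
                            branch_set = c("leaf", "subtree"),
                            multiplier = 5, missing_rate = 0.05,
                            n_genes = 40L, n_list_a = 12L, n_list_b = 12L,
                            gene_span_range = c(3000L, 8000L),
                            tree_depth = 0.75, seed = 1L) {
  branch_set <- match.arg(branch_set)
  stopifnot(n_species >= 4, frac_accel >= 0, frac_accel <= 1, rho_true >= 1,
            multiplier >= 1, missing_rate >= 0, missing_rate < 1,
            n_list_a + n_list_b <= n_genes)
  structure(as.list(environment()), class = "scenario_config")
}

#' Random placental-like tree with a designated target cherry
#'
#' A coalescent-shaped random tree rescaled to the requested mean
#' root-to-tip depth. One cherry is renamed to the target subtree
#' (`wedSeal`, `walrus`) and its pendant branches are floored at a quarter
#' of the depth (emulating a seal/walrus split deep enough to carry
#' substitutions); one non-cherry leaf becomes the reference.
#'
#' @param n_species number of leaves (>= 4).
#' @param seed integer seed.
#' @param depth target mean root-to-tip length.
#' @param target,sister,ref leaf names to assign.
#' @return a `phylo` tree.
#' @export
make_tree <- function(n_species, seed, depth = 0.75, target = "wedSeal",
                      sister = "walrus", ref = "human") {
  stopifnot(n_species >= 4)
  set.seed(seed)
  phy <- ape::rcoal(n_species)
  d <- ape::node.depth.edgelength(phy)[seq_len(n_species)]
  phy$edge.length <- phy$edge.length * depth / mean(d)
  ## find a cherry: internal node with two leaf children
  kid <- split(phy$edge[, 2], phy$edge[, 1])
  cherries <- Filter(function(k) all(k <= n_species), kid)
  ch <- cherries[[1L]]
  labs <- paste0("sp", seq_len(n_species))
  labs[ch[1]] <- target
  labs[ch[2]] <- sister
  refcand <- setdiff(seq_len(n_species), ch)[1L]
  labs[refcand] <- ref
  phy$tip.label <- labs
  pend <- match(ch, phy$edge[, 2])
  phy$edge.length[pend] <- pmax(phy$edge.length[pend], depth / 4)
  validate_tree(phy)
}

## random REV model with frequencies bounded away from 0 and a
## transition/transversion bias, keeping likelihood surfaces well-behaved
random_rev_model <- function() {
  g <- rgamma(4, 2, 1)
  pi <- 0.6 * g / sum(g) + 0.1
  rates <- c(1, 4, 1, 1, 4, 1) * exp(rnorm(6, 0, 0.2))
  rev_model(rates, pi)
}

#' Generate a complete synthetic scenario on disk
#'
#' Writes `tree.nwk`, `neutral.mod`, `aln.maf`, `conserved.bed`,
#' `genes.bed12`, `lists/listA.txt`, `lists/listB.txt`, `truth.tsv`, and
#' `scenario.json` under `out_dir`. A fraction `frac_accel` of tiles is
#' simulated with `rho_true` on the configured branch set (list-A-adjacent
#' tiles at `multiplier` times the background rate), the rest from the
#' neutral model; species rows are dropped per block at `missing_rate`.
#'
#' @param config a `scenario_config`.
#' @param out_dir output directory (created if needed).
#' @return invisible list with `files` (named paths), `truth` (data.frame),
#'   `model`, and `config`.
#' @export
generate_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  dir.create(file.path(out_dir, "lists"), recursive = TRUE, showWarnings = FALSE)
  set.seed(cf$seed)

  tree <- make_tree(cf$n_species, seed = derive_seed(cf$seed, "tree"),
                    depth = cf$tree_depth, target = cf$target,
                    sister = cf$subtree[cf$subtree != cf$target][1], ref = cf$ref)
  set.seed(derive_seed(cf$seed, "model"))
  model <- neutral_model(tree, random_rev_model())
  species <- model_leaves(model)
  branch_leaves <- if (cf$branch_set == "leaf") cf$target else cf$subtree

  ## --- conserved elements: runs of 2..6 tiles summing to exactly n_tiles
  set.seed(derive_seed(cf$seed, "layout"))
  counts <- integer(0)
  while (sum(counts) < cf$n_tiles)
    counts <- c(counts, sample(2:6, 1L))
  counts[length(counts)] <- counts[length(counts)] - (sum(counts) - cf$n_tiles)
  counts <- counts[counts > 0L]
  widths <- counts * cf$tile_width
  n_elem <- length(counts)
  win_of <- rep(seq_len(cf$n_windows), length.out = n_elem)
  genome_length <- cf$n_windows * cf$window_length
  el_start <- integer(n_elem)
  for (w in seq_len(cf$n_windows)) {
    ii <- which(win_of == w)
    gaps <- sample(100:1500, length(ii), replace = TRUE)
    pos <- (w - 1L) * cf$window_length + cumsum(gaps + c(0L, widths[ii][-length(ii)]))
    if (max(pos + widths[ii]) >= w * cf$window_length)
      stop("infeasible element placement: window ", w, " overflows; ",
           "increase window_length or reduce n_tiles", call. = FALSE)
    el_start[ii] <- pos
  }
  elements <- data.frame(chrom = "chr1", start = el_start,
                         end = el_start + widths,
                         name = paste0("ce", seq_len(n_elem)),
                         stringsAsFactors = FALSE)
  el_win <- setNames(win_of, elements$name)    # window by element name
  elements <- elements[order(elements$start), , drop = FALSE]
  tiles <- split_elements(elements, cf$tile_width)

  ## --- gene models anchored to elements; list A and list B anchors kept in
  ## disjoint window halves so the lists occupy distinct neighborhoods
  set.seed(derive_seed(cf$seed, "genes"))
  spans <- sample(cf$gene_span_range[1]:cf$gene_span_range[2], cf$n_genes,
                  replace = TRUE)
  half_a <- which(win_of <= cf$n_windows / 2)
  half_b <- which(win_of > cf$n_windows / 2)
  if (length(half_a) < cf$n_list_a || length(half_b) < cf$n_list_b)
    stop("infeasible gene placement: too few elements per window half",
         call. = FALSE)
  anchors <- c(sample(half_a, cf$n_list_a),
               sample(half_b, cf$n_list_b),
               sample(seq_len(n_elem), cf$n_genes - cf$n_list_a - cf$n_list_b))
  g_start <- pmax(0L, pmin(genome_length - spans - 1L,
                           el_start[anchors] + sample(-5000:5000, cf$n_genes,
                                                      replace = TRUE)))
  genes <- data.frame(gene_id = paste0("g", seq_len(cf$n_genes)),
                      chrom = "chr1", start = g_start, end = g_start + spans,
                      strand = sample(c("+", "-"), cf$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  list_a <- genes$gene_id[seq_len(cf$n_list_a)]
  list_b <- genes$gene_id[cf$n_list_a + seq_len(cf$n_list_b)]

  ## --- plant acceleration: list-A-adjacent tiles at multiplier x base rate
  set.seed(derive_seed(cf$seed, "accel"))
  asn <- map_elements_to_genes(tiles, genes)
  near_a <- unique(asn$element_id[asn$gene_id %in% list_a])
  is_near_a <- tiles$element_id %in% near_a
  n <- nrow(tiles)
  nA <- sum(is_near_a)
  base <- cf$frac_accel * n / (cf$multiplier * nA + (n - nA))
  p_accel <- ifelse(is_near_a, pmin(1, cf$multiplier * base), base)
  accel <- runif(n) < p_accel

  ## --- per-block missingness (reference never dropped)
  set.seed(derive_seed(cf$seed, "missing"))
  droppable <- setdiff(species, cf$ref)
  present <- matrix(TRUE, nrow = cf$n_windows, ncol = length(species),
                    dimnames = list(NULL, species))
  present[, droppable] <- matrix(runif(cf$n_windows * length(droppable)) >=
                                   cf$missing_rate, nrow = cf$n_windows)

  ## --- simulate alignments per window block and patch accelerated tiles
  set.seed(derive_seed(cf$seed, "sequence"))
  blocks <- vector("list", cf$n_windows)
  for (w in seq_len(cf$n_windows)) {
    tw <- tiles[tiles$start >= (w - 1L) * cf$window_length &
                  tiles$end <= w * cf$window_length, , drop = FALSE]
    if (!nrow(tw)) next
    b_start <- max((w - 1L) * cf$window_length, min(tw$start) - 100L)
    b_end <- min(w * cf$window_length, max(tw$end) + 100L)
    cols <- simulate_columns(model, b_end - b_start)
    acc_ids <- tw$element_id[accel[match(tw$element_id, tiles$element_id)]]
    for (id in acc_ids) {
      t <- tw[tw$element_id == id, ]
      patch <- simulate_columns(model, t$end - t$start,
                                scale_config(1, cf$rho_true, branch_leaves))
      cols[, (t$start - b_start + 1L):(t$end - b_start)] <- patch
    }
    keep <- species[present[w, ]]
    rows <- do.call(rbind, lapply(keep, function(sp) {
      txt <- paste(NUC[cols[sp, ] + 1L], collapse = "")
      data.frame(src = if (sp == cf$ref) paste0(sp, ".chr1") else sp,
                 start = if (sp == cf$ref) b_start else 0,
                 size = b_end - b_start, strand = "+",
                 srcSize = if (sp == cf$ref) genome_length else b_end - b_start,
                 text = txt, stringsAsFactors = FALSE)
    }))
    blocks[[w]] <- maf_block(rows)
  }
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]

  ## --- truth table
  tile_genes <- vapply(tiles$element_id, function(id) {
    paste(sort(unique(asn$gene_id[asn$element_id == id])), collapse = ",")
  }, "")
  win <- unname(el_win[tiles$parent_id])
  truth <- data.frame(
    element_id = tiles$element_id, chrom = tiles$chrom, start = tiles$start,
    end = tiles$end, accelerated = as.integer(accel),
    rho = ifelse(accel, cf$rho_true, 1),
    branch_set = cf$branch_set,
    genes = tile_genes,
    in_list_a = as.integer(is_near_a),
    in_list_b = as.integer(tiles$element_id %in%
                             unique(asn$element_id[asn$gene_id %in% list_b])),
    species_present = vapply(win, function(w)
      paste(species[present[w, ]], collapse = ","), ""),
    stringsAsFactors = FALSE)

  ## --- emit files
  files <- c(tree = file.path(out_dir, "tree.nwk"),
             mod = file.path(out_dir, "neutral.mod"),
             maf = file.path(out_dir, "aln.maf"),
             bed = file.path(out_dir, "conserved.bed"),
             genes = file.path(out_dir, "genes.bed12"),
             list_a = file.path(out_dir, "lists", "listA.txt"),
             list_b = file.path(out_dir, "lists", "listB.txt"),
             truth = file.path(out_dir, "truth.tsv"),
             config = file.path(out_dir, "scenario.json"))
  writeLines(write_newick(tree), files["tree"])
  write_mod(model, files["mod"])
  write_maf(blocks, files["maf"])
  write_bed(elements, files["bed"])
  write_bed12_genes(genes, files["genes"])
  writeLines(list_a, files["list_a"])
  writeLines(list_b, files["list_b"])
  write.table(truth, files["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config)[!vapply(unclass(config), is.function, TRUE)],
                       files["config"], auto_unbox = TRUE, digits = NA)
  invisible(list(files = files, truth = truth, model = model, config = config))
}

## BED12 with the coding span as both the record span and the thick span
write_bed12_genes <- function(genes, file) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d\t0",
                     genes$chrom, genes$start, genes$end, genes$gene_id,
                     genes$strand, genes$start, genes$end,
                     genes$end - genes$start), file)
  invisible(file)
}

#' Read a scenario configuration written by [generate_scenario()]
#' @param file path to `scenario.json`.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(scenario_config, x[setdiff(names(x), character(0))])
}
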