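## The neutral model couples a tree (ape phylo) with a reversible
## substitution model; it is the null process for the acceleration test and
## the generator for parametric-bootstrap simulations.

#' Construct a neutral phylogenetic model
#'
#' @param tree a `phylo` object with branch lengths (validated).
#' @param subst a `subst_model`.
#' @return an object of class `neutral_model` with cached postorder tables.
#' @export
neutral_model <- function(tree, subst) {
  validate_tree(tree)
  stopifnot(inherits(subst, "subst_model"))
  structure(list(tree = tree, subst = subst, tables = tree_tables(tree)),
            class = "neutral_model")
}

#' @export
print.neutral_model <- function(x, ...) {
  cat("Neutral model:", length(x$tree$tip.label), "leaves, total branch length",
      format(sum(x$tree$edge.length)), "\n")
  print(x$subst)
  invisible(x)
}

#' Leaf names of a neutral model
#' @param model a `neutral_model`.
#' @return character vector of leaf names.
#' @export
model_leaves <- function(model) model$tables$tips

#' Branch scaling configuration for the acceleration test
#'
#' A global scale `s` multiplies every branch; a subtree scale `rho >= 1`
#' additionally multiplies the branches of the clade spanned by `subtree`
#' (its internal edges plus its stem; a single leaf scales just its pendant
#' branch).
#'
#' @param s global scale, in `[1e-3, 100]`.
#' @param rho subtree scale, in `[1, 100]`.
#' @param subtree character vector of leaf names, or NULL for no subtree.
#' @return an object of class `scale_config`.
#' @export
scale_config <- function(s = 1, rho = 1, subtree = NULL) {
  if (!is.finite(s) || s < 1e-3 || s > 100)
    stop("global scale s must lie in [1e-3, 100]", call. = FALSE)
  if (!is.finite(rho) || rho < 1 || rho > 100)
    stop("subtree scale rho must lie in [1, 100]", call. = FALSE)
  if (rho > 1 && is.null(subtree))
    stop("rho > 1 requires a subtree", call. = FALSE)
  structure(list(s = s, rho = rho, subtree = subtree), class = "scale_config")
}

#' Restrict a neutral model to a subset of species
#'
#' Leaves outside `present` are removed and degree-2 internal nodes are
#' suppressed with their branch lengths summed; the substitution model is
#' unchanged. Column likelihoods on the pruned model equal likelihoods on
#' the full model with the removed leaves marked missing.
#'
#' @param model a `neutral_model`.
#' @param present nonempty character vector of leaf names to keep.
#' @return a `neutral_model` on the reduced leaf set.
#' @export
prune_to_species <- function(model, present) {
  tips <- model_leaves(model)
  present <- intersect(tips, present)
  if (length(present) == 0L)
    stop("no requested species present in the model", call. = FALSE)
  if (setequal(present, tips)) return(model)
  if (length(present) == 1L)
    stop("cannot prune a tree to a single leaf", call. = FALSE)
  neutral_model(ape::keep.tip(model$tree, present), model$subst)
}

#' Simulate an aligned element under the (scaled) model
#'
#' Root states are drawn from the equilibrium frequencies and evolved down
#' each branch with the transition matrices of the scaled branch lengths.
#' Deterministic given `seed`.
#'
#' @param model a `neutral_model`.
#' @param L number of sites (>= 1 unless 0 is explicitly wanted).
#' @param scales a `scale_config` (default: neutral, s = 1, rho = 1).
#' @param seed optional integer seed.
#' @return named character vector of leaf sequences, each of length `L`.
#' @export
simulate_element <- function(model, L, scales = scale_config(), seed = NULL) {
  m <- simulate_columns(model, L, scales, seed)
  apply(m, 1L, function(row) paste(NUC[row + 1L], collapse = ""))
}

## integer-coded simulation (rows = leaves in tables order, codes 0..3)
simulate_columns <- function(model, L, scales = scale_config(), seed = NULL) {
  stopifnot(inherits(scales, "scale_config"))
  if (!is.numeric(L) || L < 0) stop("invalid L", call. = FALSE)
  L <- as.integer(L)
  if (!is.null(seed)) set.seed(seed)
  tt <- model$tables
  sub <- scaled_edge_mask(model, scales)
  states <- matrix(0L, nrow = tt$nnode, ncol = L)
  states[tt$root, ] <- sample.int(4L, L, replace = TRUE, prob = model$subst$pi)
  ord <- rev(seq_along(tt$parent))        # preorder: parents before children
  for (e in ord) {
    t_eff <- tt$len[e] * scales$s * if (sub[e]) scales$rho else 1
    P <- transition_matrix(model$subst, t_eff)
    ps <- states[tt$parent[e], ]
    cs <- integer(L)
    for (b in 1:4) {
      idx <- which(ps == b)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
    states[tt$child[e], ] <- cs
  }
  out <- states[seq_len(tt$ntip), , drop = FALSE] - 1L
  rownames(out) <- tt$tips
  out
}

## logical mask over postorder edges for the rho-scaled subtree
scaled_edge_mask <- function(model, scales) {
  if (is.null(scales$subtree))
    return(rep(FALSE, length(model$tables$parent)))
  subtree_edges(model$tree, scales$subtree)
}
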