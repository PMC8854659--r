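## Tree handling is built on ape's "phylo" container; arscan adds strict
## validation, position-aware newick errors, and the edge tables used by the
## pruning likelihood.

#' Parse a newick string into a validated phylo tree
#'
#' Wraps [ape::read.tree()] with a pre-parse syntax scan that reports the
#' character position of common malformations, and post-parse validation of
#' the invariants the likelihood machinery relies on: unique leaf names, all
#' branch lengths present and non-negative, a single root.
#'
#' @param text a newick string (must end in `;`). Branch lengths required on
#'   all edges except (optionally) the root.
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);")
#' sum(tr$edge.length)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  scan_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("newick parse error: unparseable string", call. = FALSE)
  validate_tree(phy)
  phy
}

## cheap linear scan giving 1-based character positions for structural errors
scan_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at position %d: unbalanced ')'", i), call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error at position %d: %d unclosed '('", length(chars), depth),
         call. = FALSE)
  semi <- which(chars == ";")
  if (length(semi) == 0L)
    stop(sprintf("newick parse error at position %d: missing terminal ';'", length(chars)),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate the invariants of a phylo tree used by arscan
#'
#' @param phy a `phylo` object.
#' @param require_lengths require branch lengths on every edge (default TRUE).
#' @return `phy`, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(phy, require_lengths = TRUE) {
  if (!inherits(phy, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (require_lengths) {
    if (is.null(phy$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
      stop("branch lengths must all be present and >= 0", call. = FALSE)
  }
  ## connected single-rooted: every non-root node has exactly one parent
  n_node <- ape::Ntip(phy) + phy$Nnode
  kids <- tabulate(phy$edge[, 2], nbins = n_node)
  roots <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(unique(roots)) != 1L)
    stop("tree is not singly rooted", call. = FALSE)
  if (any(kids[-unique(roots)] != 1L))
    stop("tree is not a tree: node with parent count != 1", call. = FALSE)
  invisible(phy)
}

#' Write a phylo tree as a newick string
#'
#' @param phy a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return newick string (with terminal `;`).
#' @export
write_newick <- function(phy, digits = 12) {
  ape::write.tree(phy, digits = digits)
}

## Postorder edge tables consumed by the C++ pruning kernel.
## Nodes use ape numbering: tips 1..n, root n+1, internals beyond.
tree_tables <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(po)
  list(
    parent = po$edge[, 1L],
    child  = po$edge[, 2L],
    len    = po$edge.length,
    ntip   = ntip,
    nnode  = ntip + po$Nnode,
    root   = ntip + 1L,
    tips   = po$tip.label
  )
}

#' Identify the edge set scaled by the subtree rate parameter
#'
#' The tested branch set is the clade spanned by `leaves`: every edge inside
#' the clade plus the stem edge leading into its most recent common ancestor
#' (for a single leaf this is just its pendant branch). `leaves` must be
#' exactly the leaf set of a clade of `phy`.
#'
#' @param phy a `phylo` object.
#' @param leaves character vector of leaf names (proper subset of tips).
#' @return logical vector over the rows of `tree_tables(phy)$parent` marking
#'   scaled edges, with attribute `"label"` of `"target-leaf"` or
#'   `"target-subtree"`.
#' @export
subtree_edges <- function(phy, leaves) {
  tt <- tree_tables(phy)
  tips <- tt$tips
  unknown <- setdiff(leaves, tips)
  if (length(unknown))
    stop("unknown leaf name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(leaves) == 0L) stop("empty subtree leaf set", call. = FALSE)
  if (length(leaves) >= length(tips))
    stop("subtree must be a proper subset of leaves (scales unidentifiable otherwise)",
         call. = FALSE)
  if (length(leaves) == 1L) {
    node <- match(leaves, tips)
  } else {
    node <- ape::getMRCA(phy, leaves)
    below <- clade_tips(tt, node)
    if (!setequal(below, leaves))
      stop("leaf set is not a clade; clade of their MRCA is {",
           paste(sort(below), collapse = ","), "}", call. = FALSE)
  }
  ## edges whose child lies within the clade rooted at `node` (inclusive)
  in_clade <- rep(FALSE, tt$nnode)
  in_clade[node] <- TRUE
  ## postorder lists children before parents, so sweep edges in reverse
  ## (parents before children) marking descendants of `node`
  for (i in rev(seq_along(tt$parent))) {
    if (in_clade[tt$parent[i]]) in_clade[tt$child[i]] <- TRUE
  }
  sel <- in_clade[tt$child]
  attr(sel, "label") <- if (length(leaves) == 1L) "target-leaf" else "target-subtree"
  sel
}

## tip labels beneath an internal node (inclusive of tips)
clade_tips <- function(tt, node) {
  in_clade <- rep(FALSE, tt$nnode)
  in_clade[node] <- TRUE
  for (i in rev(seq_along(tt$parent))) {
    if (in_clade[tt$parent[i]]) in_clade[tt$child[i]] <- TRUE
  }
  tt$tips[which(in_clade[seq_len(tt$ntip)])]
}
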