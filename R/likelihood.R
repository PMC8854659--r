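## Pruning likelihoods. The kernel (C++) consumes postorder edge tables, the
## eigendecomposition of the rate matrix, and an integer-coded alignment;
## missing leaves and gap/N characters contribute all-ones partials.

MISSING_CODES <- c("-", "N", "n", "?", ".")

## encode per-leaf sequences into an integer matrix (0..3, -1 missing) whose
## rows follow the model's leaf order; absent species become all-missing rows
encode_alignment <- function(model, aln) {
  tips <- model_leaves(model)
  if (is.matrix(aln) && is.integer(aln)) {        # already encoded
    stopifnot(!is.null(rownames(aln)))
    unknown <- setdiff(rownames(aln), tips)
    if (length(unknown))
      stop("unknown leaf name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    L <- ncol(aln)
    out <- matrix(-1L, nrow = length(tips), ncol = L, dimnames = list(tips, NULL))
    out[rownames(aln), ] <- aln
    return(out)
  }
  stopifnot(is.character(aln), !is.null(names(aln)))
  unknown <- setdiff(names(aln), tips)
  if (length(unknown))
    stop("unknown leaf name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  lens <- nchar(aln)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ","),
         call. = FALSE)
  L <- if (length(aln)) lens[[1]] else 0L
  out <- matrix(-1L, nrow = length(tips), ncol = L, dimnames = list(tips, NULL))
  if (L == 0L) return(out)
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  for (mc in MISSING_CODES) lut[utf8ToInt(mc)] <- -1L
  for (nm in names(aln)) {
    codes <- lut[utf8ToInt(aln[[nm]])]
    if (anyNA(codes)) {
      bad <- unique(strsplit(aln[[nm]], "")[[1]][is.na(codes)])
      stop("non-nucleotide symbol(s) in sequence for ", nm, ": ",
           paste(bad, collapse = ","), call. = FALSE)
    }
    out[nm, ] <- codes
  }
  out
}

## closure over precomputed tables/encoding: loglik(s, rho)
make_loglik_fn <- function(model, enc, sub_mask) {
  tt <- model$tables
  e <- model$subst$eig
  pi <- unname(model$subst$pi)
  tip_node <- match(rownames(enc), tt$tips)
  force(sub_mask)
  function(s, rho) {
    cpp_element_loglik(tt$parent, tt$child, tt$len, sub_mask, s, rho,
                       e$U, e$lam, e$Uinv, pi, tt$nnode, tt$root,
                       enc, tip_node)$total
  }
}

#' Log-likelihood of one alignment column
#'
#' Felsenstein pruning over the tree with every branch length multiplied by
#' `scales$s` (and additionally by `scales$rho` on the subtree edges).
#' Gap/N characters and absent species contribute all-ones partial vectors.
#'
#' @param model a `neutral_model`.
#' @param column named character vector mapping leaf names to single
#'   characters in `A,C,G,T` or a missing code (`-`, `N`, `?`, `.`).
#' @param scales a `scale_config`.
#' @return the column log-probability (<= 0; `-Inf` for impossible columns).
#' @export
column_log_likelihood <- function(model, column, scales = scale_config()) {
  element_log_likelihood(model, column, scales)
}

#' Log-likelihood of an aligned element (independent sites)
#'
#' @param model a `neutral_model`.
#' @param aln named character vector of equal-length leaf sequences (or an
#'   integer-coded matrix from the simulator); species absent from `aln` are
#'   treated as missing.
#' @param scales a `scale_config`.
#' @return sum of per-column log-likelihoods (0 for a zero-length element).
#' @export
element_log_likelihood <- function(model, aln, scales = scale_config()) {
  stopifnot(inherits(model, "neutral_model"), inherits(scales, "scale_config"))
  enc <- encode_alignment(model, aln)
  if (ncol(enc) == 0L) return(0)
  sub <- scaled_edge_mask(model, scales)
  if (length(model_leaves(model)) == 1L) {         # degenerate one-leaf model
    codes <- enc[1, ]
    return(sum(log(model$subst$pi)[codes[codes >= 0L] + 1L]))
  }
  make_loglik_fn(model, enc, sub)(scales$s, scales$rho)
}
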