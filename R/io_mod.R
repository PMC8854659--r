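## Reader/writer for the phast .mod dialect: ALPHABET, SUBST_MOD,
## BACKGROUND (4 reals), RATE_MAT (4 rows of 4 reals), TREE (newick).

#' Read a neutral model from a phast-style .mod file
#'
#' Requires a REV (or JC69) substitution model; BACKGROUND is accepted and
#' renormalized when within 1e-6 of summing to 1; the rate matrix is
#' re-normalized to one expected substitution per site.
#'
#' @param file path to the .mod file.
#' @return a `neutral_model`.
#' @export
read_mod <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keyed <- grep("^[A-Z_]+:", lines)
  fields <- list()
  for (i in seq_along(keyed)) {
    ln <- lines[keyed[i]]
    key <- sub(":.*$", "", ln)
    val <- sub("^[A-Z_]+:\\s*", "", ln)
    upto <- if (i < length(keyed)) keyed[i + 1] - 1L else length(lines)
    extra <- if (upto > keyed[i]) lines[(keyed[i] + 1L):upto] else character(0)
    fields[[key]] <- c(val, extra)
  }
  for (req in c("RATE_MAT", "TREE", "BACKGROUND"))
    if (is.null(fields[[req]]))
      stop(".mod format error: missing key ", req, call. = FALSE)
  sm <- trimws(fields[["SUBST_MOD"]][1])
  if (length(sm) && nzchar(sm) && !sm %in% c("REV", "JC69"))
    stop("unsupported substitution model: ", sm, " (REV or JC69 required)",
         call. = FALSE)
  bg <- scan(text = fields[["BACKGROUND"]][1], quiet = TRUE)
  if (length(bg) != 4L)
    stop(".mod format error: BACKGROUND must have 4 frequencies", call. = FALSE)
  if (abs(sum(bg) - 1) > 1e-6)
    stop(".mod format error: BACKGROUND sums to ", sum(bg), call. = FALSE)
  bg <- bg / sum(bg)
  matlines <- fields[["RATE_MAT"]]
  matlines <- matlines[nzchar(trimws(matlines))]
  if (length(matlines) < 4L)
    stop(".mod format error: RATE_MAT must have 4 rows", call. = FALSE)
  Q <- do.call(rbind, lapply(matlines[1:4], function(l) scan(text = l, quiet = TRUE)))
  if (!all(dim(Q) == c(4, 4)))
    stop(".mod format error: RATE_MAT must be 4x4", call. = FALSE)
  tree <- parse_newick(trimws(fields[["TREE"]][1]))
  neutral_model(tree, subst_model_from_q(Q, bg, normalize = TRUE))
}

#' Write a neutral model in the phast .mod dialect
#'
#' @param model a `neutral_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mod <- function(model, file) {
  stopifnot(inherits(model, "neutral_model"))
  q <- model$subst$Q
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "ALPHABET: A C G T",
    "ORDER: 0",
    "SUBST_MOD: REV",
    paste("BACKGROUND:", paste(sprintf("%.10f", model$subst$pi), collapse = " ")),
    "RATE_MAT:",
    apply(q, 1, function(r) paste(" ", paste(sprintf("%.10f", r), collapse = " "))),
    paste("TREE:", write_newick(model$tree))
  ), con)
  invisible(file)
}
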