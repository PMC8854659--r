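## Simulation-based null distributions of the acceleration LRT. One null is
## built per stratum -- a (species-presence set, element length) pair --
## because equal-length elements with the same species present are
## exchangeable under the neutral model, which makes a single large
## simulation reusable across all elements of the stratum.

#' Stratum key for null-distribution sharing
#' @param species character vector of species present.
#' @param L element length (reference bp).
#' @return a canonical string key.
#' @export
stratum_key <- function(species, L) {
  paste0(paste(sort(species), collapse = ","), ":", as.integer(L))
}

#' Derive a deterministic child seed from a master seed and a string key
#'
#' A small polynomial hash of the key mixed with the master seed; stays in
#' `[1, 2^31 - 2]` so it is a valid R integer seed. Used so per-stratum
#' simulation streams do not depend on processing order.
#'
#' @param master integer master seed.
#' @param key character key.
#' @return integer seed.
#' @export
derive_seed <- function(master, key) {
  b <- utf8ToInt(key)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  h <- (h + (as.double(master) %% 2147483647) * 48271) %% 2147483647
  as.integer(h) + 1L
}

#' Build the simulated null LRT distribution for one stratum
#'
#' Simulates `n_sims` elements of the stratum's length from the neutral
#' model (s = 1, rho = 1) restricted to the stratum's species, refits both
#' hypotheses on each, and stores the sorted LRT statistics.
#'
#' @param model the full `neutral_model`.
#' @param species species present in the stratum (must include at least one
#'   subtree member).
#' @param L element length in sites.
#' @param subtree tested leaf set (intersected with `species`).
#' @param n_sims number of simulations (>= 100).
#' @param seed integer seed for the simulation stream.
#' @return object of class `null_dist`: `key`, `lrt` (sorted), `n_sims`.
#' @export
build_null_distribution <- function(model, species, L, subtree, n_sims, seed) {
  if (n_sims < 100) stop("n_sims must be >= 100", call. = FALSE)
  L <- as.integer(L)
  sub <- intersect(subtree, species)
  if (length(sub) == 0L)
    stop("no subtree species present in stratum", call. = FALSE)
  pm <- prune_to_species(model, species)
  mask <- subtree_edges(pm$tree, sub)
  cols <- simulate_columns(pm, L * n_sims, seed = seed)
  tt <- pm$tables
  e <- pm$subst$eig
  lrt <- cpp_null_lrts(tt$parent, tt$child, tt$len, mask, e$U, e$lam, e$Uinv,
                       unname(pm$subst$pi), tt$nnode, tt$root, cols,
                       match(rownames(cols), tt$tips), L, as.integer(n_sims))
  structure(list(key = stratum_key(species, L), lrt = sort(lrt),
                 n_sims = n_sims),
            class = "null_dist")
}

#' Smoothed empirical p-value of an observed LRT
#'
#' `p = (1 + #simulated LRT >= observed) / (n_sims + 1)`; never exactly 0.
#'
#' @param obs_lrt observed LRT statistic(s); vectorized.
#' @param null a `null_dist`.
#' @param key optional stratum key of the element; must match the null's.
#' @return empirical p-value(s) in `(0, 1]`.
#' @export
empirical_p <- function(obs_lrt, null, key = NULL) {
  stopifnot(inherits(null, "null_dist"))
  if (!is.null(key) && !identical(key, null$key))
    stop("stratum mismatch: element key ", key, " vs null key ", null$key,
         call. = FALSE)
  ## sorted null: count of sims >= obs via binary search on strict lower bound
  n_lt <- findInterval(obs_lrt, null$lrt, left.open = TRUE)  # sims < obs
  (1 + null$n_sims - n_lt) / (null$n_sims + 1)
}
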