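## Reversible (REV/GTR) nucleotide substitution models over {A,C,G,T}.
## The rate matrix is normalized to one expected substitution per site so
## branch lengths keep their units; transition probabilities come from the
## eigendecomposition of the pi-symmetrized rate matrix.

NUC <- c("A", "C", "G", "T")

#' Construct a reversible nucleotide substitution model
#'
#' @param rates six exchangeability parameters in the order AC, AG, AT, CG,
#'   CT, GT (all > 0); the rate matrix is `Q[i,j] = rates[ij] * pi[j]`.
#' @param pi equilibrium base frequencies (A, C, G, T); nonnegative, summing
#'   to 1 within 1e-6 (renormalized).
#' @param normalize rescale so the expected substitution rate
#'   `-sum(pi * diag(Q))` is 1 (default TRUE).
#' @return an object of class `subst_model` with elements `pi`, `Q`,
#'   `rates`, and a cached eigendecomposition.
#' @examples
#' m <- rev_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))
#' transition_matrix(m, 0.1)
#' @export
rev_model <- function(rates, pi, normalize = TRUE) {
  stopifnot(length(rates) == 6L, length(pi) == 4L)
  if (any(rates < 0)) stop("exchangeabilities must be >= 0", call. = FALSE)
  if (any(pi < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-6)
    stop("frequencies must sum to 1 within 1e-6 (got ", sum(pi), ")", call. = FALSE)
  pi <- pi / sum(pi)
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  ## order AC, AG, AT, CG, CT, GT
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  R[idx] <- rates
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  subst_model_from_q(Q, pi, rates = rates, normalize = normalize)
}

#' Jukes-Cantor model (uniform frequencies and exchangeabilities)
#' @return a `subst_model`.
#' @export
jc_model <- function() rev_model(rep(1, 6), rep(0.25, 4))

## internal constructor; Q rows must sum to 0 and satisfy detailed balance
subst_model_from_q <- function(Q, pi, rates = NULL, normalize = TRUE) {
  dimnames(Q) <- list(NUC, NUC)
  offd <- Q[row(Q) != col(Q)]
  if (any(offd < -1e-9)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  Q[Q < 0 & row(Q) != col(Q)] <- 0
  if (max(abs(rowSums(Q))) > 1e-5)
    stop("rate matrix rows must sum to 0", call. = FALSE)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)            # re-center diagonals (file precision)
  F <- pi * Q                       # detailed balance: pi_i Q_ij symmetric
  if (max(abs(F - t(F))) > 1e-5 * max(abs(F)))
    stop("rate matrix violates detailed balance for the given frequencies",
         call. = FALSE)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix (zero total rate)", call. = FALSE)
  if (normalize) {
    Q <- Q / rate
    if (!is.null(rates)) rates <- rates / rate
  }
  sp <- sqrt(pi)
  B <- (Q * rep(sp, 4) / rep(sp, each = 4) +
        t(Q * rep(sp, 4) / rep(sp, each = 4))) / 2  # symmetrized, exact for REV
  e <- eigen(B, symmetric = TRUE)
  structure(
    list(
      pi = setNames(pi, NUC), Q = Q, rates = rates,
      eig = list(
        U    = e$vectors / sp,              # rows scaled by 1/sqrt(pi)
        lam  = e$values,
        Uinv = t(e$vectors * sp)            # columns scaled by sqrt(pi)
      )
    ),
    class = "subst_model"
  )
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param subst a `subst_model`.
#' @param t branch length in expected substitutions/site, `t >= 0`.
#' @return 4x4 row-stochastic matrix (rows sum to 1 within 1e-12).
#' @export
transition_matrix <- function(subst, t) {
  stopifnot(inherits(subst, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be >= 0", call. = FALSE)
  if (t == 0) return(diag(4) |> `dimnames<-`(list(NUC, NUC)))
  e <- subst$eig
  P <- e$U %*% (exp(e$lam * t) * e$Uinv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Reversible nucleotide substitution model\n")
  cat("  pi:", paste(sprintf("%s=%.4f", NUC, x$pi), collapse = " "), "\n")
  cat("  expected rate:", format(-sum(x$pi * diag(x$Q))), "subs/site\n")
  invisible(x)
}
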