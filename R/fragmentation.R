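#' Inheritance weights of vertical transmission through a fragment
#'
#' Non-negative propensities `f1`, `f2`, `f3` with which normal, defective
#' and cancerous cells of the parent end up in a detached fragment. Mobile
#' tumour cells (as in *Pelmatohydra robusta* budding) correspond to `f3`
#' close to `f1`; tumour-free budding zones to `f3` near 0. Binary fission
#' with equitable cell distribution forces `f1 == f2 == f3`.
#'
#' @param f1,f2,f3 transmission propensities, `>= 0`, not all zero.
#' @return An `inheritance_weights` numeric vector of length 3.
#' @examples
#' inheritance_weights(5, 1, 0.5)   # purging-prone asymmetric fragmentation
#' inheritance_weights(1, 1, 1)     # binary fission
#' @export
inheritance_weights <- function(f1, f2, f3) {
  f <- c(f1 = f1, f2 = f2, f3 = f3)
  if (anyNA(f) || any(f < 0)) {
    stop("inheritance weights must be non-negative", call. = FALSE)
  }
  if (all(f == 0)) {
    stop("at least one inheritance weight must be positive", call. = FALSE)
  }
  structure(f, class = "inheritance_weights")
}

as_weights <- function(f) {
  if (inherits(f, "inheritance_weights")) return(f)
  if (length(f) != 3L) stop("need 3 inheritance weights", call. = FALSE)
  inheritance_weights(f[[1L]], f[[2L]], f[[3L]])
}

#' Cell composition inherited by a fragment
#'
#' The composition of a nascent fragment is the parent's composition at
#' maturity reweighted by the transmission propensities and renormalized:
#' \deqn{(\Pi_F, \Psi_F, \Gamma_F) = \frac{(f_1 \Pi_P, f_2 \Psi_P, f_3 \Gamma_P)}
#'       {f_1 \Pi_P + f_2 \Psi_P + f_3 \Gamma_P}.}
#' The same relation governs the somatic compartment. The map is invariant
#' to rescaling the weights, so only their ratios matter. With equal weights
#' (binary fission) the fragment is a clone of the parent's composition.
#'
#' @param parent parent composition at maturity.
#' @param f [inheritance_weights()] or a 3-vector.
#' @return The fragment's [cell_composition()] at replication-age 0.
#' @examples
#' fragment_inherit(c(0.9, 0.08, 0.02), c(5, 1, 0.5))
#' @export
fragment_inherit <- function(parent, f) {
  parent <- as_composition(parent)
  f <- as_weights(f)
  w <- unclass(f)[1:3] * unclass(parent)[1:3]
  s <- sum(w)
  if (s <= 0) {
    stop("degenerate fragment: the inherited composition contains no cells",
         call. = FALSE)
  }
  cell_composition(w / s, role = attr(parent, "role"))
}

#' Composition trajectory across consecutive fragmentations
#'
#' Iterates the fragmentation life cycle: a mature parent sheds a fragment
#' (weighted inheritance), the fragment grows to maturity over `TF`
#' replications (two-hit chain), and itself becomes the next parent.
#' Element `i + 1` of the returned matrix is the maturity composition after
#' `i` consecutive fragmentations; row 1 is the starting composition `x0`.
#' Whether the cancerous proportion decays (fragmentational purging) or
#' grows (fragmentational accumulation) along the sequence is determined by
#' [classify_regime()].
#'
#' @param x0 maturity composition of the fragmentational ancestor.
#' @param f [inheritance_weights()].
#' @param mu1,mu2 transition rates of the compartment being tracked (use
#'   `k1`, `k2` for the somatic analogue).
#' @param TF replications to maturity after fragmentation.
#' @param n number of consecutive fragmentations, `>= 0`.
#' @return A `(n + 1) x 3` matrix of maturity compositions, one row per
#'   generation along the fragmentation run.
#' @examples
#' lineage_iterate(c(0.9, 0.05, 0.05), c(5, 1, 0.5), 0.02, 0.03, 15, n = 5)
#' @export
lineage_iterate <- function(x0, f, mu1, mu2, TF, n) {
  x0 <- as_composition(x0)
  f <- as_weights(f)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = n + 1L, ncol = 3L,
                dimnames = list(NULL, c("normal", "defective", "cancerous")))
  x <- unclass(x0)[1:3]
  out[1L, ] <- x
  if (n == 0L) return(out)
  M <- transfer_operator(mu1, mu2, TF)
  fw <- unclass(f)[1:3]
  for (i in seq_len(n)) {
    w <- fw * x
    s <- sum(w)
    if (s <= 0) {
      stop("degenerate fragment at generation ", i, call. = FALSE)
    }
    x <- as.vector(M %*% (w / s))
    out[i + 1L, ] <- x
  }
  out
}

#' Classify the trans-generational fragmentation regime
#'
#' One fragmentation generation acts on a maturity composition as the
#' normalized linear map `x -> M x / |M x|` with
#' `M = transfer_operator(mu1, mu2, TF) %*% diag(f)`, a lower-triangular
#' matrix with diagonal
#' \deqn{d = (f_1 e^{-\mu_1 T_F},\; f_2 e^{-\mu_2 T_F},\; f_3).}
#' The long-run behaviour of consecutive fragmentations is decided by which
#' diagonal entry dominates:
#' \itemize{
#'   \item `d3` strictly largest: fragmentational \emph{accumulation} — the
#'     cancerous proportion rises every generation and converges to 1;
#'     purging is impossible. Equal weights (binary fission) always land
#'     here, since `exp(-mu t) < 1`.
#'   \item `d1` strictly largest: the composition of lineages seeded with
#'     normal cells converges to a limit with a positive normal share
#'     (\emph{fragmentational purging} is possible).
#'   \item `d2 > d3` with `d1` not dominant: lineages without normal cells
#'     (defective ancestors) converge to a limit supported on the
#'     defective/cancerous states.
#'   \item ties among the relevant entries: \emph{indeterminate} — no unique
#'     limit; the strict inequalities the analysis rests on fail.
#' }
#'
#' @param f [inheritance_weights()].
#' @param mu1,mu2 compartment transition rates.
#' @param TF replications to maturity after fragmentation, `> 0`.
#' @return A `regime_classification` list: `regime` (one of
#'   `"accumulation"`, `"convergent_purging_NF"`, `"convergent_DF"`,
#'   `"indeterminate"`), `d` (the three diagonal values), `dominant_value`,
#'   and `limit` (the limit composition, or `NULL` when indeterminate).
#' @examples
#' classify_regime(c(1, 1, 1), 0.02, 0.03, 15)    # accumulation
#' classify_regime(c(5, 1, 0.5), 0.02, 0.03, 15)  # purging regime
#' @export
classify_regime <- function(f, mu1, mu2, TF) {
  f <- as_weights(f)
  if (!is.numeric(TF) || length(TF) != 1L || TF <= 0) {
    stop("TF must be a positive scalar", call. = FALSE)
  }
  d <- c(f[[1L]] * exp(-mu1 * TF), f[[2L]] * exp(-mu2 * TF), f[[3L]])
  names(d) <- c("d1", "d2", "d3")
  regime <-
    if (d[[1L]] > max(d[[2L]], d[[3L]])) "convergent_purging_NF"
    else if (d[[3L]] > max(d[[1L]], d[[2L]])) "accumulation"
    else if (d[[2L]] > max(d[[1L]], d[[3L]])) "convergent_DF"
    else "indeterminate"
  limit <- if (regime == "indeterminate") NULL else {
    limit_composition_closed(f, mu1, mu2, TF, which.max(d))
  }
  structure(list(regime = regime, d = d, dominant_value = max(d),
                 limit = limit),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("<regime: %s>\n", x$regime))
  cat(sprintf("  diagonal values: d1 = %.6g, d2 = %.6g, d3 = %.6g\n",
              x$d[[1L]], x$d[[2L]], x$d[[3L]]))
  if (!is.null(x$limit)) {
    cat(sprintf("  limit composition: (%.6g, %.6g, %.6g)\n",
                x$limit[[1L]], x$limit[[2L]], x$limit[[3L]]))
  }
  invisible(x)
}

## Dominant eigenvector of M = transfer_operator %*% diag(f), in closed form.
## M is lower triangular, eigenvalues on the diagonal; back-substitution
## gives the eigenvector of the m-th (dominant) eigenvalue. Under strict
## dominance all denominators are positive and the vector is non-negative.
limit_composition_closed <- function(f, mu1, mu2, TF, m) {
  M <- transfer_operator(mu1, mu2, TF) %*% diag(unclass(f)[1:3])
  d <- diag(M)
  v <- numeric(3L)
  v[m] <- 1
  if (m == 1L) {
    v[2L] <- M[2L, 1L] / (d[1L] - d[2L])
    v[3L] <- (M[3L, 1L] + M[3L, 2L] * v[2L]) / (d[1L] - d[3L])
  } else if (m == 2L) {
    v[3L] <- M[3L, 2L] / (d[2L] - d[3L])
  }
  cell_composition(v / sum(v))
}

#' Limit composition of an infinite fragmentation run
#'
#' The maturity composition that [lineage_iterate()] converges to as the
#' number of consecutive fragmentations grows, computed exactly as the
#' normalized dominant eigenvector of the composed operator
#' `transfer_operator(mu1, mu2, TF) %*% diag(f)`. The matrix is lower
#' triangular, so the eigensystem is solved in closed form by
#' back-substitution; no iterative tolerance is involved. In the
#' accumulation regime the limit is the pure-cancer vertex `(0, 0, 1)`.
#'
#' @inheritParams classify_regime
#' @return The limit [cell_composition()].
#' @examples
#' limit_composition(c(5, 1, 0.5), 0.02, 0.03, 15)
#' @export
limit_composition <- function(f, mu1, mu2, TF) {
  cls <- classify_regime(f, mu1, mu2, TF)
  if (cls$regime == "indeterminate") {
    stop("tied dominant values: the fragmentation run has no unique limit",
         call. = FALSE)
  }
  cls$limit
}
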