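#' Baseline cell-state transition rate as a function of cancer suppression
#'
#' The per-replication rate at which cells acquire the next oncogenic state
#' before compartment-specific modifiers are applied. Stronger combined
#' cancer-suppression capability (immunity, tumour-suppressor function) `I`
#' lowers mutation and mis-proliferation rates, so `eta_rate()` is strictly
#' decreasing in `I`. The default form is exponential decay,
#' `eta0 * exp(-lambda * I)`, which is strictly positive on (0, 1).
#'
#' @param I cancer-suppression capability, in (0, 1).
#' @param eta0 rate at the `I -> 0` limit (per cell replication). Default 0.05.
#' @param lambda decay of the rate per unit of suppression capability.
#'   Default 3.
#' @return Baseline transition rate (per replication), strictly positive.
#' @examples
#' eta_rate(0.5)                    # 0.05 * exp(-1.5)
#' eta_rate(0.9) < eta_rate(0.1)    # TRUE
#' @export
eta_rate <- function(I, eta0 = 0.05, lambda = 3) {
  stopifnot(is.numeric(I), is.numeric(eta0), is.numeric(lambda))
  if (any(I <= 0 | I >= 1)) {
    stop("cancer-suppression capability I must lie in (0, 1)", call. = FALSE)
  }
  if (eta0 <= 0 || lambda <= 0) {
    stop("eta0 and lambda must be positive", call. = FALSE)
  }
  eta0 * exp(-lambda * I)
}

#' Construct germline and somatic transition rates
#'
#' Builds the four per-replication transition rates from the strategy
#' parameters. The germline (PGC/APSC) rate carries the APSC-proliferability
#' surcharge `1 + theta` (proliferation elevates mutation risk) and the
#' fidelity bias `2 - s`; the somatic rate carries the complementary bias
#' `s`. `s < 1` shields somatic cells at the expense of the germline and
#' vice versa. Second-hit transitions (defective to cancerous) run 1.5 times
#' faster than first hits, reflecting genomic instability after the first
#' tumour-suppressor loss:
#'
#' \deqn{k_1 = s\,\eta(I),\quad \mu_1 = (1+\theta)(2-s)\,\eta(I),\quad
#'       k_2 = 1.5 k_1,\quad \mu_2 = 1.5 \mu_1.}
#'
#' @param I cancer-suppression capability in (0, 1).
#' @param s replication-fidelity bias in (0, 2); the scenario sweeps use
#'   0.5, 0.75, 1, 1.25, 1.5.
#' @param theta APSC proliferability in `[0, 1)`; 0 for organisms without
#'   APSCs.
#' @param eta0,lambda parameters of [eta_rate()].
#' @return A `transition_rates` list with elements `mu1`, `mu2` (germline)
#'   and `k1`, `k2` (somatic).
#' @examples
#' make_rates(I = 0.5, s = 1, theta = 0)     # mu1 == k1 == eta_rate(0.5)
#' make_rates(I = 0.5, s = 1.5, theta = 0.7) # germline-protected strategy
#' @export
make_rates <- function(I, s, theta = 0, eta0 = 0.05, lambda = 3) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s >= 2) {
    stop("fidelity bias s must lie in (0, 2)", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("APSC proliferability theta must lie in [0, 1)", call. = FALSE)
  }
  eta <- eta_rate(I, eta0 = eta0, lambda = lambda)
  k1 <- s * eta
  mu1 <- (1 + theta) * (2 - s) * eta
  structure(list(mu1 = mu1, mu2 = 1.5 * mu1, k1 = k1, k2 = 1.5 * k1),
            class = "transition_rates")
}

#' @export
print.transition_rates <- function(x, ...) {
  cat("<transition_rates>\n")
  cat(sprintf("  germline: mu1 = %.6g, mu2 = %.6g\n", x$mu1, x$mu2))
  cat(sprintf("  somatic:  k1  = %.6g, k2  = %.6g\n", x$k1, x$k2))
  invisible(x)
}

## Solution of the two-hit transition chain
##   p1' = -a p1 ; p2' = a p1 - b p2 ; p3' = b p2
## at time t, as the three basis responses needed by both propagate() and
## transfer_operator(). The a == b case is the removable-singularity limit
## psi = p2(0) e^{-at} + a t p1(0) e^{-at}.
chain_solution <- function(p1_0, p2_0, a, b, t) {
  e1 <- exp(-a * t)
  p1 <- p1_0 * e1
  if (abs(b - a) < 1e-12 * max(a, b, 1)) {
    p2 <- p2_0 * e1 + a * t * p1_0 * e1
  } else {
    # (e1 - e2)/(b - a) via expm1 to avoid cancellation at small gaps
    p2 <- p2_0 * exp(-b * t) +
      a * p1_0 * e1 * (-expm1(-(b - a) * t)) / (b - a)
  }
  c(p1, p2)
}

#' Propagate a cell composition through t replications
#'
#' Evolves the proportions of normal, defective and cancerous cells in one
#' compartment over `t` cell replications under the irreversible two-hit
#' chain normal -> defective -> cancerous with first- and second-hit rates
#' `mu1` and `mu2`. The closed-form solution is used:
#' \deqn{\Pi_t = \Pi_0 e^{-\mu_1 t}}
#' \deqn{\Psi_t = \Psi_0 e^{-\mu_2 t} +
#'   \mu_1 \Pi_0 \frac{e^{-\mu_1 t} - e^{-\mu_2 t}}{\mu_2 - \mu_1}}
#' with the cancerous proportion as the simplex remainder. `t` is a
#' continuous non-negative quantity (replication count, or age under a
#' constant replication rate). Equal rates take the analytic limit of the
#' second line, so the function is total in `(mu1, mu2)`.
#'
#' For the somatic compartment pass `k1`, `k2` as `mu1`, `mu2`; the chain is
#' identical.
#'
#' @param x0 composition at replication-age 0 ([cell_composition()] or a
#'   3-vector on the simplex).
#' @param mu1,mu2 first- and second-hit transition rates, `>= 0`.
#' @param t replication count, `>= 0`.
#' @return The composition at replication-age `t`, same role as `x0`.
#' @examples
#' propagate(c(1, 0, 0), 0.02, 0.03, 35)
#' propagate(c(0, 1, 0), 0.02, 0.03, 10)  # never regains normal cells
#' @export
propagate <- function(x0, mu1, mu2, t) {
  x0 <- as_composition(x0)
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("replication count t must be a non-negative scalar", call. = FALSE)
  }
  if (mu1 < 0 || mu2 < 0) stop("transition rates must be >= 0", call. = FALSE)
  p12 <- chain_solution(x0[[1L]], x0[[2L]], mu1, mu2, t)
  p12 <- pmin(pmax(p12, 0), 1)
  cell_composition(c(p12, max(0, 1 - sum(p12))), role = attr(x0, "role"))
}

#' Linear transfer operator of the two-hit chain
#'
#' The 3x3 lower-triangular column-stochastic matrix `M(t)` with
#' `M(t) %*% x0 == propagate(x0, mu1, mu2, t)` for every simplex point.
#' Its eigenvalues are `exp(-mu1 t)`, `exp(-mu2 t)` and 1, read off the
#' diagonal. The operator underlies the analytical purging/accumulation
#' classification: a run of fragmentation generations composes `M(TF)` with
#' the diagonal inheritance weights, and the dominant eigenvector of that
#' product is the trans-generational limit composition.
#'
#' @inheritParams propagate
#' @return A 3x3 numeric matrix, lower triangular, columns summing to 1.
#' @examples
#' M <- transfer_operator(0.02, 0.03, 15)
#' colSums(M)   # all 1
#' @export
transfer_operator <- function(mu1, mu2, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("replication count t must be a non-negative scalar", call. = FALSE)
  }
  if (mu1 < 0 || mu2 < 0) stop("transition rates must be >= 0", call. = FALSE)
  c1 <- chain_solution(1, 0, mu1, mu2, t)
  c2 <- chain_solution(0, 1, mu1, mu2, t)
  M <- matrix(0, 3L, 3L)
  M[1:2, 1L] <- c1
  M[3L, 1L] <- 1 - sum(c1)
  M[2L, 2L] <- c2[[2L]]
  M[3L, 2L] <- 1 - c2[[2L]]
  M[3L, 3L] <- 1
  M
}

#' Blend somatic composition with the APSC pool at maturity
#'
#' In organisms bearing adult primordial stem cells (APSCs), part of the
#' mature somatic tissue is produced by the APSC pool rather than by the
#' original somatic lineage, so the somatic composition at maturity is a
#' convex combination weighted by the APSC proliferability:
#' `theta * apsc + (1 - theta) * somatic`. With `theta = 0` (no APSCs) the
#' somatic composition is untouched.
#'
#' @param apsc germline/APSC composition at maturity.
#' @param somatic somatic composition at maturity before APSC influence.
#' @param theta APSC proliferability in `[0, 1)`.
#' @return The blended somatic [cell_composition()].
#' @examples
#' couple_somatic(c(1, 0, 0), c(0.8, 0.2, 0), theta = 0.5)  # (0.9, 0.1, 0)
#' @export
couple_somatic <- function(apsc, somatic, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("APSC proliferability theta must lie in [0, 1)", call. = FALSE)
  }
  apsc <- as_composition(apsc)
  somatic <- as_composition(somatic, role = "somatic")
  cell_composition(theta * unclass(apsc)[1:3] + (1 - theta) * unclass(somatic)[1:3],
                   role = "somatic")
}

#' Replications needed to reach the mature cell number
#'
#' Under synchronous binary cell division with no cell death, a body of
#' `n_start` cells needs `log2(n_mature / n_start)` replications to reach
#' `n_mature` cells. A zygote (`n_start = 1`) composed into a 1024-cell
#' adult divides 10 times; a detached 128-cell fragment of the same species
#' needs only 3. The gap between the two is the replication saving that
#' fragmentation buys.
#'
#' @param n_mature cell number of the mature organism.
#' @param n_start cell number at the start of development (1 for a zygote;
#'   the fragment size for fissiparity or budding).
#' @return Number of replications (continuous; integral when the ratio is a
#'   power of two).
#' @examples
#' replications_to_maturity(1024)        # 10
#' replications_to_maturity(1024, 128)   # 3
#' @export
replications_to_maturity <- function(n_mature, n_start = 1) {
  if (any(n_mature <= 0) || any(n_start <= 0)) {
    stop("cell numbers must be positive", call. = FALSE)
  }
  if (any(n_start > n_mature)) {
    stop("starting cell number exceeds the mature cell number", call. = FALSE)
  }
  log2(n_mature / n_start)
}
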