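#' Fitness parameters
#'
#' Bundles the constants of the organism-level fitness function and of the
#' population-level genetic-diversity penalty.
#'
#' The composition coefficients must satisfy `alphaN >= alphaD >= alphaC`:
#' normal tissue contributes most to fitness, cancerous tissue least. The
#' exponent `epsilon >= 1` encodes cancer aggressiveness — at `epsilon = 2`
#' a 10% shift of normal tissue into cancer costs 19% of the composition
#' term, versus 10% at `epsilon = 1`.
#'
#' @param omega0 baseline fitness.
#' @param alphaN,alphaD,alphaC composition coefficients (non-increasing).
#' @param epsilon cancer-fatality exponent, `>= 1` (scenarios use 1 to 2).
#' @param tau frequency of external damage events, `>= 0`.
#' @param delta fitness loss per damage event, `>= 0`.
#' @param c0 cost coefficient of sustaining cancer suppression, `>= 0`.
#' @param b0 diversity floor in (0, 1): the fitness multiplier of a fully
#'   clonal population. Lower values mean harsher penalties for losing
#'   genetic diversity.
#' @param chi_form reading of the regeneration discount in the damage cost:
#'   `"one_minus_theta_sq"` for `1 - theta^2` (default) or `"sq_one_minus_theta"`
#'   for `(1 - theta)^2`.
#' @param H_form reading of the diversity curve: `"root"` for
#'   `b0 + (1 - b0) (1 - rho)^(1/4)` (default) or `"quartic"` for
#'   `b0 + (1 - b0) (1 - rho^4)`.
#' @return A `fitness_params` list.
#' @examples
#' fitness_params(epsilon = 2, tau = 0.5, delta = 0.4)
#' @export
fitness_params <- function(omega0 = 1, alphaN = 1, alphaD = 0.8, alphaC = 0,
                           epsilon = 2, tau = 0.3, delta = 0.1, c0 = 1,
                           b0 = 0.5,
                           chi_form = c("one_minus_theta_sq", "sq_one_minus_theta"),
                           H_form = c("root", "quartic")) {
  chi_form <- match.arg(chi_form)
  H_form <- match.arg(H_form)
  if (!(alphaN >= alphaD && alphaD >= alphaC)) {
    stop("composition coefficients must satisfy alphaN >= alphaD >= alphaC",
         call. = FALSE)
  }
  if (epsilon < 1) stop("epsilon must be >= 1", call. = FALSE)
  if (tau < 0 || delta < 0 || c0 < 0) {
    stop("tau, delta and c0 must be non-negative", call. = FALSE)
  }
  if (b0 <= 0 || b0 >= 1) stop("b0 must lie in (0, 1)", call. = FALSE)
  structure(list(omega0 = omega0, alphaN = alphaN, alphaD = alphaD,
                 alphaC = alphaC, epsilon = epsilon, tau = tau, delta = delta,
                 c0 = c0, b0 = b0, chi_form = chi_form, H_form = H_form),
            class = "fitness_params")
}

#' Composition contribution to fitness
#'
#' The somatic-composition term
#' \eqn{\alpha_N N^\varepsilon + \alpha_D D^\varepsilon + \alpha_C C^\varepsilon}
#' of the fitness function. Because the proportions sum to 1, raising
#' `epsilon` above 1 makes a given shift of mass from normal to cancerous
#' tissue more costly: at `alphaN = 1, alphaC = 0` the term is 0.9 for the
#' composition (0.9, 0, 0.1) when `epsilon = 1` but 0.81 when `epsilon = 2`.
#'
#' @param somatic somatic [cell_composition()] at maturity.
#' @param p [fitness_params()].
#' @return The composition term (dimensionless).
#' @examples
#' p <- fitness_params(alphaN = 1, alphaD = 0, alphaC = 0, epsilon = 2)
#' composition_term(c(0.9, 0, 0.1), p)  # 0.81
#' @export
composition_term <- function(somatic, p) {
  x <- unclass(as_composition(somatic, role = "somatic"))[1:3]
  p$alphaN * x[[1L]]^p$epsilon + p$alphaD * x[[2L]]^p$epsilon +
    p$alphaC * x[[3L]]^p$epsilon
}

#' Expected fitness loss from external damage
#'
#' Physical trauma (injury, predator attack) strikes at frequency `tau`
#' with severity `delta`; regeneration powered by the APSC pool discounts
#' the expected loss, so the cost is `tau * delta * (1 - theta^2)` under the
#' default reading (alternatively `tau * delta * (1 - theta)^2`). Either
#' form is strictly decreasing in `theta` whenever `tau * delta > 0`.
#'
#' @param tau,delta damage frequency and severity, `>= 0`.
#' @param theta APSC proliferability in `[0, 1)`.
#' @param chi_form see [fitness_params()].
#' @return The expected fitness reduction.
#' @examples
#' damage_cost(0.3, 0.1, 0.7)  # 0.03 * (1 - 0.49)
#' @export
damage_cost <- function(tau, delta, theta,
                        chi_form = c("one_minus_theta_sq", "sq_one_minus_theta")) {
  chi_form <- match.arg(chi_form)
  if (tau < 0 || delta < 0) stop("tau and delta must be >= 0", call. = FALSE)
  if (any(theta < 0 | theta >= 1)) {
    stop("theta must lie in [0, 1)", call. = FALSE)
  }
  disc <- if (chi_form == "one_minus_theta_sq") 1 - theta^2 else (1 - theta)^2
  tau * delta * disc
}

#' Physiological cost of cancer suppression
#'
#' Sustaining a cancer-suppression capability `I` (replication fidelity,
#' immune surveillance, tumour-suppressor activity) reduces fitness
#' quadratically: `c0 * I^2`.
#'
#' @param c0 cost coefficient, `>= 0`.
#' @param I cancer-suppression capability in (0, 1).
#' @return The fitness reduction.
#' @examples
#' suppression_cost(1, 0.5)  # 0.25
#' @export
suppression_cost <- function(c0, I) {
  if (c0 < 0) stop("c0 must be >= 0", call. = FALSE)
  if (any(I <= 0 | I >= 1)) stop("I must lie in (0, 1)", call. = FALSE)
  c0 * I^2
}

#' Organism fitness
#'
#' Assembles the fitness of a mature organism:
#' \deqn{\omega = \omega_0 + \alpha_N N^\varepsilon + \alpha_D D^\varepsilon +
#'       \alpha_C C^\varepsilon - \chi(\theta) - g(I),}
#' the baseline plus the somatic-composition term, minus the expected
#' external-damage cost and the cost of sustaining cancer suppression.
#' Fitness enters the population recursion as a reproductive-output
#' multiplier, so it is clamped below at 0: costs can cancel reproduction
#' but not make it negative.
#'
#' @param somatic somatic composition at maturity.
#' @param theta APSC proliferability.
#' @param I cancer-suppression capability.
#' @param p [fitness_params()].
#' @return Non-negative fitness.
#' @examples
#' p <- fitness_params(epsilon = 2, tau = 0.5, delta = 0.4, c0 = 1)
#' organism_fitness(c(0.95, 0.04, 0.01), theta = 0.7, I = 0.4, p = p)
#' @export
organism_fitness <- function(somatic, theta, I, p) {
  w <- p$omega0 + composition_term(somatic, p) -
    damage_cost(p$tau, p$delta, theta, p$chi_form) -
    suppression_cost(p$c0, I)
  max(0, w)
}

#' Genetic-diversity coefficient
#'
#' Fragmentation produces clones; a clonal population is more vulnerable to
#' infectious disease and transmissible cancer. Given the clone proportion
#' `rho` (share of fragmentation-derived organisms in the population), the
#' fitness of clonal organisms is multiplied by
#' \deqn{H = b_0 + (1 - b_0)(1 - \rho)^{1/4},}
#' a concave decreasing curve with `H(0) = 1` (a few clones cost nothing)
#' and `H(1) = b0` (a fully clonal population pays the full penalty). The
#' alternative quartic reading `b0 + (1 - b0)(1 - rho^4)` shares the
#' boundary values and monotonicity and is selectable via `H_form`.
#'
#' @param rho clone proportion in `[0, 1]`.
#' @param b0 diversity floor in (0, 1).
#' @param H_form see [fitness_params()].
#' @return `H` in `[b0, 1]`.
#' @examples
#' diversity_coefficient(0.5, b0 = 0.7)
#' @export
diversity_coefficient <- function(rho, b0, H_form = c("root", "quartic")) {
  H_form <- match.arg(H_form)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]", call. = FALSE)
  if (b0 <= 0 || b0 >= 1) stop("b0 must lie in (0, 1)", call. = FALSE)
  if (H_form == "root") b0 + (1 - b0) * (1 - rho)^(1 / 4)
  else b0 + (1 - b0) * (1 - rho^4)
}
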