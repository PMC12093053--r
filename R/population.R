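#' Zygote-type probabilities from a germline composition
#'
#' In a sexual reproduction attempt, gametes are drawn from the mature
#' germline pool with fertilization functionality `r1`, `r2`, `r3` for
#' normal, defective and cancerous germ cells. A normal gamete yields a
#' normal zygote with probability `U1`, a defective gamete a defective
#' zygote with probability `U2`; a cancerous gamete may fertilize but the
#' embryo cannot develop, so `1 - U1 - U2` is reproductive failure:
#' \deqn{U_1 = \frac{r_1 \Pi}{r_1 \Pi + r_2 \Psi + r_3 \Gamma}, \qquad
#'       U_2 = \frac{r_2 \Psi}{r_1 \Pi + r_2 \Psi + r_3 \Gamma}.}
#' Organisms without normal germ cells have `U1 = 0`: defective lineages
#' can never produce normal offspring.
#'
#' @param germline germline [cell_composition()] at maturity.
#' @param r1,r2,r3 fertilization functionality of the three germ-cell
#'   states, `>= 0`.
#' @return List with elements `U1` and `U2` (`U1 + U2 <= 1`).
#' @examples
#' zygote_probabilities(c(0.5, 0.3, 0.2), 1, 0.5, 0.1)
#' @export
zygote_probabilities <- function(germline, r1, r2, r3) {
  g <- unclass(as_composition(germline))[1:3]
  if (any(c(r1, r2, r3) < 0)) {
    stop("fertilization functionalities must be >= 0", call. = FALSE)
  }
  den <- r1 * g[[1L]] + r2 * g[[2L]] + r3 * g[[3L]]
  if (den <= 0) {
    stop("no viable gametes: all fertilization-weighted proportions are zero",
         call. = FALSE)
  }
  list(U1 = r1 * g[[1L]] / den, U2 = r2 * g[[2L]] / den)
}

#' Bounded population-regulation transform
#'
#' Environmental capacity damps generation-to-generation fluctuations of the
#' total population: the proposed growth ratio `P*_{j+1} / P_j` is mapped
#' through a generalized logistic
#' \deqn{\Theta(x) = L + \frac{U - L}{1 + A e^{-k (x - 1)}},\quad
#'       L = 0.9391,\ U = 1.08,\ A = \frac{U - 1}{1 - L},}
#' which is monotone increasing, satisfies `Theta(1) = 1` exactly (neutral
#' growth is untouched) and is bounded in `[0.9391, 1.08]`, so the realized
#' population can neither crash nor explode in a single generation.
#'
#' @param ratio proposed growth ratio, `> 0`.
#' @param k logistic steepness (default 5).
#' @param lower,upper the ratio bounds.
#' @return `Theta(ratio)`, vectorized over `ratio`.
#' @examples
#' theta_transform(c(0.5, 1, 2))
#' @export
theta_transform <- function(ratio, k = 5, lower = 0.9391, upper = 1.08) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("growth ratio must be positive", call. = FALSE)
  }
  A <- (upper - 1) / (1 - lower)
  lower + (upper - lower) / (1 + A * exp(-k * (ratio - 1)))
}

#' Mature state of an organism of a given lineage
#'
#' Assembles the germline and somatic compositions at maturity, and the
#' fitness, of one organism. Sexually produced organisms (`NU`, `DU`)
#' develop from a pure normal or pure defective zygote over `TU`
#' replications. Fragmentation-produced organisms (`NF`, `DF`) start from
#' the parent's maturity compositions filtered through the inheritance
#' weights and mature over `TF < TU` replications. In APSC-bearing
#' organisms (`theta > 0`) the somatic composition at maturity is blended
#' with the APSC pool via [couple_somatic()]; the `apsc_coupling_fragments`
#' switch controls whether the blending is reapplied at fragment maturity.
#'
#' @param lineage `"NU"`, `"DU"`, `"NF"` or `"DF"`.
#' @param rates [make_rates()] output.
#' @param theta APSC proliferability.
#' @param TU,TF replications to maturity for unitary development and
#'   fragmentation.
#' @param fp [fitness_params()].
#' @param I cancer-suppression capability (enters the fitness cost).
#' @param parent parent `organism_state` (required for `NF`/`DF`).
#' @param f [inheritance_weights()] (required for `NF`/`DF`).
#' @param apsc_coupling_fragments apply the APSC blend at fragment maturity
#'   (default `TRUE`).
#' @return An `organism_state` list: `lineage`, `depth`, `germline`,
#'   `somatic`, `fitness`.
#' @examples
#' r <- make_rates(0.5, 1, 0.3)
#' fp <- fitness_params()
#' nu <- maturity_state("NU", r, 0.3, 35, 15, fp, I = 0.5)
#' maturity_state("NF", r, 0.3, 35, 15, fp, I = 0.5,
#'                parent = nu, f = c(5, 1, 0.5))
#' @export
maturity_state <- function(lineage = c("NU", "DU", "NF", "DF"), rates, theta,
                           TU, TF, fp, I, parent = NULL, f = NULL,
                           apsc_coupling_fragments = TRUE) {
  lineage <- match.arg(lineage)
  fragment <- lineage %in% c("NF", "DF")
  if (fragment && (is.null(parent) || is.null(f))) {
    stop("fragment lineages need a parent state and inheritance weights",
         call. = FALSE)
  }
  if (fragment) {
    g0 <- fragment_inherit(parent$germline, f)
    s0 <- fragment_inherit(parent$somatic, f)
    t_mat <- TF
  } else {
    pure <- if (lineage == "NU") c(1, 0, 0) else c(0, 1, 0)
    g0 <- cell_composition(pure)
    s0 <- cell_composition(pure, role = "somatic")
    t_mat <- TU
  }
  germline <- propagate(g0, rates$mu1, rates$mu2, t_mat)
  somatic <- propagate(s0, rates$k1, rates$k2, t_mat)
  couple <- theta > 0 && (!fragment || apsc_coupling_fragments)
  if (couple) somatic <- couple_somatic(germline, somatic, theta)
  structure(list(lineage = lineage,
                 depth = if (fragment) (parent$depth %||% 0L) + 1L else 0L,
                 germline = germline, somatic = somatic,
                 fitness = organism_fitness(somatic, theta, I, fp)),
            class = "organism_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.organism_state <- function(x, ...) {
  tag <- if (x$depth > 0L) sprintf("%s%d", x$lineage, x$depth) else x$lineage
  cat(sprintf("<organism_state %s>  fitness = %.6g\n", tag, x$fitness))
  cat(sprintf("  germline: (%.4g, %.4g, %.4g)\n",
              x$germline[[1L]], x$germline[[2L]], x$germline[[3L]]))
  cat(sprintf("  somatic:  (%.4g, %.4g, %.4g)\n",
              x$somatic[[1L]], x$somatic[[2L]], x$somatic[[3L]]))
  invisible(x)
}

## Precompute maturity states for NU, DU and NF_i / DF_i up to depth_cap.
## Returns per-lineage fitness, zygote probabilities and somatic cancer
## proportions as flat vectors indexed by depth, which is all the
## generation recursion needs.
lineage_table <- function(cfg, depth_cap) {
  rates <- make_rates(cfg$I, cfg$s, cfg$theta,
                      eta0 = cfg$eta0, lambda = cfg$lambda)
  fp <- cfg$fitness
  NU <- maturity_state("NU", rates, cfg$theta, cfg$TU, cfg$TF, fp, cfg$I)
  DU <- maturity_state("DU", rates, cfg$theta, cfg$TU, cfg$TF, fp, cfg$I)
  mk <- function(ancestor, lin) {
    states <- vector("list", depth_cap)
    parent <- ancestor
    for (i in seq_len(depth_cap)) {
      parent <- maturity_state(lin, rates, cfg$theta, cfg$TU, cfg$TF, fp,
                               cfg$I, parent = parent, f = cfg$f,
                               apsc_coupling_fragments = cfg$apsc_coupling_fragments)
      states[[i]] <- parent
    }
    states
  }
  NF <- mk(NU, "NF")
  DF <- mk(DU, "DF")
  uz <- function(st) zygote_probabilities(st$germline, cfg$r1, cfg$r2, cfg$r3)
  u_nu <- uz(NU); u_du <- uz(DU)
  list(
    rates = rates, NU = NU, DU = DU, NF = NF, DF = DF,
    omega = list(V = NU$fitness, W = DU$fitness,
                 Z = vapply(NF, `[[`, numeric(1), "fitness"),
                 Q = vapply(DF, `[[`, numeric(1), "fitness")),
    U1 = list(V = u_nu$U1, W = u_du$U1,
              Z = vapply(NF, function(s) uz(s)$U1, numeric(1)),
              Q = vapply(DF, function(s) uz(s)$U1, numeric(1))),
    U2 = list(V = u_nu$U2, W = u_du$U2,
              Z = vapply(NF, function(s) uz(s)$U2, numeric(1)),
              Q = vapply(DF, function(s) uz(s)$U2, numeric(1))),
    C = list(V = NU$somatic[[3L]], W = DU$somatic[[3L]],
             Z = vapply(NF, function(s) s$somatic[[3L]], numeric(1)),
             Q = vapply(DF, function(s) s$somatic[[3L]], numeric(1)))
  )
}

#' Advance the pedigree recursion by one generation
#'
#' Computes the untransformed subpopulation sizes of the next generation
#' from the current sizes, the per-lineage maturity states and the
#' reproduction parameters, then applies the population-regulation
#' transform. Sexual inflows are weighted by zygote-success probabilities
#' and juvenile survival (`deltaV`, `deltaW`); contributions of clonal
#' (fragmentation-derived) parents are multiplied by the current diversity
#' coefficient `H`; fragmentation inflows shift the depth index by one and
#' are multiplied by the offspring count per fragmentation event (2 for
#' binary fission, 1 for budding or asymmetric fission).
#'
#' @param state list with numeric `V`, `W` and vectors `Z`, `Q` (sizes by
#'   fragmentation depth) for the current generation.
#' @param tab internal lineage table (fitness, zygote probabilities per
#'   lineage/depth) as built inside [run_pedigree()].
#' @param cfg a [scenario_config()].
#' @return The state list of the next generation (realized sizes, plus
#'   `P`, `rho`, `H`, `ratio`).
#' @keywords internal
step_generation <- function(state, tab, cfg) {
  m <- cfg$offspring_per_fragmentation
  phi <- cfg$phi
  rho <- if (state$P > 0) (sum(state$Z) + sum(state$Q)) / state$P else 0
  H <- diversity_coefficient(rho, cfg$fitness$b0, cfg$fitness$H_form)

  wZ <- state$Z * tab$omega$Z
  wQ <- state$Q * tab$omega$Q
  Vs <- cfg$deltaV * (1 - phi) *
    (state$V * tab$omega$V * tab$U1$V + H * sum(wZ * tab$U1$Z))
  Ws <- cfg$deltaW * (1 - phi) *
    (state$V * tab$omega$V * tab$U2$V + state$W * tab$omega$W * tab$U2$W +
       H * sum(wZ * tab$U2$Z) + H * sum(wQ * tab$U2$Q))
  n <- length(state$Z)
  Zs <- c(m * phi * state$V * tab$omega$V, m * phi * H * wZ)[seq_len(n)]
  Qs <- c(m * phi * state$W * tab$omega$W, m * phi * H * wQ)[seq_len(n)]

  Ps <- Vs + Ws + sum(Zs) + sum(Qs)
  if (!is.finite(Ps) || Ps <= 0) {
    stop(structure(class = c("fragevo_extinct", "error", "condition"),
                   list(message = "population extinct", call = NULL)))
  }
  ratio <- Ps / state$P
  th <- theta_transform(ratio, k = cfg$theta_k)
  scale <- if (cfg$theta_rule == "ratio") th * state$P / Ps else th
  out <- list(V = Vs * scale, W = Ws * scale, Z = Zs * scale, Q = Qs * scale)
  out$P <- out$V + out$W + sum(out$Z) + sum(out$Q)
  ## prune negligible depth classes to keep the support compact
  tiny <- 1e-12 * out$P
  out$Z[out$Z < tiny] <- 0
  out$Q[out$Q < tiny] <- 0
  out$rho <- (sum(out$Z) + sum(out$Q)) / out$P
  out$H <- diversity_coefficient(out$rho, cfg$fitness$b0, cfg$fitness$H_form)
  out$ratio <- th
  out
}

#' Size-weighted cancer prevalence of a population state
#'
#' The mean somatic cancerous proportion over all organisms alive in one
#' generation, weighting each lineage/depth class by its subpopulation
#' size.
#'
#' @param state a population state (`V`, `W`, `Z`, `Q`, `P`).
#' @param C per-lineage somatic cancerous proportions: list with scalar
#'   `V`, `W` and per-depth vectors `Z`, `Q`.
#' @return Prevalence in `[0, 1]`.
#' @examples
#' cancer_prevalence(list(V = 3, W = 0, Z = 1, Q = 0, P = 4),
#'                   list(V = 0.1, W = 0, Z = 0.3, Q = 0))
#' @export
cancer_prevalence <- function(state, C) {
  if (state$P <= 0) stop("prevalence undefined for an extinct population",
                         call. = FALSE)
  (state$V * C$V + state$W * C$W + sum(state$Z * C$Z) + sum(state$Q * C$Q)) /
    state$P
}

#' Run the multi-generation pedigree recursion
#'
#' Simulates the population over discrete generations. Generation 1 is
#' composed entirely of organisms developed from normal zygotes (size 1 in
#' relative units; the recursion is homogeneous in sizes, so absolute scale
#' is unidentifiable). Each step applies the reproduction equations for
#' sexual and fragmentation offspring and the bounded regulation transform.
#' The sum of individual fitness at the final generation is the
#' optimization index used to rank reproductive strategies.
#'
#' @param cfg a [scenario_config()]; its scalar `phi`, `I`, `theta`, `s`
#'   fields define the strategy being evaluated.
#' @param n_generations number of generations (default 30).
#' @return A `pedigree_run` list: `trajectory` (data.frame with one row per
#'   generation: `j`, `V`, `W`, `Ztot`, `Qtot`, `P`, `rho`, `H`,
#'   `total_fitness`, `cancer_prevalence`), `optimization_index`,
#'   `final_state`, `lineages` (the per-depth maturity states), and
#'   `extinct` flag.
#' @examples
#' cfg <- scenario_config(phi = 0.5, I = 0.4, theta = 0.3, s = 1.25)
#' run_pedigree(cfg, n_generations = 10)$trajectory
#' @export
run_pedigree <- function(cfg, n_generations = 30) {
  stopifnot(n_generations >= 1)
  cfg <- resolve_config(cfg)
  depth_cap <- max(1L, n_generations - 1L)
  tab <- lineage_table(cfg, depth_cap)
  state <- list(V = 1, W = 0, Z = numeric(depth_cap), Q = numeric(depth_cap),
                P = 1, rho = 0, H = 1, ratio = NA_real_)
  traj <- vector("list", n_generations)
  total_fitness <- function(st) {
    clone <- sum(st$Z * tab$omega$Z) + sum(st$Q * tab$omega$Q)
    if (cfg$include_H_in_index) clone <- st$H * clone
    st$V * tab$omega$V + st$W * tab$omega$W + clone
  }
  row <- function(j, st) data.frame(
    j = j, V = st$V, W = st$W, Ztot = sum(st$Z), Qtot = sum(st$Q), P = st$P,
    rho = st$rho, H = st$H, ratio = st$ratio,
    total_fitness = total_fitness(st),
    cancer_prevalence = cancer_prevalence(st, tab$C))
  traj[[1L]] <- row(1L, state)
  extinct <- FALSE
  for (j in seq_len(n_generations - 1L)) {
    state <- tryCatch(step_generation(state, tab, cfg),
                      fragevo_extinct = function(e) e)
    if (inherits(state, "condition")) { extinct <- TRUE; break }
    traj[[j + 1L]] <- row(j + 1L, state)
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  final <- trajectory[nrow(trajectory), ]
  structure(list(trajectory = trajectory,
                 optimization_index = if (extinct) 0 else final$total_fitness,
                 final_state = if (extinct) NULL else state,
                 lineages = tab, extinct = extinct, config = cfg),
            class = "pedigree_run")
}

#' @export
print.pedigree_run <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("<pedigree_run: %d generations%s>\n", n,
              if (x$extinct) ", extinct" else ""))
  cat(sprintf("  strategy: phi = %.3g, I = %.3g, theta = %.3g, s = %.3g\n",
              x$config$phi, x$config$I, x$config$theta, x$config$s))
  cat(sprintf("  optimization index (total fitness, gen %d): %.6g\n",
              n, x$optimization_index))
  cat(sprintf("  final cancer prevalence: %.6g\n",
              x$trajectory$cancer_prevalence[n]))
  invisible(x)
}
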