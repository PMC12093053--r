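#' Named scenario configurations
#'
#' Seven scenario files ship with the package, one per published model
#' variant: `FRPG-FR`, `FRPG-UD` (fragmentational purging, with
#' fragmentation resp. unitary development being fitness-maximizing),
#' `FRAC-FR`, `FRAC-UD` (fragmentational accumulation) and `BINF-FRa`,
#' `BINF-FRb`, `BINF-UD` (binary fission, equal inheritance weights, two
#' offspring per fission). Each file carries per-field provenance tags:
#' `printed` values come from the model description; `reconstructed` values
#' are this package's choices for constants only available in supplementary
#' material, selected to satisfy the documented regime membership and
#' qualitative optima. The scenario files are the single source of truth
#' for these defaults.
#'
#' @param name one of the seven scenario names, or a path to a YAML config
#'   file.
#' @return A [scenario_config()].
#' @examples
#' cfg <- load_scenario("FRPG-FR")
#' cfg$f                    # (5, 1, 0.5) -- printed
#' classify_regime_config(cfg)$regime
#' @export
load_scenario <- function(name) {
  shipped <- c("FRPG-FR", "FRPG-UD", "FRAC-FR", "FRAC-UD",
               "BINF-FRa", "BINF-FRb", "BINF-UD")
  if (name %in% shipped) {
    file <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                        package = "fragevo", mustWork = TRUE)
  } else if (file.exists(name)) {
    file <- name
  } else {
    stop("unknown scenario '", name, "'; expected one of ",
         paste(shipped, collapse = ", "), " or an existing config file",
         call. = FALSE)
  }
  parse_config(file)
}

## One surface cell: run the recursion, return index + final prevalence.
## Failures are flagged, not fatal: the sweep continues.
run_cell <- function(cfg, tab, n_generations) {
  tryCatch({
    r <- run_with_tab(cfg, tab, n_generations)
    list(fitness = r$index, prevalence = r$prevalence, ok = TRUE)
  }, error = function(e) list(fitness = NA_real_, prevalence = NA_real_,
                              ok = FALSE))
}

## Generation loop against a precomputed lineage table (hot path shared by
## run_pedigree and the sweeps; the table depends on everything but phi).
run_with_tab <- function(cfg, tab, n_generations) {
  state <- list(V = 1, W = 0,
                Z = numeric(max(1L, n_generations - 1L)),
                Q = numeric(max(1L, n_generations - 1L)),
                P = 1, rho = 0, H = 1)
  for (j in seq_len(n_generations - 1L)) {
    state <- step_generation(state, tab, cfg)
  }
  clone <- sum(state$Z * tab$omega$Z) + sum(state$Q * tab$omega$Q)
  if (cfg$include_H_in_index) clone <- state$H * clone
  list(index = state$V * tab$omega$V + state$W * tab$omega$W + clone,
       prevalence = cancer_prevalence(state, tab$C),
       state = state)
}

#' Fitness surface over fragmentation prevalence and cancer suppression
#'
#' Runs the pedigree recursion for every cell of the `phi_grid x I_grid`
#' strategy grid at fixed APSC proliferability `theta` and fidelity bias
#' `s`, recording the optimization index (total population fitness at the
#' final generation) and the cancer prevalence there. Cells with `phi = 0`
#' are run with `theta = 0`, since absent fragmentation implies absent
#' APSCs. The model contains no randomness, so repeated sweeps are
#' bit-identical. Besides the full grid, three marker sets are extracted:
#' the per-`phi` maxima over `I`, the global maximum, and the
#' no-fragmentation maximum (`phi = 0` column).
#'
#' @param cfg a [scenario_config()], scenario name or config path.
#' @param theta,s strategy values for this surface (default: the config's).
#' @param n_generations horizon of each run (default 30).
#' @return A `fitness_surface`: list with `grid` (data.frame `phi`, `I`,
#'   `fitness`, `prevalence`, `ok`), `per_phi` (per-`phi` optima),
#'   `global`, `no_frag` (one-row data.frames) and the surface coordinates.
#' @examples
#' \donttest{
#' sw <- sweep_fitness("FRPG-FR", theta = 0.7, s = 1.5)
#' sw$global
#' }
#' @export
sweep_fitness <- function(cfg, theta = NULL, s = NULL, n_generations = 30) {
  cfg <- resolve_config(cfg)
  theta <- theta %||% cfg$theta
  s <- s %||% cfg$s
  grid <- expand.grid(phi = cfg$phi_grid, I = cfg$I_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fitness <- prevalence <- rep(NA_real_, nrow(grid))
  ok <- logical(nrow(grid))
  for (I in unique(grid$I)) {
    cfg_I <- cfg; cfg_I$I <- I; cfg_I$s <- s; cfg_I$theta <- theta
    tab <- lineage_table(cfg_I, max(1L, n_generations - 1L))
    tab0 <- NULL
    rows <- which(grid$I == I)
    for (r in rows) {
      cfg_cell <- cfg_I
      cfg_cell$phi <- grid$phi[r]
      if (cfg_cell$phi == 0) {
        cfg_cell$theta <- 0
        if (is.null(tab0)) {
          cfg0 <- cfg_cell
          tab0 <- lineage_table(cfg0, max(1L, n_generations - 1L))
        }
        cell <- run_cell(cfg_cell, tab0, n_generations)
      } else {
        cell <- run_cell(cfg_cell, tab, n_generations)
      }
      fitness[r] <- cell$fitness
      prevalence[r] <- cell$prevalence
      ok[r] <- cell$ok
    }
  }
  grid$fitness <- fitness
  grid$prevalence <- prevalence
  grid$ok <- ok
  per_phi <- do.call(rbind, lapply(unique(grid$phi), function(p) {
    sub <- grid[grid$phi == p & grid$ok, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub[which.max(sub$fitness), c("phi", "I", "fitness", "prevalence")]
  }))
  rownames(per_phi) <- NULL
  global <- per_phi[which.max(per_phi$fitness), , drop = FALSE]
  no_frag <- per_phi[per_phi$phi == 0, , drop = FALSE]
  structure(list(name = cfg$name, theta = theta, s = s, grid = grid,
                 per_phi = per_phi, global = global, no_frag = no_frag),
            class = "fitness_surface")
}

#' @export
print.fitness_surface <- function(x, ...) {
  cat(sprintf("<fitness_surface: %s, theta = %g, s = %g>\n",
              x$name, x$theta, x$s))
  cat(sprintf("  grid: %d phi x %d I cells (%d failed)\n",
              length(unique(x$grid$phi)), length(unique(x$grid$I)),
              sum(!x$grid$ok)))
  cat(sprintf("  global max: fitness %.6g at phi = %g, I = %g (prevalence %.4g)\n",
              x$global$fitness, x$global$phi, x$global$I, x$global$prevalence))
  if (nrow(x$no_frag)) {
    cat(sprintf("  no-fragmentation max: fitness %.6g at I = %g\n",
                x$no_frag$fitness, x$no_frag$I))
  }
  invisible(x)
}

#' Globally optimal reproductive strategy of a scenario
#'
#' Sweeps every `(theta, s)` pair of the scenario's strategy sets, computes
#' the fitness surface for each, and returns the argmax over all surfaces.
#' Ties are broken towards the lexicographically smallest
#' `(theta, s, phi, I)`.
#'
#' @inheritParams sweep_fitness
#' @param keep_surfaces return all surfaces alongside the optimum.
#' @return List with the optimal `theta`, `s`, `phi`, `I`, the `fitness`
#'   there, the `prevalence`, and (optionally) `surfaces`.
#' @examples
#' \donttest{
#' global_optimum("FRPG-FR")[c("theta", "s", "phi")]
#' }
#' @export
global_optimum <- function(cfg, n_generations = 30, keep_surfaces = FALSE) {
  cfg <- resolve_config(cfg)
  combos <- expand.grid(theta = cfg$theta_set, s = cfg$s_set,
                        KEEP.OUT.ATTRS = FALSE)
  surfaces <- vector("list", nrow(combos))
  cand <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sw <- sweep_fitness(cfg, theta = combos$theta[i], s = combos$s[i],
                        n_generations = n_generations)
    surfaces[[i]] <- sw
    g <- sw$grid[sw$grid$ok, , drop = FALSE]
    g$theta <- combos$theta[i]
    g$s <- combos$s[i]
    cand[[i]] <- g
  }
  all_cells <- do.call(rbind, cand)
  ## argmax with deterministic lexicographic tie-break
  best_fit <- max(all_cells$fitness)
  tied <- all_cells[all_cells$fitness == best_fit, , drop = FALSE]
  tied <- tied[order(tied$theta, tied$s, tied$phi, tied$I), , drop = FALSE]
  best <- tied[1L, ]
  theta_eff <- if (best$phi == 0) 0 else best$theta
  out <- list(theta = theta_eff, s = best$s, phi = best$phi, I = best$I,
              fitness = best$fitness, prevalence = best$prevalence)
  if (keep_surfaces) out$surfaces <- surfaces
  out
}

#' Cancer prevalence along the fragmentation axis
#'
#' For one `(theta, s)` surface, evaluates the cancer prevalence at each
#' per-`phi` optimal cancer-suppression level — the markers of the fitness
#' surface. Purging scenarios show prevalence decreasing in `phi` (frequent
#' fragmentation purges cancer), accumulation scenarios the opposite.
#'
#' @inheritParams sweep_fitness
#' @return Data frame with `phi`, `I` (the per-`phi` optimal suppression),
#'   `prevalence` and `fitness`.
#' @examples
#' \donttest{
#' prevalence_vs_phi("FRPG-FR", theta = 0.7, s = 1.5)
#' }
#' @export
prevalence_vs_phi <- function(cfg, theta = NULL, s = NULL,
                              n_generations = 30) {
  sw <- sweep_fitness(cfg, theta = theta, s = s,
                      n_generations = n_generations)
  sw$per_phi[, c("phi", "I", "prevalence", "fitness")]
}

#' Export a pedigree run trajectory as CSV
#'
#' One row per generation with the subpopulation totals and derived
#' quantities; optionally a long-format depth-resolved table.
#'
#' @param run a [run_pedigree()] result.
#' @param file output CSV path.
#' @param depth_resolved write the long format (`j`, `lineage`, `depth`,
#'   `size`) instead of the per-generation summary. Depth-resolved export
#'   covers the final generation only (earlier generations are summarized
#'   in the trajectory).
#' @return `file`, invisibly.
#' @export
export_trajectory <- function(run, file, depth_resolved = FALSE) {
  stopifnot(inherits(run, "pedigree_run"))
  if (!depth_resolved) return(write_csv17(run$trajectory, file))
  st <- run$final_state
  if (is.null(st)) stop("no final state to export (extinct run)", call. = FALSE)
  j <- max(run$trajectory$j)
  long <- rbind(
    data.frame(j = j, lineage = "NU", depth = 0L, size = st$V),
    data.frame(j = j, lineage = "DU", depth = 0L, size = st$W),
    data.frame(j = j, lineage = "NF", depth = seq_along(st$Z), size = st$Z),
    data.frame(j = j, lineage = "DF", depth = seq_along(st$Q), size = st$Q))
  write_csv17(long[long$size > 0 | long$depth == 0L, ], file)
}

#' Export a fitness surface as CSV
#'
#' @param surface a [sweep_fitness()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
export_surface <- function(surface, file) {
  stopifnot(inherits(surface, "fitness_surface"))
  write_csv17(surface$grid[, c("phi", "I", "fitness", "prevalence")], file)
}
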