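## Search configuration.

#' Search configuration
#'
#' Defaults mirror the benchmark protocol of the docking experiments this
#' engine reproduces: population 50, 27,000 generations, 1.5e6 energy
#' evaluations per docking, elite fraction theta in `[0.01, 0.1]` (default
#' 0.05, the midpoint of that range).  The test suite and the synthetic
#' regression benchmarks use [reducedSearchConfig()], the same protocol scaled
#' to desk size.
#'
#' @param popSize population size P (default 50).
#' @param maxGenerations generation budget G (default 27000).
#' @param maxEvaluations energy-evaluation budget E (default 1.5e6);
#'   termination happens at whichever of G or E is hit first.
#' @param theta elite fraction of the CEP mechanism, in `[0.01, 0.1]`.
#' @param crossoverRate probability a selected pair is crossed (default 0.8).
#' @param mutationRate per-gene mutation probability (default 0.5).  The
#'   default is deliberately aggressive: because CEP shields the elites and
#'   their parents from loss, the rest of the population can afford
#'   near-restart exploration kicks, which is what keeps the search from
#'   stalling in a side basin.
#' @param mutationScaleT,mutationScaleTor,mutationScaleRot mutation step sds:
#'   translation (A), torsion (rad), orientation angle (rad).  The rotational
#'   defaults (3.14 rad) effectively resample the hit gene block.
#' @param selectionPressure linear ranking pressure s in (1, 2].
#' @param lsFraction fraction of the population refined by local search each
#'   generation (default 0.06).
#' @param lsMaxIter Solis-Wets iteration cap (default 300).
#' @param lsRho,lsRhoMin initial and terminal step scales.
#' @param lsSuccessLim,lsFailLim consecutive successes/failures before the
#'   step scale expands/contracts.
#' @param lsScaleT translation step size multiplier inside local search (A).
#' @param seed RNG seed of the run.
#' @return a named list of class `cepdock_config`
#' @export
searchConfig <- function(popSize = 50L,
                         maxGenerations = 27000L,
                         maxEvaluations = 1.5e6,
                         theta = 0.05,
                         crossoverRate = 0.8,
                         mutationRate = 0.5,
                         mutationScaleT = 2.0,
                         mutationScaleTor = 3.14,
                         mutationScaleRot = 3.14,
                         selectionPressure = 1.5,
                         lsFraction = 0.06,
                         lsMaxIter = 300L,
                         lsRho = 1.0,
                         lsRhoMin = 0.01,
                         lsSuccessLim = 4L,
                         lsFailLim = 4L,
                         lsScaleT = 1.0,
                         seed = 1L) {
  cfg <- list(popSize = as.integer(popSize),
              maxGenerations = as.integer(maxGenerations),
              maxEvaluations = maxEvaluations,
              theta = theta,
              crossoverRate = crossoverRate,
              mutationRate = mutationRate,
              mutationScaleT = mutationScaleT,
              mutationScaleTor = mutationScaleTor,
              mutationScaleRot = mutationScaleRot,
              selectionPressure = selectionPressure,
              lsFraction = lsFraction,
              lsMaxIter = as.integer(lsMaxIter),
              lsRho = lsRho,
              lsRhoMin = lsRhoMin,
              lsSuccessLim = as.integer(lsSuccessLim),
              lsFailLim = as.integer(lsFailLim),
              lsScaleT = lsScaleT,
              seed = as.integer(seed))
  validateConfig(cfg)
  structure(cfg, class = "cepdock_config")
}

validateConfig <- function(cfg) {
  stopifnot(cfg$popSize >= 2L,
            cfg$maxGenerations >= 0L,
            cfg$maxEvaluations > 0,
            cfg$crossoverRate >= 0, cfg$crossoverRate <= 1,
            cfg$mutationRate >= 0, cfg$mutationRate <= 1,
            cfg$selectionPressure > 1, cfg$selectionPressure <= 2,
            cfg$lsFraction >= 0, cfg$lsFraction <= 1)
  if (cfg$theta < 0.01 || cfg$theta > 0.1)
    stop("theta must lie in [0.01, 0.1]")
  nE <- as.integer(ceiling(cfg$theta * cfg$popSize))
  if (3L * nE > cfg$popSize)
    stop(sprintf("CEP infeasible: 3 * ceiling(theta * P) = %d > P = %d",
                 3L * nE, cfg$popSize))
  invisible(cfg)
}

#' Reduced-budget configuration for desk-scale benchmarks
#'
#' The same search protocol as [searchConfig()] with the budget scaled down
#' for synthetic fixtures: population 50, 500 generations, 150,000
#' evaluations (the evaluation cost of 500 generations under the default
#' local-search schedule), and a lighter local search (50 iterations).
#'
#' @param ... overrides passed to [searchConfig()].
#' @return a `cepdock_config`
#' @export
reducedSearchConfig <- function(...) {
  defaults <- list(popSize = 50L, maxGenerations = 500L,
                   maxEvaluations = 150000, lsMaxIter = 50L)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(searchConfig, defaults)
}

#' Read a search configuration from a YAML file
#'
#' Keys mirror the [searchConfig()] argument names; missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a `cepdock_config`
#' @export
readSearchConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(searchConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(searchConfig, vals)
}

#' @export
print.cepdock_config <- function(x, ...) {
  cat(sprintf(
    "cepdock search config: P=%d, G=%d, E=%g, theta=%.3f (elites %d), seed=%d\n",
    x$popSize, x$maxGenerations, x$maxEvaluations, x$theta,
    ceiling(x$theta * x$popSize), x$seed))
  invisible(x)
}
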