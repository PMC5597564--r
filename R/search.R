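## Search module: rank selection, one-point crossover, real mutation, the
## crossover elitist preservation (CEP) mechanism, Solis-Wets local search,
## and the CEPGA / plain-GA generational drivers.
##
## Populations are plain lists of individuals; an individual is
## list(genome, energy, father, mother) where father/mother are the parent
## individuals (with their cached energies) from the generation that produced
## it, or NULL for generation 0 (generation-0 individuals preserve
## themselves).  A single seeded RNG (R's global generator, seeded once per
## run) is threaded through every operator; draws happen in the documented
## order: parent selection, crossover cut points, CEP replacement slots,
## mutation, local search.

#' Create an individual
#' @param genome numeric genome.
#' @param energy cached energy (NA until evaluated).
#' @param father,mother parent individuals, or NULL for generation 0.
#' @return a list of class `cepdock_individual`
#' @export
newIndividual <- function(genome, energy = NA_real_, father = NULL, mother = NULL) {
  structure(list(genome = genome, energy = energy,
                 father = father, mother = mother),
            class = "cepdock_individual")
}

#' Linear rank-selection probabilities
#'
#' Individuals are sorted by energy ascending (best = lowest, rank 0) and the
#' selection probability decreases linearly with rank:
#' `p_i = (s - (2s - 2) * rank_i / (P - 1)) / P` with selection pressure
#' `s` in (1, 2].  Lower energy always means strictly higher probability;
#' ties are broken by stable sort order.
#'
#' @param P population size.
#' @param s selection pressure (default 1.5).
#' @return numeric vector of probabilities by rank (best first), summing to 1
#' @export
rankProbs <- function(P, s = 1.5) {
  stopifnot(P >= 1, s > 1, s <= 2)
  if (P == 1L) return(1)
  (s - (2 * s - 2) * (seq_len(P) - 1) / (P - 1)) / P
}

#' Rank ("sort") selection
#'
#' Draws `n` population indices with linear rank probabilities.
#'
#' @param energies numeric vector of the population's energies.
#' @param n number of draws.
#' @param s selection pressure, see [rankProbs()].
#' @return integer vector of selected population indices
#' @export
rankSelect <- function(energies, n = 1L, s = 1.5) {
  P <- length(energies)
  if (P == 0L) stop("cannot select from an empty population")
  if (P == 1L) return(rep(1L, n))
  ## tied energies share the average of their ranks' probabilities, so
  ## all-equal populations are selected uniformly
  r <- rank(energies, ties.method = "average") - 1
  p <- (s - (2 * s - 2) * r / (P - 1)) / P
  sample.int(P, n, replace = TRUE, prob = p)
}

#' One-point crossover
#'
#' Cuts both genomes at a gene boundary `k` drawn uniformly from
#' `1..L-1` and swaps the tails.  If the cut splits the orientation block of
#' a pose genome, both children's quaternions are renormalized.
#'
#' @param a,b parent genomes (equal length).
#' @param genomeSpec genome structure (a context's `$genomeSpec`); NULL means
#'   a plain vector genome.
#' @param cut optional forced cut point (tests); default random.
#' @return list with `childA`, `childB`, `cut`
#' @export
onePointCrossover <- function(a, b, genomeSpec = NULL, cut = NULL) {
  L <- length(a)
  if (length(b) != L) stop("parent genomes differ in length")
  if (L < 2L) return(list(childA = a, childB = b, cut = NA_integer_))
  k <- if (is.null(cut)) sample.int(L - 1L, 1L) else as.integer(cut)
  ca <- c(a[seq_len(k)], b[seq.int(k + 1L, L)])
  cb <- c(b[seq_len(k)], a[seq.int(k + 1L, L)])
  if (!is.null(genomeSpec) && genomeSpec$kind == "pose" && k >= 4L && k <= 6L) {
    ca[QUAT] <- ca[QUAT] / sqrt(sum(ca[QUAT]^2))
    cb[QUAT] <- cb[QUAT] / sqrt(sum(cb[QUAT]^2))
  }
  list(childA = ca, childB = cb, cut = k)
}

#' Real-coded mutation
#'
#' Each gene is independently perturbed with probability `rate`:
#' translation genes get Gaussian noise (sd `scaleT`, clamped to the search
#' box), torsion genes get Gaussian noise (sd `scaleTor`, wrapped to
#' `(-pi, pi]`), and the orientation block is treated as one unit - with
#' probability `rate` it is composed with a small random rotation (angle sd
#' `scaleRot`) and renormalized.  Box genomes use `scaleT` and clamp to their
#' bounds.
#'
#' @param genome numeric genome.
#' @param genomeSpec genome structure (a context's `$genomeSpec`).
#' @param rate per-gene mutation probability in `[0, 1]`.
#' @param scaleT translation sd (A); default 2.0.
#' @param scaleTor torsion sd (rad); default 0.35.
#' @param scaleRot orientation rotation angle sd (rad); default 0.35.
#' @return list with `genome` and logical `changed`
#' @export
realMutation <- function(genome, genomeSpec, rate, scaleT = 2.0,
                         scaleTor = 0.35, scaleRot = 0.35) {
  stopifnot(rate >= 0, rate <= 1)
  g <- genome
  changed <- FALSE
  if (genomeSpec$kind == "pose") {
    hitT <- runif(3) < rate
    if (any(hitT)) {
      g[1:3][hitT] <- g[1:3][hitT] + rnorm(sum(hitT), 0, scaleT)
      g[1:3] <- clampTranslation(g[1:3], genomeSpec)
      changed <- TRUE
    }
    if (runif(1) < rate) {
      axis <- rnorm(3)
      dq <- axisAngleQuat(axis, rnorm(1, 0, scaleRot))
      q <- quatMultiply(dq, g[QUAT])
      g[QUAT] <- q / sqrt(sum(q^2))
      changed <- TRUE
    }
    nt <- genomeSpec$nTorsions
    if (nt > 0L) {
      hit <- runif(nt) < rate
      if (any(hit)) {
        idx <- 7L + which(hit)
        g[idx] <- wrapAngle(g[idx] + rnorm(sum(hit), 0, scaleTor))
        changed <- TRUE
      }
    }
  } else {
    hit <- runif(length(g)) < rate
    if (any(hit)) {
      g[hit] <- g[hit] + rnorm(sum(hit), 0, scaleT)
      g <- pmin(pmax(g, genomeSpec$lower), genomeSpec$upper)
      changed <- TRUE
    }
  }
  list(genome = g, changed = changed)
}

#' Elite and preserved-parent counts of the CEP mechanism
#'
#' The number of elitist individuals is `ceiling(theta * P)` (theta times the
#' population size, rounded up), and each elite contributes its two parents,
#' so `2 * ceiling(theta * P)` parents are preserved.  The mechanism is
#' feasible only when elites plus preserved parents fit the population:
#' `3 * ceiling(theta * P) <= P`.
#'
#' @param theta elite fraction, in `[0.01, 0.1]`.
#' @param P population size.
#' @return named integer vector `c(elites, parents)`
#' @export
cepCounts <- function(theta, P) {
  stopifnot(theta >= 0.01, theta <= 0.1, P >= 1)
  nE <- as.integer(ceiling(theta * P))
  c(elites = nE, parents = 2L * nE)
}

#' Crossover elitist preservation update
#'
#' Given the evaluated offspring generation and the elitist records (each the
#' generation's elite individual together with its preserved father and
#' mother), the preserved parents replace distinct, uniformly chosen
#' non-elite members of the offspring.  Elites are never replaced, and the
#' population size is conserved: the returned population contains every elite
#' and every preserved parent.
#'
#' @param offspring list of individuals ([newIndividual()]), all evaluated.
#' @param eliteIdx integer indices of the elite individuals within
#'   `offspring` (the `ceiling(theta * P)` best).
#' @param records list of `list(father = , mother = )` individuals, one per
#'   elite, in elite order.
#' @param slots optional forced replacement slot indices (length
#'   `2 * length(records)`, non-elite, distinct); default drawn uniformly
#'   without replacement from the non-elite slots.
#' @return the updated population (same size)
#' @export
cepUpdate <- function(offspring, eliteIdx, records, slots = NULL) {
  P <- length(offspring)
  need <- 2L * length(records)
  nonElite <- setdiff(seq_len(P), eliteIdx)
  if (length(nonElite) < need)
    stop(sprintf(
      "CEP infeasible: %d elites + %d preserved parents exceed population %d",
      length(eliteIdx), need, P))
  if (is.null(slots)) {
    slots <- nonElite[sample.int(length(nonElite), need)]
  } else {
    slots <- as.integer(slots)
    if (length(slots) != need || anyDuplicated(slots) ||
        any(slots %in% eliteIdx) || any(slots < 1L | slots > P))
      stop("invalid forced replacement slots")
  }
  for (k in seq_along(records)) {
    offspring[[slots[2L * k - 1L]]] <- records[[k]]$father
    offspring[[slots[2L * k]]] <- records[[k]]$mother
  }
  offspring
}

## Solis-Wets step proposal for one genome; returns a delta object that can
## be applied with either sign.
drawDelta <- function(gs, rho, scaleT, scaleTor, scaleRot) {
  if (gs$kind == "pose") {
    list(dt = rnorm(3, 0, rho * scaleT),
         axis = rnorm(3),
         angle = rnorm(1, 0, rho * scaleRot),
         dtor = if (gs$nTorsions > 0L) rnorm(gs$nTorsions, 0, rho * scaleTor)
                else numeric())
  } else {
    list(dg = rnorm(gs$nGenes, 0, rho * scaleT))
  }
}

applyDelta <- function(genome, delta, sign, gs) {
  g <- genome
  if (gs$kind == "pose") {
    g[1:3] <- clampTranslation(g[1:3] + sign * delta$dt, gs)
    dq <- axisAngleQuat(delta$axis, sign * delta$angle)
    q <- quatMultiply(dq, g[QUAT])
    g[QUAT] <- q / sqrt(sum(q^2))
    if (length(delta$dtor))
      g[seq.int(8L, length(g))] <- wrapAngle(g[seq.int(8L, length(g))] + sign * delta$dtor)
  } else {
    g <- pmin(pmax(g + sign * delta$dg, gs$lower), gs$upper)
  }
  g
}

#' Solis-Wets local search (Lamarckian)
#'
#' Adaptive random-walk refinement: propose a Gaussian step of scale `rho`,
#' accept it only if the energy strictly decreases, otherwise test the
#' opposite step; after `successLim` consecutive successes `rho` doubles,
#' after `failLim` consecutive failures it halves.  Stops after `maxIter`
#' iterations, when `rho` falls below `rhoMin`, or when the evaluation budget
#' runs out (returning the best point so far).  The improved genome is
#' written back (Lamarckian): the returned energy is never worse than the
#' input.
#'
#' @param genome starting genome.
#' @param energy its energy (evaluated if NA; that evaluation counts).
#' @param ctx evaluation context.
#' @param maxIter maximum iterations (default 300).
#' @param rho initial step scale (default 1.0).
#' @param rhoMin termination scale (default 0.01).
#' @param successLim,failLim adaptation counters (default 4).
#' @param scaleT,scaleTor,scaleRot per-block step sizes multiplied by `rho`.
#' @return list with `genome`, `energy`, `iterations`
#' @export
localSearch <- function(genome, energy, ctx, maxIter = 300L, rho = 1.0,
                        rhoMin = 0.01, successLim = 4L, failLim = 4L,
                        scaleT = 1.0, scaleTor = 0.35, scaleRot = 0.35) {
  gs <- ctx$genomeSpec
  if (maxIter <= 0L)
    return(list(genome = genome, energy = energy, iterations = 0L))
  x <- genome
  fx <- if (is.na(energy)) {
    if (budgetLeft(ctx) < 1) return(list(genome = genome, energy = energy,
                                         iterations = 0L))
    evaluateGenome(x, ctx)
  } else energy
  succ <- 0L; fail <- 0L; it <- 0L
  while (it < maxIter && rho >= rhoMin) {
    if (budgetLeft(ctx) < 1) break
    it <- it + 1L
    delta <- drawDelta(gs, rho, scaleT, scaleTor, scaleRot)
    y <- applyDelta(x, delta, 1, gs)
    fy <- evaluateGenome(y, ctx)
    if (fy < fx) {
      x <- y; fx <- fy; succ <- succ + 1L; fail <- 0L
    } else {
      if (budgetLeft(ctx) < 1) break
      y2 <- applyDelta(x, delta, -1, gs)
      fy2 <- evaluateGenome(y2, ctx)
      if (fy2 < fx) {
        x <- y2; fx <- fy2; succ <- succ + 1L; fail <- 0L
      } else {
        fail <- fail + 1L; succ <- 0L
      }
    }
    if (succ >= successLim) { rho <- rho * 2; succ <- 0L }
    if (fail >= failLim) { rho <- rho / 2; fail <- 0L }
  }
  list(genome = x, energy = fx, iterations = it)
}

## Evaluate every individual with a missing cached energy.  Returns
## list(pop, exhausted).
evaluatePopulation <- function(pop, ctx) {
  exhausted <- FALSE
  for (i in seq_along(pop)) {
    if (!is.na(pop[[i]]$energy)) next
    e <- tryCatch(evaluateGenome(pop[[i]]$genome, ctx),
                  cepdock_budget_exhausted = function(c) NA_real_)
    if (is.na(e)) { exhausted <- TRUE; break }
    pop[[i]]$energy <- e
  }
  list(pop = pop, exhausted = exhausted)
}

#' Run the CEPGA search
#'
#' Generational loop: rank-select parent pairs and apply one-point crossover
#' to breed the offspring; evaluate them; identify the `ceiling(theta * P)`
#' elitist offspring and preserve the parents that produced them, re-injecting
#' those parents into the offspring in place of randomly chosen non-elite
#' members (CEP); mutate the non-elite members; refine the best configured
#' fraction by Lamarckian Solis-Wets local search.  Terminates at
#' `maxGenerations` or when `maxEvaluations` is exhausted, whichever comes
#' first, and returns the best individual ever evaluated together with the
#' improvement trace.
#'
#' @param ctx a [dockingContext()] or [objectiveContext()].  The context's
#'   evaluation budget is tightened to `config$maxEvaluations` if that is
#'   smaller.
#' @param config a [searchConfig()].
#' @param useCEP,useLS internal ablation switches; prefer [runGA()].
#' @param algorithm label stored in the result.
#' @return a [DockingRun-class]
#' @export
runCEPGA <- function(ctx, config = searchConfig(), useCEP = TRUE, useLS = TRUE,
                     algorithm = if (useCEP) "cepga" else if (useLS) "ga+ls" else "ga") {
  P <- config$popSize
  if (P < 2L) stop("population size must be at least 2 (crossover needs two parents)")
  if (useCEP) {
    nE <- cepCounts(config$theta, P)[["elites"]]
    if (3L * nE > P)
      stop(sprintf("CEP infeasible at config time: 3 * ceiling(theta * P) = %d > P = %d",
                   3L * nE, P))
  } else nE <- 0L
  if (is.finite(config$maxEvaluations))
    ctx$maxEvaluations <- min(ctx$maxEvaluations, ctx$count + config$maxEvaluations)
  set.seed(config$seed)
  gs <- ctx$genomeSpec

  pop <- lapply(seq_len(P), function(i) newIndividual(randomGenome(ctx)))
  ev <- evaluatePopulation(pop, ctx)
  pop <- ev$pop
  exhausted <- ev$exhausted
  gen <- 0L

  while (!exhausted && gen < config$maxGenerations) {
    gen <- gen + 1L
    energies <- vapply(pop, `[[`, numeric(1), "energy")

    ## breed: rank selection + one-point crossover
    nPairs <- ceiling(P / 2)
    parentIdx <- rankSelect(energies, 2L * nPairs, s = config$selectionPressure)
    offspring <- vector("list", P)
    oi <- 0L
    for (p in seq_len(nPairs)) {
      ia <- parentIdx[2L * p - 1L]; ib <- parentIdx[2L * p]
      pa <- pop[[ia]]; pb <- pop[[ib]]
      if (runif(1) < config$crossoverRate) {
        cx <- onePointCrossover(pa$genome, pb$genome, gs)
        ga <- cx$childA; gb <- cx$childB
        ea <- NA_real_; eb <- NA_real_
      } else {
        ga <- pa$genome; gb <- pb$genome
        ea <- pa$energy; eb <- pb$energy   # clones keep their cached energy
      }
      ## parents are recorded as genome + cached energy only: ancestry does
      ## not chain beyond one generation
      fa <- newIndividual(pa$genome, pa$energy)
      mo <- newIndividual(pb$genome, pb$energy)
      oi <- oi + 1L
      offspring[[oi]] <- newIndividual(ga, ea, father = fa, mother = mo)
      if (oi < P) {
        oi <- oi + 1L
        offspring[[oi]] <- newIndividual(gb, eb, father = fa, mother = mo)
      }
    }

    ev <- evaluatePopulation(offspring, ctx)
    offspring <- ev$pop
    if (ev$exhausted) { exhausted <- TRUE; break }

    ## CEP: elites of the evaluated offspring; preserve and re-inject their
    ## parents (cached parent energies are reused, not re-evaluated)
    eliteIdx <- integer()
    if (useCEP) {
      energies <- vapply(offspring, `[[`, numeric(1), "energy")
      eliteIdx <- order(energies)[seq_len(nE)]
      records <- lapply(eliteIdx, function(i) {
        ind <- offspring[[i]]
        if (is.null(ind$father))   # generation-0 parents: self-preservation
          list(father = newIndividual(ind$genome, ind$energy),
               mother = newIndividual(ind$genome, ind$energy))
        else list(father = ind$father, mother = ind$mother)
      })
      offspring <- cepUpdate(offspring, eliteIdx, records)
    }

    ## mutation (elites immune when CEP is on)
    for (i in setdiff(seq_len(P), eliteIdx)) {
      mu <- realMutation(offspring[[i]]$genome, gs, config$mutationRate,
                         config$mutationScaleT, config$mutationScaleTor,
                         config$mutationScaleRot)
      if (mu$changed) {
        offspring[[i]]$genome <- mu$genome
        offspring[[i]]$energy <- NA_real_
      }
    }
    ev <- evaluatePopulation(offspring, ctx)
    offspring <- ev$pop
    if (ev$exhausted) { exhausted <- TRUE; pop <- offspring; break }

    ## Lamarckian local search on the best fraction
    if (useLS && config$lsFraction > 0 && config$lsMaxIter > 0L) {
      nLS <- max(1L, round(config$lsFraction * P))
      energies <- vapply(offspring, `[[`, numeric(1), "energy")
      for (i in order(energies)[seq_len(nLS)]) {
        res <- tryCatch(
          localSearch(offspring[[i]]$genome, offspring[[i]]$energy, ctx,
                      maxIter = config$lsMaxIter, rho = config$lsRho,
                      rhoMin = config$lsRhoMin,
                      successLim = config$lsSuccessLim,
                      failLim = config$lsFailLim,
                      scaleT = config$lsScaleT,
                      scaleTor = config$mutationScaleTor,
                      scaleRot = config$mutationScaleRot),
          cepdock_budget_exhausted = function(c) NULL)
        if (is.null(res)) { exhausted <- TRUE; break }
        offspring[[i]]$genome <- res$genome
        offspring[[i]]$energy <- res$energy
      }
    }
    pop <- offspring
  }

  finalizeRun(ctx, config, gen, algorithm)
}

#' Run the baseline genetic algorithm
#'
#' Identical loop to [runCEPGA()] with the CEP mechanism disabled and,
#' optionally, local search disabled too, so that paired runs isolate the
#' contribution of CEP.
#'
#' @inheritParams runCEPGA
#' @param withLocalSearch keep the Lamarckian local search (the "ga+ls" arm)?
#' @return a [DockingRun-class]
#' @export
runGA <- function(ctx, config = searchConfig(), withLocalSearch = FALSE) {
  runCEPGA(ctx, config, useCEP = FALSE, useLS = withLocalSearch,
           algorithm = if (withLocalSearch) "ga+ls" else "ga")
}

finalizeRun <- function(ctx, config, gen, algorithm) {
  rmsd <- NA_real_
  if (!is.null(ctx$reference) && !is.null(ctx$bestGenome))
    rmsd <- ligandRmsd(ctx$bestGenome, ctx$reference, ctx$topo)
  new("DockingRun",
      algorithm = algorithm,
      seed = as.integer(config$seed),
      bestGenome = as.numeric(ctx$bestGenome),
      bestEnergy = ctx$bestEnergy,
      finalRmsd = rmsd,
      evaluations = as.integer(ctx$count),
      generations = as.integer(gen),
      trace = data.frame(neval = ctx$traceNeval, energy = ctx$traceEnergy))
}
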