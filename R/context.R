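## Objective contexts: the mutable state threaded through a search run.
##
## A context is an environment holding the objective function, the genome
## structure ("pose" genomes carry quaternion/torsion semantics; "box"
## genomes are plain bounded vectors used by the analytic test landscapes),
## the monotone evaluation counter with its budget, and the best-so-far
## bookkeeping that yields the run trace.

#' Docking objective context
#'
#' Binds a ligand topology, receptor, and energy model into an evaluation
#' context: each [evaluateGenome()] call decodes the genome, scores the pose,
#' increments the evaluation counter, and updates the best-so-far trace.
#'
#' @param topo a [LigandTopology-class].
#' @param receptor a [ReceptorModel-class] (its box bounds the translation
#'   genes).
#' @param model an [EnergyModel-class].
#' @param maxEvaluations evaluation budget; the 1 + budget-th call signals a
#'   `cepdock_budget_exhausted` condition.
#' @param reference optional n x 3 reference coordinates; when present, runs
#'   report heavy-atom RMSD of their best pose against it.
#' @return an environment of class `cepdock_context`
#' @export
dockingContext <- function(topo, receptor, model = defaultEnergyModel(),
                           maxEvaluations = Inf, reference = NULL) {
  setup <- scoringSetup(topo, receptor, model)
  ctx <- newContext(
    objective = setup$fast,
    genomeSpec = list(
      kind = "pose",
      nTorsions = nTorsions(topo),
      boxCenter = receptor@boxCenter,
      boxHalf = receptor@boxHalf,
      rootCentroid = colMeans(topo@refCoords[topo@rootAtoms, , drop = FALSE])
    ),
    maxEvaluations = maxEvaluations)
  ctx$topo <- topo
  ctx$receptor <- receptor
  ctx$model <- model
  ctx$reference <- reference
  ctx
}

#' Generic objective context (test landscapes)
#'
#' @param fn objective: function(genome) -> scalar energy.
#' @param nGenes genome length.
#' @param lower,upper bounds (recycled to `nGenes`); mutation and
#'   initialization stay inside them.
#' @param maxEvaluations evaluation budget.
#' @return an environment of class `cepdock_context`
#' @export
objectiveContext <- function(fn, nGenes, lower = -5.12, upper = 5.12,
                             maxEvaluations = Inf) {
  newContext(
    objective = fn,
    genomeSpec = list(kind = "box", nGenes = as.integer(nGenes),
                      lower = rep_len(lower, nGenes),
                      upper = rep_len(upper, nGenes)),
    maxEvaluations = maxEvaluations)
}

newContext <- function(objective, genomeSpec, maxEvaluations) {
  ctx <- new.env(parent = emptyenv())
  ctx$objective <- objective
  ctx$genomeSpec <- genomeSpec
  ctx$maxEvaluations <- maxEvaluations
  ctx$count <- 0L
  ctx$bestEnergy <- Inf
  ctx$bestGenome <- NULL
  ctx$traceNeval <- numeric()
  ctx$traceEnergy <- numeric()
  class(ctx) <- c("cepdock_context", "environment")
  ctx
}

budgetExhaustedCondition <- function(count) {
  structure(
    class = c("cepdock_budget_exhausted", "error", "condition"),
    list(message = sprintf("evaluation budget exhausted after %d evaluations", count),
         call = NULL))
}

#' Evaluate a genome within a context
#'
#' Increments the evaluation counter exactly once per call and updates the
#' context's best-so-far record (the run trace).  Results are never cached
#' here; individuals carry their own cached energies, and re-using a cached
#' energy does not touch the counter.
#'
#' @param genome numeric genome.
#' @param ctx a context from [dockingContext()] or [objectiveContext()].
#' @return scalar energy
#' @export
evaluateGenome <- function(genome, ctx) {
  if (ctx$count >= ctx$maxEvaluations)
    stop(budgetExhaustedCondition(ctx$count))
  e <- ctx$objective(genome)
  ctx$count <- ctx$count + 1L
  if (e < ctx$bestEnergy) {
    ctx$bestEnergy <- e
    ctx$bestGenome <- genome
    ctx$traceNeval <- c(ctx$traceNeval, ctx$count)
    ctx$traceEnergy <- c(ctx$traceEnergy, e)
  }
  e
}

#' Evaluations consumed / remaining budget of a context
#' @param ctx a context
#' @return integer count
#' @export
evaluationCount <- function(ctx) ctx$count

#' @rdname evaluationCount
#' @export
budgetLeft <- function(ctx) ctx$maxEvaluations - ctx$count

#' Draw a uniformly random genome for a context
#'
#' Pose genomes: root centroid uniform in the search box, uniform random
#' orientation (Shoemake quaternion), torsions uniform on `(-pi, pi]`.
#' Box genomes: uniform within bounds.
#'
#' @param ctx a context
#' @return numeric genome
#' @export
randomGenome <- function(ctx) {
  gs <- ctx$genomeSpec
  if (gs$kind == "pose") {
    pos <- gs$boxCenter + runif(3, -1, 1) * gs$boxHalf
    u <- runif(3)
    q <- c(sqrt(u[1]) * cos(2 * pi * u[3]),
           sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]))
    tors <- wrapAngle(runif(gs$nTorsions, -pi, pi))
    newGenome(pos - gs$rootCentroid, q, tors)
  } else {
    runif(gs$nGenes, gs$lower, gs$upper)
  }
}

## Clamp the translation genes so the ligand root centroid stays in the box.
clampTranslation <- function(trans, gs) {
  pos <- gs$rootCentroid + trans
  pos <- pmin(pmax(pos, gs$boxCenter - gs$boxHalf), gs$boxCenter + gs$boxHalf)
  pos - gs$rootCentroid
}
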