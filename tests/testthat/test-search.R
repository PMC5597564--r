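test_that("linear rank probabilities follow the closed form", {
  expect_identical(rankProbs(2, s = 1.5), c(0.75, 0.25))
  expect_equal(sum(rankProbs(50)), 1, tolerance = 1e-12)
  ## strictly decreasing with rank
  expect_true(all(diff(rankProbs(50)) < 0))
})

test_that("rank selection matches its theoretical distribution", {
  ## equal energies: selection is uniform (ranks broken by stable order)
  set.seed(1)
  picks <- rankSelect(rep(1, 10), n = 2e4)
  freq <- tabulate(picks, 10) / 2e4
  se <- sqrt(0.1 * 0.9 / 2e4)
  expect_true(all(abs(freq - 0.1) < 4 * se))
  ## P = 50: empirical frequency of best and worst within 3 sigma
  set.seed(2)
  energies <- rnorm(50)
  picks <- rankSelect(energies, n = 1e5)
  pBest <- rankProbs(50)[1]
  pWorst <- rankProbs(50)[50]
  fBest <- mean(picks == which.min(energies))
  fWorst <- mean(picks == which.max(energies))
  expect_lt(abs(fBest - pBest), 3 * sqrt(pBest * (1 - pBest) / 1e5))
  expect_lt(abs(fWorst - pWorst), 3 * sqrt(pWorst * (1 - pWorst) / 1e5))
  expect_error(rankSelect(numeric()), "empty")
})

test_that("one-point crossover swaps tails at the cut", {
  a <- 1:5 + 0.0; b <- 11:15 + 0.0
  cx <- onePointCrossover(a, b, cut = 2)
  expect_identical(cx$childA, c(1, 2, 13, 14, 15))
  expect_identical(cx$childB, c(11, 12, 3, 4, 5))
  ## identical parents reproduce themselves for every cut point
  for (k in 1:4) {
    cx <- onePointCrossover(a, a, cut = k)
    expect_identical(cx$childA, a)
    expect_identical(cx$childB, a)
  }
  ## gene multiset conserved across all cut points on L = 7
  a7 <- rnorm(7); b7 <- rnorm(7)
  for (k in 1:6) {
    cx <- onePointCrossover(a7, b7, cut = k)
    expect_identical(sort(c(cx$childA, cx$childB)), sort(c(a7, b7)))
  }
  ## degenerate length: copies
  short <- onePointCrossover(1, 2)
  expect_identical(short$childA, 1)
  ## quaternion renormalized when the cut splits the orientation block
  spec <- list(kind = "pose", nTorsions = 1L)
  pa <- newGenome(c(0, 0, 0), c(1, 0, 0, 0), 0.3)
  pb <- newGenome(c(1, 1, 1), c(0, 1, 0, 0), -0.5)
  cx <- onePointCrossover(pa, pb, genomeSpec = spec, cut = 5)
  expect_equal(sum(cx$childA[4:7]^2), 1, tolerance = 1e-9)
  expect_equal(sum(cx$childB[4:7]^2), 1, tolerance = 1e-9)
})

test_that("real mutation honors its rate and wraps torsions", {
  spec <- list(kind = "pose", nTorsions = 3L,
               boxCenter = c(0, 0, 0), boxHalf = c(10, 10, 10),
               rootCentroid = c(0, 0, 0))
  g <- newGenome(c(1, 2, 3), c(1, 0, 0, 0), c(0.1, -0.2, 0.3))
  set.seed(1)
  m0 <- realMutation(g, spec, rate = 0)
  expect_identical(m0$genome, g)
  expect_false(m0$changed)
  ## rate 1 with vanishing scales: numerically the identity
  set.seed(1)
  m1 <- realMutation(g, spec, rate = 1, scaleT = 1e-12, scaleTor = 1e-12,
                     scaleRot = 1e-12)
  expect_equal(m1$genome, g, tolerance = 1e-9)
  ## mass wrap check + folded-normal mean displacement
  nT <- 10000L
  bigSpec <- list(kind = "pose", nTorsions = nT,
                  boxCenter = c(0, 0, 0), boxHalf = c(10, 10, 10),
                  rootCentroid = c(0, 0, 0))
  gBig <- c(rep(0, 3), c(1, 0, 0, 0), rep(0, nT))
  set.seed(7)
  mBig <- realMutation(gBig, bigSpec, rate = 1, scaleTor = 0.35)
  tors <- mBig$genome[-(1:7)]
  expect_true(all(tors > -pi & tors <= pi))
  disp <- abs(tors)
  expected <- 0.35 * sqrt(2 / pi)           # folded-normal mean, no wrap mass
  se <- sd(disp) / sqrt(nT)
  expect_lt(abs(mean(disp) - expected), 3 * se)
  ## translations stay inside the box
  tightSpec <- modifyList(bigSpec, list(nTorsions = 0L, boxHalf = c(1, 1, 1)))
  set.seed(8)
  for (i in 1:20) {
    m <- realMutation(c(0.9, 0.9, 0.9, 1, 0, 0, 0), tightSpec, rate = 1,
                      scaleT = 5)
    pos <- m$genome[1:3]
    expect_true(all(pos >= -1 - 1e-12 & pos <= 1 + 1e-12))
  }
})

test_that("CEP counts follow the ceiling rule", {
  expect_identical(cepCounts(0.1, 50), c(elites = 5L, parents = 10L))
  expect_identical(cepCounts(0.01, 50), c(elites = 1L, parents = 2L))
  expect_identical(cepCounts(0.05, 50), c(elites = 3L, parents = 6L))
  expect_error(cepCounts(0.2, 50))
  ## infeasible configurations are rejected at config time
  expect_error(searchConfig(popSize = 2, theta = 0.1), "infeasible")
})

test_that("CEP reproduces the worked six-individual example", {
  mk <- function(name, e) newIndividual(genome = as.numeric(charToRaw(name)),
                                        energy = e)
  p1a <- mk("1a", -1); p1b <- mk("1b", -2)
  off <- list(mk("2a", -10), mk("2b", -1), mk("2c", -2),
              mk("2d", -3), mk("2e", -4), mk("2f", -5))
  upd <- cepUpdate(off, eliteIdx = 1L,
                   records = list(list(father = p1a, mother = p1b)),
                   slots = c(2L, 3L))
  expect_identical(upd[[1]], off[[1]])   # the elite is untouched
  expect_identical(upd[[2]], p1a)        # preserved father
  expect_identical(upd[[3]], p1b)        # preserved mother
  expect_identical(upd[4:6], off[4:6])   # everyone else untouched
  expect_length(upd, 6L)
})

test_that("CEP never displaces an elite and conserves size", {
  set.seed(99)
  for (rep in 1:1000) {
    P <- sample(10:50, 1)
    theta <- runif(1, 0.01, 0.1)
    nE <- ceiling(theta * P)
    if (3 * nE > P) next
    pop <- lapply(seq_len(P), function(i)
      newIndividual(rnorm(3), energy = rnorm(1)))
    eliteIdx <- order(vapply(pop, `[[`, numeric(1), "energy"))[seq_len(nE)]
    records <- lapply(seq_len(nE), function(k)
      list(father = newIndividual(rnorm(3), -100 - k),
           mother = newIndividual(rnorm(3), -200 - k)))
    upd <- cepUpdate(pop, eliteIdx, records)
    expect_length(upd, P)
    for (i in eliteIdx) expect_identical(upd[[i]], pop[[i]])
    for (rec in records) {
      expect_true(any(vapply(upd, identical, logical(1), rec$father)))
      expect_true(any(vapply(upd, identical, logical(1), rec$mother)))
    }
  }
  ## not enough non-elite slots -> error
  pop4 <- lapply(1:4, function(i) newIndividual(rnorm(2), i))
  recs2 <- lapply(1:2, function(k) list(father = pop4[[1]], mother = pop4[[2]]))
  expect_error(cepUpdate(pop4, eliteIdx = c(1L, 2L), records = recs2),
               "infeasible")
})

test_that("Solis-Wets local search descends and respects its contract", {
  ## 1-gene quadratic: contraction brings |x| below 0.1 within 100 iterations
  ctx <- objectiveContext(function(g) g[1]^2, nGenes = 1)
  set.seed(123)
  res <- localSearch(1, NA_real_, ctx, maxIter = 100)
  expect_lt(abs(res$genome), 0.1)
  expect_lte(res$energy, 1)
  ## never worsens: start at the optimum of a bowl
  ctx2 <- objectiveContext(function(g) sum(g^2), nGenes = 3)
  set.seed(5)
  res2 <- localSearch(c(0, 0, 0), NA_real_, ctx2, maxIter = 50, rho = 0.1)
  expect_lte(res2$energy, 1e-12)
  ## no-op when maxIter = 0, consuming zero evaluations
  ctx3 <- objectiveContext(function(g) sum(g^2), nGenes = 2)
  res3 <- localSearch(c(1, 1), 2, ctx3, maxIter = 0)
  expect_identical(res3$genome, c(1, 1))
  expect_identical(evaluationCount(ctx3), 0L)
  ## budget exhaustion returns the best point so far
  ctx4 <- objectiveContext(function(g) sum(g^2), nGenes = 2, maxEvaluations = 5)
  set.seed(6)
  res4 <- localSearch(c(1, 1), NA_real_, ctx4, maxIter = 100)
  expect_identical(evaluationCount(ctx4), 5L)
  expect_lte(res4$energy, 2)
})

test_that("zero generations returns the best of the random population", {
  land <- makeLandscape("bowl", dims = 3)
  ctx <- objectiveContext(land$fn, land$dims, land$lower, land$upper)
  run <- runCEPGA(ctx, searchConfig(popSize = 20, maxGenerations = 0, seed = 3))
  expect_identical(run@evaluations, 20L)
  expect_identical(run@generations, 0L)
  expect_identical(bestEnergy(run), min(run@trace$energy))
})

test_that("CEPGA solves a smooth bowl to high accuracy", {
  land <- makeLandscape("bowl", dims = 2)
  ctx <- objectiveContext(land$fn, land$dims, land$lower, land$upper)
  run <- runCEPGA(ctx, searchConfig(popSize = 20, maxGenerations = 50,
                                    maxEvaluations = 1e5, seed = 4))
  expect_lt(bestEnergy(run) - land$globalMin, 1e-2)
})

test_that("seeded runs are bitwise reproducible and traces are monotone", {
  fix <- makeFixture(fixtureSpec(nTorsions = 2, seed = 3))
  cfg <- reducedSearchConfig(maxGenerations = 25, seed = 11)
  r1 <- runCEPGA(fixtureContext(fix, maxEvaluations = 5000), cfg)
  r2 <- runCEPGA(fixtureContext(fix, maxEvaluations = 5000), cfg)
  expect_identical_runs(r1, r2)
  tr <- runTrace(r1)
  expect_true(all(diff(tr$energy) < 0))
  expect_true(all(diff(tr$neval) > 0))
  expect_identical(bestEnergy(r1), tr$energy[nrow(tr)])
})

test_that("evaluation budget is an exact upper bound", {
  fix <- makeFixture(fixtureSpec(nTorsions = 1, seed = 2))
  ctx <- fixtureContext(fix, maxEvaluations = 777)
  run <- runCEPGA(ctx, reducedSearchConfig(seed = 1, maxEvaluations = 777))
  expect_identical(run@evaluations, 777L)   # budget-triggered termination
  ## generation-triggered termination stays under budget
  ctx2 <- fixtureContext(fix, maxEvaluations = 1e6)
  run2 <- runCEPGA(ctx2, reducedSearchConfig(seed = 1, maxGenerations = 10,
                                             maxEvaluations = 1e6))
  expect_lt(run2@evaluations, 1e6)
  expect_identical(run2@generations, 10L)
})

test_that("the plain GA shares operators but skips CEP and local search", {
  fix <- makeFixture(fixtureSpec(nTorsions = 1, seed = 2))
  cfg <- reducedSearchConfig(maxGenerations = 15, seed = 9)
  ga <- runGA(fixtureContext(fix, maxEvaluations = 4000), cfg)
  cep <- runCEPGA(fixtureContext(fix, maxEvaluations = 4000), cfg)
  expect_identical(ga@algorithm, "ga")
  expect_identical(cep@algorithm, "cepga")
  ## same seed: both start from the identical random population, so the very
  ## first trace entries coincide before the first CEP/LS event
  expect_identical(runTrace(ga)$energy[1], runTrace(cep)$energy[1])
  expect_false(identical(runTrace(ga), runTrace(cep)))
  expect_error(searchConfig(popSize = 1))
})

test_that("CEPGA never beats the exhaustive lattice oracle", {
  land <- makeLandscape("lattice", dims = 3)
  oracle <- enumerateLattice(land)
  expect_identical(oracle$min, -1)
  expect_identical(oracle$argmin, c(0, 0, 0))
  hits <- 0
  for (s in 1:3) {
    ctx <- objectiveContext(land$fn, land$dims, land$lower, land$upper)
    run <- runCEPGA(ctx, searchConfig(popSize = 20, maxGenerations = 100,
                                      maxEvaluations = 1e5, seed = s,
                                      lsMaxIter = 10))
    expect_gte(bestEnergy(run), oracle$min - 1e-12)
    hits <- hits + (abs(bestEnergy(run) - oracle$min) < 1e-12)
  }
  expect_gte(hits, 2)
})
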