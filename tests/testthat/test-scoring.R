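test_that("single 12-6 pair has its closed-form minimum", {
  ## pure van der Waals: all other weights zero
  model <- defaultEnergyModel(weights = c(hbond = 0, elec = 0, desolv = 0, tor = 0))
  topo <- LigandTopology(atoms = data.frame(type = "C", charge = 0),
                         coords = matrix(0, 1, 3))
  row <- model@typeTable[model@typeTable$type == "C", ]
  A <- row$epsii * row$Rii^12
  B <- 2 * row$epsii * row$Rii^6
  rstar <- (2 * A / B)^(1 / 6)
  depth <- -model@weights[["vdw"]] * B^2 / (4 * A)
  rec <- pointReceptor(c(rstar, 0, 0))
  expect_equal(scorePose(matrix(0, 1, 3), topo, rec, model)$total, depth,
               tolerance = 1e-9)
  ## numeric minimum sits at r* (well within the 8 A cutoff)
  f <- function(r) scorePose(matrix(0, 1, 3), topo,
                             pointReceptor(c(r, 0, 0)), model)$total
  opt <- optimize(f, c(2, 7), tol = 1e-10)
  expect_equal(opt$minimum, rstar, tolerance = 1e-6)
})

test_that("pairs beyond the cutoff contribute exactly zero", {
  model <- defaultEnergyModel()
  fix <- makeFixture(fixtureSpec(nTorsions = 2, seed = 1))
  topo <- fix$topo
  far <- pointReceptor(c(500, 0, 0), charge = 0.4)
  s <- scorePose(refCoords(topo), topo, far, model)
  expect_identical(s$vdw + s$hbond + s$elec + s$desolv, 0)
  expect_equal(s$total, s$torsional + s$intramolecular)
  ## adding a receptor atom beyond the cutoff changes nothing
  near <- pointReceptor(c(4, 0, 0), charge = 0.2)
  both <- ReceptorModel(rbind(atomData(near), atomData(far)),
                        rbind(refCoords(near), refCoords(far)),
                        boxCenter = c(0, 0, 0), boxHalf = c(10, 10, 10))
  expect_identical(scorePose(refCoords(topo), topo, both, model)$total,
                   scorePose(refCoords(topo), topo, near, model)$total)
})

test_that("vectorized, naive, and compiled scorers agree on random systems", {
  for (seed in 1:3) {
    sys <- randomSystem(25, 25, seed)
    coords <- refCoords(sys$topo)
    sv <- scorePose(coords, sys$topo, sys$receptor)
    sn <- scorePoseNaive(coords, sys$topo, sys$receptor)
    for (comp in names(sv))
      expect_equal(sv[[comp]], sn[[comp]], tolerance = 1e-9,
                   label = sprintf("component %s (seed %d)", comp, seed))
    ## the compiled fast path used by search contexts
    setup <- scoringSetup(sys$topo, sys$receptor)
    g <- identityGenome(sys$topo)
    expect_equal(setup$fast(g), sv$total, tolerance = 1e-9)
  }
  ## a flexible ligand exercises the intramolecular terms as well
  fix <- makeFixture(fixtureSpec(nTorsions = 5, seed = 9))
  ctx <- fixtureContext(fix)
  set.seed(11)
  for (rep in 1:3) {
    g <- randomGenome(ctx)
    co <- decodePose(g, fix$topo)
    expect_equal(scorePose(co, fix$topo, fix$receptor)$total,
                 scorePoseNaive(co, fix$topo, fix$receptor)$total,
                 tolerance = 1e-9)
    expect_equal(ctx$objective(g),
                 scorePose(co, fix$topo, fix$receptor)$total, tolerance = 1e-9)
  }
})

test_that("energy is invariant under atom reordering", {
  sys <- randomSystem(12, 12, 4)
  coords <- refCoords(sys$topo)
  base <- scorePose(coords, sys$topo, sys$receptor)$total
  perm <- sample(12)
  recPerm <- ReceptorModel(atomData(sys$receptor)[perm, ],
                           refCoords(sys$receptor)[perm, ],
                           boxCenter = c(0, 0, 0), boxHalf = c(10, 10, 10))
  expect_equal(scorePose(coords, sys$topo, recPerm)$total, base,
               tolerance = 1e-9)
})

test_that("overlapping atoms are clamped, never NaN or Inf", {
  topo <- LigandTopology(atoms = data.frame(type = "C", charge = 0.5),
                         coords = matrix(0, 1, 3))
  for (d in c(0, 0.001, 0.1, 0.49)) {
    s <- scorePose(matrix(0, 1, 3), topo, pointReceptor(c(d, 0, 0), charge = -0.5))
    expect_true(is.finite(s$total))
  }
  ## no NaN anywhere in the search box for random genomes
  fix <- makeFixture(fixtureSpec(nTorsions = 3, seed = 2))
  ctx <- fixtureContext(fix)
  set.seed(3)
  es <- replicate(200, evaluateGenome(randomGenome(ctx), ctx))
  expect_true(all(is.finite(es)))
})

test_that("empty receptor leaves only torsional and internal terms", {
  fix <- makeFixture(fixtureSpec(nTorsions = 2, seed = 1))
  empty <- ReceptorModel(data.frame(type = character(), charge = numeric(),
                                    element = character()),
                         matrix(numeric(), 0, 3),
                         boxCenter = c(0, 0, 0), boxHalf = c(5, 5, 5))
  s <- scorePose(refCoords(fix$topo), fix$topo, empty)
  expect_identical(s$vdw + s$hbond + s$elec + s$desolv, 0)
  expect_equal(s$torsional, defaultEnergyModel()@weights[["tor"]] * 2)
})

test_that("the breakdown always sums to the total", {
  for (seed in 1:3) {
    sys <- randomSystem(15, 20, seed + 20)
    s <- scorePose(refCoords(sys$topo), sys$topo, sys$receptor)
    expect_equal(s$total, s$vdw + s$hbond + s$elec + s$desolv +
                   s$intramolecular + s$torsional, tolerance = 1e-9)
  }
})

test_that("evaluation counting is exact and budget-limited", {
  fix <- makeFixture(fixtureSpec(nTorsions = 1, seed = 1))
  ctx <- fixtureContext(fix, maxEvaluations = 10)
  g <- fix$plantedGenome
  e1 <- evaluateGenome(g, ctx)
  e2 <- evaluateGenome(g, ctx)
  expect_identical(e1, e2)              # deterministic
  expect_identical(evaluationCount(ctx), 2L)
  for (i in 3:10) evaluateGenome(g, ctx)
  expect_identical(evaluationCount(ctx), 10L)
  expect_error(evaluateGenome(g, ctx), class = "cepdock_budget_exhausted")
  expect_identical(evaluationCount(ctx), 10L)   # the failed call is not counted
})
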