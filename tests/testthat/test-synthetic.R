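test_that("fixtures are deterministic in their seed", {
  a <- makeFixture(fixtureSpec(nTorsions = 3, seed = 21))
  b <- makeFixture(fixtureSpec(nTorsions = 3, seed = 21))
  expect_identical(refCoords(a$topo), refCoords(b$topo))
  expect_identical(refCoords(a$receptor), refCoords(b$receptor))
  expect_identical(a$plantedGenome, b$plantedGenome)
  c <- makeFixture(fixtureSpec(nTorsions = 3, seed = 22))
  expect_false(identical(a$plantedGenome, c$plantedGenome))
})

test_that("fixture geometry matches its specification", {
  for (Tn in c(0L, 1L, 5L)) {
    fix <- makeFixture(fixtureSpec(nTorsions = Tn, seed = 2))
    expect_identical(nTorsions(fix$topo), Tn)
    expect_length(fix$plantedGenome, 7L + Tn)
    expect_identical(decodePose(fix$plantedGenome, fix$topo), fix$reference)
    expect_true(validObject(fix$topo))
    expect_true(validObject(fix$receptor))
  }
  expect_error(makeFixture(fixtureSpec(boxHalf = 0.5)), "too small")
})

test_that("the planted pose is a deep basin", {
  for (Tn in c(0, 2, 4)) {
    fix <- makeFixture(fixtureSpec(nTorsions = Tn, seed = 7))
    ck <- checkFixture(fix, n = 300, seed = 1)
    expect_true(ck$ok,
                label = sprintf("planted pose beats 300 random poses (T=%d)", Tn))
  }
})

test_that("analytic landscapes expose their optima", {
  bowl <- makeLandscape("bowl", dims = 3)
  expect_identical(bowl$fn(rep(0, 3)), 0)
  expect_gt(bowl$fn(c(1, 1, 1)), 0)
  multi <- makeLandscape("multimodal", dims = 2)
  expect_identical(multi$fn(multi$globalArg), multi$globalMin)
  expect_gt(multi$fn(c(0.5, 0.5)), multi$globalMin)
  expect_error(makeLandscape("volcano"), "arg")
})

test_that("the lattice landscape is exhaustively enumerable", {
  land <- makeLandscape("lattice", dims = 3)
  oracle <- enumerateLattice(land)
  expect_identical(oracle$min, land$globalMin)
  ## snapping: nearby continuous genomes share the lattice value
  expect_identical(land$fn(c(0.2, -0.3, 0.4)), land$fn(c(0, 0, 0)))
  expect_identical(land$fn(c(1.4, 0, 0)), land$fn(c(1, 0, 0)))
  ## 11 states per dimension
  expect_length(land$grid, 11L)
})
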