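test_that("identity genome reproduces the template exactly", {
  fix <- makeFixture(fixtureSpec(nTorsions = 3, seed = 5))
  expect_identical(decodePose(identityGenome(fix$topo), fix$topo),
                   refCoords(fix$topo))
})

test_that("pure translation shifts every atom", {
  topo <- twoAtomLigand()
  out <- decodePose(newGenome(translation = c(0, 0, 2)), topo)
  expect_equal(out, rbind(c(0, 0, 2), c(1, 0, 2)), tolerance = 1e-12)
})

test_that("a 180-degree torsion reflects the moved atom across the bond axis", {
  topo <- oneTorsionLigand()
  out <- decodePose(newGenome(torsions = pi), topo)
  expect_equal(out[3, ], c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(out[1:2, ], refCoords(topo)[1:2, ], tolerance = 1e-12)
})

test_that("decode preserves rigid geometry for random genomes", {
  set.seed(42)
  for (rep in 1:5) {
    fix <- makeFixture(fixtureSpec(nTorsions = 4, seed = rep))
    topo <- fix$topo
    ctx <- fixtureContext(fix)
    g <- randomGenome(ctx)
    out <- decodePose(g, topo)
    ## every bond keeps its template length
    ref <- refCoords(topo)
    for (k in seq_len(nrow(topo@bonds))) {
      i <- topo@bonds[k, 1]; j <- topo@bonds[k, 2]
      expect_equal(sqrt(sum((out[i, ] - out[j, ])^2)),
                   sqrt(sum((ref[i, ] - ref[j, ])^2)), tolerance = 1e-9)
    }
    ## torsion genes only move their moved set: zeroing one torsion must not
    ## change atoms outside it (compare against the same genome)
    tor1 <- topo@torsions[[1]]
    g2 <- g
    g2[8] <- 0
    out2 <- decodePose(g2, topo)
    still <- setdiff(seq_len(nAtoms(topo)), tor1$moved)
    expect_equal(out[still, ], out2[still, ], tolerance = 1e-9)
    ## decode is pure: repeated calls are bitwise identical
    expect_identical(out, decodePose(g, topo))
  }
})

test_that("genome contract violations are caught", {
  topo <- oneTorsionLigand()
  expect_error(decodePose(numeric(7), topo), "length")
  g <- newGenome(torsions = 0)
  g[4:7] <- c(2, 0, 0, 0)
  expect_warning(decodePose(g, topo), "renormaliz")
  g[4:7] <- 0
  expect_error(decodePose(g, topo), "zero-norm")
})

test_that("rmsd follows its definition", {
  a <- matrix(rnorm(30), 10, 3)
  expect_identical(poseRmsd(a, a), 0)
  expect_equal(poseRmsd(a, a + rep(c(0, 0, 2), each = 10)), 2, tolerance = 1e-12)
  b3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  a3 <- b3; a3[1, ] <- a3[1, ] + c(3, 0, 0)
  expect_equal(poseRmsd(a3, b3), sqrt(3), tolerance = 1e-12)
  ## symmetry and rigid-translation invariance
  b <- a + matrix(rnorm(30), 10, 3)
  expect_equal(poseRmsd(a, b), poseRmsd(b, a))
  shift <- rep(c(1, -2, 3), each = 10)
  expect_equal(poseRmsd(a + shift, b + shift), poseRmsd(a, b), tolerance = 1e-12)
  expect_error(poseRmsd(a, a[1:5, ]), "differ in size")
})

test_that("the 2.0 A validity threshold is strict", {
  expect_true(isValidPose(1.90))
  expect_false(isValidPose(2.0))
  expect_true(isValidPose(0))
  expect_error(isValidPose(-0.1), "negative")
})

test_that("angles wrap to (-pi, pi]", {
  expect_equal(wrapAngle(pi), pi)
  expect_equal(wrapAngle(-pi), pi)
  expect_equal(wrapAngle(3 * pi / 2), -pi / 2, tolerance = 1e-12)
  x <- runif(1000, -20, 20)
  w <- wrapAngle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-9)
  expect_equal(cos(w), cos(x), tolerance = 1e-9)
})
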