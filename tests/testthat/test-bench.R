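test_that("box statistics follow the Tukey convention", {
  bs <- boxStats(c(1, 2, 3, 4, 5))
  expect_identical(unname(bs),
                   c(1, 2, 3, 4, 5))
  ## outlier excluded from the whisker
  bs2 <- boxStats(c(1, 2, 3, 4, 100))
  expect_identical(unname(bs2["upper_quartile"]), 4)
  expect_identical(unname(bs2["upper_edge"]), 4)
  ## degenerate inputs
  expect_identical(unname(boxStats(rep(7, 9))), rep(7, 5))
  expect_identical(unname(boxStats(3)), rep(3, 5))
  expect_error(boxStats(numeric()), "at least one")
})

test_that("separated samples give the exact minimal rank-sum p-value", {
  res <- pairwiseTest(c(1, 2, 3), c(10, 11, 12))
  expect_identical(res$p.value, 1 / choose(6, 3))
  expect_identical(res$method, "exact")
  ## agrees with the stock exact Wilcoxon test
  ref <- wilcox.test(c(1, 2, 3), c(10, 11, 12), alternative = "less",
                     exact = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  ## reversed direction is non-significant
  expect_gt(pairwiseTest(c(10, 11, 12), c(1, 2, 3))$p.value, 0.9)
})

test_that("opposite one-sided p-values mirror each other", {
  ## exact path: the pair sums to 1 plus the discrete mass at the observed
  ## statistic
  set.seed(1)
  a <- rnorm(8); b <- rnorm(8) + 0.5
  pa <- pairwiseTest(a, b); pb <- pairwiseTest(b, a)
  mass <- dwilcox(pa$statistic, 8, 8)
  expect_equal(pa$p.value + pb$p.value, 1 + mass, tolerance = 1e-12)
  ## normal path (n > 10, tie-free): the pair sums to exactly 1
  set.seed(2)
  a2 <- rnorm(12); b2 <- rnorm(12) + 0.3
  p2a <- pairwiseTest(a2, b2); p2b <- pairwiseTest(b2, a2)
  expect_identical(p2a$method, "normal")
  expect_equal(p2a$p.value + p2b$p.value, 1, tolerance = 1e-12)
  ## cross-check against the stock normal approximation without continuity
  ## correction
  ref <- suppressWarnings(wilcox.test(a2, b2, alternative = "less",
                                      exact = FALSE, correct = FALSE))
  expect_equal(p2a$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("ties are flagged and degenerate samples give p = 0.5", {
  res <- pairwiseTest(rep(1, 5), rep(1, 5))
  expect_identical(res$p.value, 0.5)
  expect_true(res$tied)
  ## identical (non-constant) samples: no claim of superiority
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  res2 <- pairwiseTest(x, x)
  expect_gte(res2$p.value, 0.5)
  expect_true(res2$tied)
})

test_that("runExperiment aggregates seeded runs per cell", {
  land <- makeLandscape("bowl", dims = 2)
  mkCtx <- function() objectiveContext(land$fn, land$dims, land$lower,
                                       land$upper, maxEvaluations = 1500)
  cfg <- searchConfig(popSize = 10, maxGenerations = 20,
                      maxEvaluations = 1500, lsMaxIter = 10)
  ## R = 1: the cell's lowest energy is that run's final energy
  ex1 <- runExperiment(list(bowl = mkCtx), algorithms = "cepga", runs = 1,
                       config = cfg, baseSeed = 5)
  expect_identical(ex1$summary$lowest_energy, ex1$runs$energy[1])
  expect_identical(ex1$runs$seed[1], 6L)          # baseSeed + run index
  ## two algorithms, three runs: 6 rows, aggregated per cell
  ex <- runExperiment(list(bowl = mkCtx), algorithms = c("cepga", "ga"),
                      runs = 3, config = cfg, baseSeed = 1)
  expect_identical(nrow(ex$runs), 6L)
  expect_identical(nrow(ex$summary), 2L)
  for (alg in c("cepga", "ga")) {
    d <- ex$runs[ex$runs$algorithm == alg, ]
    expect_identical(min(d$energy),
                     ex$summary$lowest_energy[ex$summary$algorithm == alg])
  }
  ## a crashing instance is recorded as failed, not fatal
  boom <- function() stop("broken instance")
  ex2 <- runExperiment(list(bad = boom, bowl = mkCtx), algorithms = "cepga",
                       runs = 2, config = cfg, baseSeed = 1)
  expect_identical(sum(ex2$runs$failed), 2L)
  expect_identical(ex2$summary$n_failed[ex2$summary$instance == "bad"], 2L)
  expect_identical(sum(!ex2$runs$failed), 2L)
})

test_that("success counting applies the strict 2.0 A rule", {
  expect_identical(sum(isValidPose(c(1.9, 2.0, 2.1))), 1L)
})

test_that("non-monotone traces are rejected on construction", {
  expect_error(new("DockingRun", algorithm = "cepga", seed = 1L,
                   bestGenome = 0, bestEnergy = -1, finalRmsd = NA_real_,
                   evaluations = 10L, generations = 1L,
                   trace = data.frame(neval = c(1, 5), energy = c(-1, -0.5))),
               "strictly decreasing")
  expect_error(new("DockingRun", algorithm = "cepga", seed = 1L,
                   bestGenome = 0, bestEnergy = -1, finalRmsd = NA_real_,
                   evaluations = 10L, generations = 1L,
                   trace = data.frame(neval = c(5, 5), energy = c(-0.5, -1))),
               "strictly increasing")
})
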