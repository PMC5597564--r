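# Small structures built in code for the unit tests.

# rigid two-atom ligand on the x axis
twoAtomLigand <- function() {
  LigandTopology(
    atoms = data.frame(element = c("C", "C"), type = c("C", "C"),
                       charge = c(0, 0)),
    coords = rbind(c(0, 0, 0), c(1, 0, 0)),
    bonds = rbind(c(1L, 2L)))
}

# three atoms with one torsion about the z-aligned bond 1-2; atom 3 moves
oneTorsionLigand <- function() {
  LigandTopology(
    atoms = data.frame(element = c("C", "C", "C"), type = c("C", "C", "C"),
                       charge = c(0, 0, 0)),
    coords = rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)),
    bonds = rbind(c(1L, 2L), c(2L, 3L)),
    torsions = list(list(axis = c(1L, 2L), moved = 3L)),
    rootAtoms = 1L)
}

# single-atom receptor at a given position with an explicit box
pointReceptor <- function(pos, type = "C", charge = 0, boxHalf = 10) {
  ReceptorModel(
    atoms = data.frame(element = typeToElementPublic(type), type = type,
                       charge = charge),
    coords = matrix(pos, 1, 3),
    boxCenter = c(0, 0, 0), boxHalf = rep(boxHalf, 3))
}

typeToElementPublic <- function(type) {
  # minimal mirror of the package's internal mapping for test fixtures
  ifelse(type %in% c("HD", "H"), "H", substr(type, 1, 1))
}

# random rigid ligand + receptor pair for oracle-equivalence checks
randomSystem <- function(nLig, nRec, seed) {
  set.seed(seed)
  types <- c("C", "OA", "N", "HD", "A")
  lt <- sample(types, nLig, replace = TRUE)
  rt <- sample(types, nRec, replace = TRUE)
  topo <- LigandTopology(
    atoms = data.frame(type = lt, charge = round(runif(nLig, -0.5, 0.5), 3)),
    coords = matrix(runif(nLig * 3, -4, 4), nLig, 3))
  rec <- ReceptorModel(
    atoms = data.frame(type = rt, charge = round(runif(nRec, -0.5, 0.5), 3)),
    coords = matrix(runif(nRec * 3, -6, 6), nRec, 3))
  list(topo = topo, receptor = rec)
}

expect_identical_runs <- function(a, b) {
  expect_identical(runTrace(a), runTrace(b))
  expect_identical(bestGenome(a), bestGenome(b))
  expect_identical(bestEnergy(a), bestEnergy(b))
}
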