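## Synthetic receptor-ligand fixtures and analytic test landscapes.
##
## Real crystal complexes cannot provide ground truth for a search algorithm
## at desk scale, so the generator builds small systems where the answer is
## planted by construction: a branched ligand with a chosen number of
## rotatable bonds, a pose genome designated as the optimum, and a receptor
## "pocket" with one complementary partner atom per ligand heavy atom placed
## at the pair potential's minimum distance, making the planted pose a deep
## energy basin.

#' Specification of a synthetic docking fixture
#'
#' @param nTorsions number of rotatable bonds T, 0 to 15 (the span of the
#'   benchmark ligands the generator emulates).
#' @param nRootAtoms atoms in the rigid ROOT block (>= 3).
#' @param boxHalf search-box half-extent (A), recycled to length 3.
#' @param bondLength heavy-atom bond length (A).
#' @param plantedGenome optional explicit planted genome; default drawn from
#'   `seed` (translation within half the box, random orientation and
#'   torsions).
#' @param acceptorEvery every `acceptorEvery`-th chain atom is a
#'   hydrogen-bond acceptor that receives a donor anchor in the pocket
#'   (default 2).
#' @param chargeMag magnitude of the alternating partial charges (e).
#' @param gridSpacing lateral spacing (A) of the molded pocket surface.
#' @param seed RNG seed; the same seed reproduces the identical fixture.
#' @return a list of class `cepdock_fixture_spec`
#' @export
fixtureSpec <- function(nTorsions = 2L, nRootAtoms = 3L, boxHalf = 6,
                        bondLength = 1.5, plantedGenome = NULL,
                        acceptorEvery = 2L, chargeMag = 0.3,
                        gridSpacing = 1.5, seed = 1L) {
  stopifnot(nTorsions >= 0L, nTorsions <= 15L, nRootAtoms >= 3L,
            acceptorEvery >= 1L, chargeMag >= 0, gridSpacing > 0)
  boxHalf <- rep_len(boxHalf, 3L)
  ## the box constrains the root centroid; it must at least exceed one bond
  ## length so a ligand can move inside it at all
  if (any(boxHalf < bondLength))
    stop("box too small for the ligand")
  structure(list(nTorsions = as.integer(nTorsions),
                 nRootAtoms = as.integer(nRootAtoms),
                 boxHalf = boxHalf, bondLength = bondLength,
                 plantedGenome = plantedGenome,
                 acceptorEvery = as.integer(acceptorEvery),
                 chargeMag = chargeMag,
                 gridSpacing = gridSpacing,
                 seed = as.integer(seed)),
            class = "cepdock_fixture_spec")
}

#' Build a synthetic receptor-ligand fixture with a planted optimum
#'
#' Constructs (deterministically for a given spec) a branched heavy-atom
#' ligand with `nTorsions` rotatable bonds, decodes the planted genome to the
#' reference pose, and surrounds that pose with one attractive receptor
#' partner per ligand atom at the 12-6 minimum distance, so the planted pose
#' sits in a deep, roughly global energy basin.  The search box is centered
#' on the planted pose.
#'
#' @param spec a [fixtureSpec()].
#' @param model the [EnergyModel-class] whose minimum-distance geometry the
#'   pocket should match.
#' @return list with `topo` ([LigandTopology-class]), `receptor`
#'   ([ReceptorModel-class]), `reference` (n x 3 planted coordinates),
#'   `plantedGenome`, and `spec`
#' @export
makeFixture <- function(spec = fixtureSpec(), model = defaultEnergyModel()) {
  stopifnot(inherits(spec, "cepdock_fixture_spec"))
  withSeed(spec$seed, buildFixture(spec, model))
}

buildFixture <- function(spec, model) {
  T <- spec$nTorsions
  bl <- spec$bondLength
  ## Rigid ROOT block: near-equilateral polygon of carbons in the xy plane.
  nR <- spec$nRootAtoms
  ang <- 2 * pi * (seq_len(nR) - 1) / nR
  rad <- bl / (2 * sin(pi / nR))
  rootXYZ <- cbind(rad * cos(ang), rad * sin(ang), 0)
  ## Chain of T + 1 atoms hanging off root atom 1; bond k of the chain is
  ## rotatable for k = 1..T (torsion k moves everything distal of chain atom k).
  ## heteroatom size variation along the ring gives the molded surface a
  ## shape registry on top of the charge registry
  types <- rep(c("C", "N"), length.out = nR)
  ## sparse hydrogen-bond acceptors along the chain: their donor partners
  ## give the pocket deep, well-localized wells, and the spacing (together
  ## with the donor-donor separation enforced below) prevents one acceptor
  ## from chelating two donors, so the planted 1:1 matching is the ceiling
  chainTypes <- rep(c("OA", rep("C", spec$acceptorEvery - 1L)),
                    length.out = T + 1L)
  coords <- rootXYZ
  bonds <- cbind(seq_len(nR), c(seq_len(nR)[-1], 1L))
  ## extended planar zig-zag with tetrahedral bond angles, growing along +x
  ## away from the ring (template is clash-free by construction)
  alpha <- (pi - 109.5 * pi / 180) / 2
  prev1 <- 1L
  for (k in seq_len(T + 1L)) {
    dirn <- c(cos(alpha), 0, sin(alpha) * (-1)^k)
    newAtom <- coords[prev1, ] + bl * dirn
    coords <- rbind(coords, newAtom)
    idx <- nrow(coords)
    bonds <- rbind(bonds, c(prev1, idx))
    types <- c(types, chainTypes[k])
    prev1 <- idx
  }
  n <- nrow(coords)
  torsions <- list()
  for (k in seq_len(T)) {
    a <- if (k == 1L) 1L else nR + k - 1L   # proximal axis atom
    b <- nR + k                             # distal axis atom
    torsions[[k]] <- list(axis = c(a, b),
                          moved = seq.int(nR + k + 1L, n),
                          parent = k - 1L)
  }
  ## alternating signs with seeded irregular magnitudes plus a strongly
  ## charged head atom: breaks the translational/flip symmetry of the chain
  ## so no shifted or reversed registry can tie the planted pose
  charges <- round(rep(c(1, -1), length.out = n) *
                     runif(n, 0.5 * spec$chargeMag, 1.5 * spec$chargeMag), 3)
  charges[1] <- round(1.67 * spec$chargeMag, 3)
  atoms <- data.frame(name = paste0(types, seq_len(n)), element = typeToElement(types),
                      type = types, charge = charges,
                      resName = "LIG", resSeq = 1L)
  ## rigid ligands carry every atom in the ROOT block, as PDBQT would
  rootIdx <- if (T == 0L) seq_len(n) else seq_len(nR)
  topo <- LigandTopology(atoms, coords, bonds, torsions,
                         rootAtoms = rootIdx, torsdof = T)

  ## Planted genome and reference pose.  Planted torsions are resampled until
  ## the conformation is free of intramolecular clashes (every
  ## torsion-variable pair beyond 90% of its pair equilibrium distance), so
  ## the planted pose carries no internal strain.
  tt <- model@typeTable
  pairRstarIdx <- function(iA, iB) {
    if ((tt$hb[iA] == "A" && tt$hb[iB] == "D") ||
        (tt$hb[iA] == "D" && tt$hb[iB] == "A")) {
      tt$hbRij[if (tt$hb[iA] == "A") iA else iB]
    } else (tt$Rii[iA] + tt$Rii[iB]) / 2
  }
  typeIdx <- match(types, tt$type)
  ip <- intraPairs(topo)
  clashFree <- function(coords) {
    if (!nrow(ip)) return(TRUE)
    all(vapply(seq_len(nrow(ip)), function(k) {
      i <- ip[k, 1]; j <- ip[k, 2]
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      d > 0.8 * pairRstarIdx(typeIdx[i], typeIdx[j])
    }, logical(1)))
  }
  planted <- spec$plantedGenome
  if (is.null(planted)) {
    u <- runif(3)
    q <- c(sqrt(u[1]) * cos(2 * pi * u[3]),
           sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]))
    trans <- runif(3, -0.5, 0.5) * spec$boxHalf
    for (try in seq_len(100)) {
      ## near-extended conformers: bound ligands favor low-strain torsions,
      ## and they present a broad face to the molded wall
      tors <- runif(T, -pi / 3, pi / 3)
      planted <- newGenome(trans, q, tors)
      if (clashFree(decodePose(planted, topo))) break
      ## fall back to the extended template conformation, clash-free by
      ## construction
      if (try == 100) planted <- newGenome(trans, q, rep(0, T))
    }
  }
  if (length(planted) != 7L + T) stop("planted genome length mismatch")
  reference <- decodePose(planted, topo)

  ## Pocket: a molded complementary surface (lock-and-key dent).  A wall
  ## with a seeded random orientation is tiled with receptor atoms on a
  ## regular lateral grid; each grid atom is lowered to the highest position
  ## that keeps it outside the van der Waals contact distance of every
  ## ligand atom, so the surface hugs the planted pose at the pair-potential
  ## minimum without ever clashing.  Each surface atom takes the opposite
  ## partial charge of its nearest ligand atom (electrostatic registry), and
  ## the surface atom directly beneath each hydrogen-bond acceptor becomes a
  ## donor hydrogen at the 12-10 equilibrium distance, locking position and
  ## orientation.  The open face above the wall leaves an approach funnel.
  pairRstar <- function(typeA, typeB) {
    iA <- match(typeA, tt$type); iB <- match(typeB, tt$type)
    if ((tt$hb[iA] == "A" && tt$hb[iB] == "D") ||
        (tt$hb[iA] == "D" && tt$hb[iB] == "A")) {
      acc <- if (tt$hb[iA] == "A") iA else iB
      tt$hbRij[acc]
    } else (tt$Rii[iA] + tt$Rii[iB]) / 2
  }
  ## the wall lies along the ligand's flattest principal plane (randomly
  ## signed), so the planted pose presents its broadest face to the surface
  ## and no alternative pose can collect more contacts against the mold
  ev <- eigen(stats::cov(reference), symmetric = TRUE)
  wallN <- ev$vectors[, 3] * sign(runif(1) - 0.5)
  wallN <- wallN / sqrt(sum(wallN^2))
  e1 <- ev$vectors[, 1]
  e2 <- c(wallN[2] * e1[3] - wallN[3] * e1[2],
          wallN[3] * e1[1] - wallN[1] * e1[3],
          wallN[1] * e1[2] - wallN[2] * e1[1])
  aL <- as.vector(reference %*% e1)       # lateral / height decomposition
  bL <- as.vector(reference %*% e2)
  hL <- as.vector(reference %*% wallN)
  rstarC <- vapply(atoms$type, function(tp) pairRstar(tp, "C"), numeric(1))
  sp <- spec$gridSpacing
  margin <- 2.5
  sGrid <- seq(min(aL) - margin, max(aL) + margin, by = sp)
  tGrid <- seq(min(bL) - margin, max(bL) + margin, by = sp)
  recCoords <- NULL; recTypes <- character(); recCharges <- numeric()
  for (s in sGrid) for (t in tGrid) {
    rho2 <- (s - aL)^2 + (t - bL)^2
    H <- min(hL - sqrt(pmax(rstarC^2 - rho2, 0)))
    pos <- s * e1 + t * e2 + H * wallN
    d <- sqrt(rho2 + (hL - H)^2)
    j <- which.min(d)
    if (d[j] > model@cutoff) next         # far outside the dent: no signal
    recCoords <- rbind(recCoords, pos)
    recTypes <- c(recTypes, "C")
    recCharges <- c(recCharges, -charges[j])
  }
  ## donor anchors: one HD directly beneath each acceptor, at the 12-10
  ## equilibrium distance along the wall normal; an anchor is only kept if
  ## its net interaction with the whole planted pose is strongly attractive
  ## (it must not sit inside the repulsive wall of a neighboring atom)
  w <- model@weights
  partnerEnergy <- function(pos, pt, qpt) {
    pc <- pairCoefficients(atoms$type, charges, pt, qpt, model)
    r <- sqrt(rowSums(sweep(reference, 2, pos)^2))
    ce <- pairEnergies(matrix(r, ncol = 1), pc, model)
    sum(w[c("vdw", "hbond", "elec", "desolv")] * ce)
  }
  accIdx <- which(tt$hb[typeIdx] == "A")
  for (i in accIdx) {
    rhb <- pairRstar(atoms$type[i], "HD")
    pos <- reference[i, ] - rhb * wallN
    if (partnerEnergy(pos, "HD", -charges[i]) > -0.3) next
    if (!is.null(recCoords)) {
      dRec <- sqrt(rowSums(sweep(recCoords, 2, pos)^2))
      drop <- dRec < 1.0                  # displace the grid atoms it replaces
      if (any(drop)) {
        recCoords <- recCoords[!drop, , drop = FALSE]
        recTypes <- recTypes[!drop]; recCharges <- recCharges[!drop]
      }
    }
    recCoords <- rbind(recCoords, pos)
    recTypes <- c(recTypes, "HD")
    recCharges <- c(recCharges, -charges[i])
  }
  recAtoms <- data.frame(name = paste0(recTypes, seq_along(recTypes)),
                         element = typeToElement(recTypes), type = recTypes,
                         charge = round(recCharges, 3),
                         resName = "POC", resSeq = seq_along(recTypes))
  rootCentroidRef <- colMeans(reference[rootIdx, , drop = FALSE])
  receptor <- ReceptorModel(recAtoms, recCoords,
                            boxCenter = rootCentroidRef,
                            boxHalf = spec$boxHalf)
  list(topo = topo, receptor = receptor, reference = reference,
       plantedGenome = planted, spec = spec)
}

## attempt-indexed deterministic direction fan around u0
rotateDirection <- function(u0, attempt) {
  if (attempt == 0) return(u0)
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ax <- axes[(attempt - 1) %% 3 + 1, ]
  if (abs(sum(ax * u0)) > 0.99) ax <- axes[attempt %% 3 + 1, ]
  ax <- ax - sum(ax * u0) * u0
  ax <- ax / sqrt(sum(ax^2))
  angle <- (floor((attempt - 1) / 3) + 1) * (pi / 6)
  as.vector(rotatePoints(matrix(u0, 1, 3), c(0, 0, 0), ax, angle))
}

#' Evaluation context for a synthetic fixture
#'
#' @param fixture result of [makeFixture()].
#' @param model an [EnergyModel-class].
#' @param maxEvaluations evaluation budget.
#' @return a [dockingContext()] carrying the fixture's reference coordinates
#' @export
fixtureContext <- function(fixture, model = defaultEnergyModel(),
                           maxEvaluations = Inf) {
  dockingContext(fixture$topo, fixture$receptor, model,
                 maxEvaluations = maxEvaluations,
                 reference = fixture$reference)
}

#' Monte-Carlo basin check of a fixture
#'
#' Verifies that the planted pose scores below every one of `n` random poses
#' (minimum over the sample), i.e. the planted basin is deep.
#'
#' @param fixture result of [makeFixture()].
#' @param n number of random poses.
#' @param model an [EnergyModel-class].
#' @param seed RNG seed for the random poses.
#' @return list with `plantedEnergy`, `minRandom`, `ok`
#' @export
checkFixture <- function(fixture, n = 1000L, model = defaultEnergyModel(),
                         seed = 1L) {
  ctx <- fixtureContext(fixture, model)
  planted <- evaluateGenome(fixture$plantedGenome, ctx)
  rand <- withSeed(seed, vapply(seq_len(n), function(i)
    evaluateGenome(randomGenome(ctx), ctx), numeric(1)))
  list(plantedEnergy = planted, minRandom = min(rand), ok = planted < min(rand))
}

#' Analytic test landscapes with known optima
#'
#' \describe{
#'   \item{bowl}{`f(x) = sum(x^2)`; global minimum 0 at the origin.}
#'   \item{multimodal}{shifted Rastrigin-style surface
#'     `f(x) = -1 + sum(x_i^2 - A cos(2 pi x_i) + A)` with `A = 3`;
#'     global minimum -1 at the origin among many local minima.}
#'   \item{lattice}{the multimodal surface sampled on the integer lattice:
#'     genomes snap to the nearest of 11 grid points per dimension on
#'     `[-5, 5]`, giving `11^dims` states that an exhaustive oracle can
#'     enumerate; global minimum -1 at the origin.}
#' }
#'
#' @param name one of `"bowl"`, `"multimodal"`, `"lattice"`.
#' @param dims number of genes.
#' @return list with `fn`, `dims`, `lower`, `upper`, `globalMin`,
#'   `globalArg`, and for the lattice its `grid`
#' @export
makeLandscape <- function(name = c("bowl", "multimodal", "lattice"), dims = 3L) {
  name <- match.arg(name)
  dims <- as.integer(dims)
  A <- 3
  multi <- function(x) -1 + sum(x^2 - A * cos(2 * pi * x) + A)
  switch(name,
    bowl = list(
      fn = function(x) sum(x^2),
      dims = dims, lower = -5.12, upper = 5.12,
      globalMin = 0, globalArg = rep(0, dims)),
    multimodal = list(
      fn = multi,
      dims = dims, lower = -5.12, upper = 5.12,
      globalMin = -1, globalArg = rep(0, dims)),
    lattice = {
      grid <- seq(-5, 5, by = 1)
      snap <- function(x) grid[pmax(1L, pmin(length(grid), round(x) + 6L))]
      list(
        fn = function(x) multi(snap(x)),
        dims = dims, lower = -5.5, upper = 5.5,
        globalMin = -1, globalArg = rep(0, dims), grid = grid)
    })
}

#' Exhaustive minimum of a lattice landscape
#'
#' Brute-force oracle: enumerates all `11^dims` lattice states and returns
#' the global minimum value (and one argmin).
#'
#' @param landscape a `"lattice"` landscape from [makeLandscape()].
#' @return list with `min` and `argmin`
#' @export
enumerateLattice <- function(landscape) {
  stopifnot(!is.null(landscape$grid))
  states <- as.matrix(do.call(expand.grid, rep(list(landscape$grid), landscape$dims)))
  vals <- apply(states, 1, landscape$fn)
  i <- which.min(vals)
  list(min = vals[i], argmin = unname(states[i, ]))
}
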