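## Semi-empirical pairwise scoring.
##
## The objective follows the AutoDock4 functional form (weighted 12-6 van der
## Waals, 12-10 hydrogen bonding, screened Coulomb electrostatics with a
## sigmoidal distance-dependent dielectric, Gaussian pairwise desolvation,
## and a torsional penalty proportional to the ligand's TORSDOF), evaluated by
## direct pairwise summation over receptor-ligand atom pairs plus the
## torsion-variable intraligand pairs.  Published AutoDock4 constants are
## shipped as the default parameter table for face validity; no grid maps and
## no claim of bit-compatibility with AutoDock itself.

#' Default energy model
#'
#' Loads the shipped atom-type table (see
#' `system.file("extdata", "ad4_atom_params.tsv", package = "cepdock")`) and
#' the published AutoDock4 free-energy weights.
#'
#' @param typeTable optional replacement atom-type table (same columns).
#' @param weights named numeric overriding any of `vdw`, `hbond`, `elec`,
#'   `desolv`, `tor`.
#' @param cutoff nonbonded cutoff in A (default 8).
#' @param clashDist clash clamp distance in A (default 0.5).
#' @param clashSlope linear clash penalty, kcal/mol per A of overlap.
#' @return an [EnergyModel-class]
#' @export
defaultEnergyModel <- function(typeTable = NULL, weights = NULL,
                               cutoff = 8, clashDist = 0.5, clashSlope = 100) {
  if (is.null(typeTable)) {
    path <- system.file("extdata", "ad4_atom_params.tsv", package = "cepdock")
    ## na.strings empty: "NA" is the nitrogen-acceptor atom type, not missing
    typeTable <- read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            na.strings = character(0))
  }
  typeTable$hb[typeTable$hb == "-"] <- ""
  w <- c(vdw = 0.1662, hbond = 0.1209, elec = 0.1406,
         desolv = 0.1322, tor = 0.2983)
  if (!is.null(weights)) w[names(weights)] <- weights
  new("EnergyModel",
      typeTable = typeTable, weights = w,
      cutoff = cutoff, clashDist = clashDist, clashSlope = clashSlope,
      dielectric = c(eps0 = 78.4, A = -8.5525, lambda = 0.003627, k = 7.7839),
      qsolpar = 0.01097, sigma = 3.5, elecScale = 332.06363)
}

## Mehler-Solmajer sigmoidal distance-dependent dielectric.
dielectricAt <- function(r, d) {
  B <- d[["eps0"]] - d[["A"]]
  d[["A"]] + B / (1 + d[["k"]] * exp(-d[["lambda"]] * B * r))
}

typeRow <- function(model, types) {
  idx <- match(types, model@typeTable$type)
  if (anyNA(idx))
    stop("unknown atom type(s): ", paste(unique(types[is.na(idx)]), collapse = ", "))
  idx
}

## Precompute per-pair coefficients between two atom sets.
## Returns matrices (nA x nB): A12, B6 (12-6), C12, D10 (12-10), hb mask,
## qq (scaled charge products), ds (solvation cross terms).
pairCoefficients <- function(typesA, chargesA, typesB, chargesB, model) {
  tt <- model@typeTable
  ia <- typeRow(model, typesA); ib <- typeRow(model, typesB)
  Ra <- tt$Rii[ia] / 2; Rb <- tt$Rii[ib] / 2
  ea <- tt$epsii[ia];   eb <- tt$epsii[ib]
  Rij <- outer(Ra, Rb, "+")
  eij <- sqrt(outer(ea, eb))
  A12 <- eij * Rij^12
  B6  <- 2 * eij * Rij^6
  ## hydrogen bond: donor hydrogen paired with an acceptor; 12-10 parameters
  ## taken from the acceptor's row
  donA <- tt$hb[ia] == "D"; accA <- tt$hb[ia] == "A"
  donB <- tt$hb[ib] == "D"; accB <- tt$hb[ib] == "A"
  hb <- outer(donA, accB, "&") | outer(accA, donB, "&")
  Rhb <- outer(tt$hbRij[ia], rep(1, length(ib))) * outer(accA, rep(TRUE, length(ib)))
  Rhb <- Rhb + outer(rep(1, length(ia)), tt$hbRij[ib]) * outer(rep(TRUE, length(ia)), accB)
  Ehb <- outer(tt$hbEps[ia], rep(1, length(ib))) * outer(accA, rep(TRUE, length(ib)))
  Ehb <- Ehb + outer(rep(1, length(ia)), tt$hbEps[ib]) * outer(rep(TRUE, length(ia)), accB)
  C12 <- ifelse(hb, 5 * Ehb * Rhb^12, 0)
  D10 <- ifelse(hb, 6 * Ehb * Rhb^10, 0)
  qq <- model@elecScale * outer(chargesA, chargesB)
  Sa <- tt$solpar[ia] + model@qsolpar * abs(chargesA)
  Sb <- tt$solpar[ib] + model@qsolpar * abs(chargesB)
  Va <- tt$vol[ia]; Vb <- tt$vol[ib]
  ds <- outer(Sa, Vb) + outer(Va, Sb)
  list(A12 = A12, B6 = B6, C12 = C12, D10 = D10, hb = hb, qq = qq, ds = ds)
}

## Pairwise energy components given a distance matrix and precomputed
## coefficients.  Distances beyond the cutoff contribute exactly zero;
## distances below the clash clamp are evaluated at the clamp distance and a
## linear penalty (added to the vdW channel) keeps the surface finite and
## monotone into the overlap region.
pairEnergies <- function(r, pc, model) {
  keep <- r <= model@cutoff
  if (!any(keep))
    return(c(vdw = 0, hbond = 0, elec = 0, desolv = 0))
  rc <- pmax(r, model@clashDist)
  inv2 <- 1 / (rc * rc)
  inv6 <- inv2 * inv2 * inv2
  inv10 <- inv6 * inv2 * inv2
  inv12 <- inv6 * inv6
  vdwM <- (pc$A12 * inv12 - pc$B6 * inv6) * !pc$hb
  hbM  <- (pc$C12 * inv12 - pc$D10 * inv10) * pc$hb
  clash <- r < model@clashDist
  if (any(clash)) vdwM[clash] <- vdwM[clash] +
      model@clashSlope * (model@clashDist - r[clash])
  elecM <- pc$qq / (dielectricAt(rc, model@dielectric) * rc)
  dsM <- pc$ds * exp(-(rc * rc) / (2 * model@sigma^2))
  c(vdw = sum(vdwM[keep]), hbond = sum(hbM[keep]),
    elec = sum(elecM[keep]), desolv = sum(dsM[keep]))
}

## Intraligand pair list: atom pairs three or more bonds apart whose distance
## can change with the torsions (the set of torsions moving atom i differs
## from the set moving atom j).  Rigid ligands have none.
intraPairs <- function(topo) {
  n <- nAtoms(topo)
  if (n < 2L || nTorsions(topo) == 0L) return(cbind(integer(), integer()))
  ## bond-graph shortest paths (BFS per atom; molecules are small)
  adj <- vector("list", n)
  for (k in seq_len(nrow(topo@bonds))) {
    i <- topo@bonds[k, 1]; j <- topo@bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
    }
    dist[s, ] <- d
  }
  movedBy <- matrix(FALSE, n, nTorsions(topo))
  for (k in seq_len(nTorsions(topo))) movedBy[topo@torsions[[k]]$moved, k] <- TRUE
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (dist[i, j] < 3) next
    if (any(xor(movedBy[i, ], movedBy[j, ]))) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) cbind(integer(), integer()) else do.call(rbind, out)
}

#' Precomputed scoring context for one receptor-ligand system
#'
#' Internal building block of [dockingContext()]; exported because the fast
#' scorer and the benchmark harness reuse it.
#'
#' @param topo a [LigandTopology-class].
#' @param receptor a [ReceptorModel-class].
#' @param model an [EnergyModel-class].
#' @return a list with precomputed inter- and intramolecular coefficients
#' @export
scoringSetup <- function(topo, receptor, model = defaultEnergyModel()) {
  la <- atomData(topo); ra <- atomData(receptor)
  inter <- if (nrow(ra)) {
    pairCoefficients(la$type, la$charge, ra$type, ra$charge, model)
  } else NULL
  ip <- intraPairs(topo)
  intra <- if (nrow(ip)) {
    pcAll <- pairCoefficients(la$type, la$charge, la$type, la$charge, model)
    idx <- cbind(ip[, 1], ip[, 2])
    list(pairs = ip,
         pc = list(A12 = pcAll$A12[idx], B6 = pcAll$B6[idx],
                   C12 = pcAll$C12[idx], D10 = pcAll$D10[idx],
                   hb = pcAll$hb[idx], qq = pcAll$qq[idx], ds = pcAll$ds[idx]))
  } else NULL
  out <- list(model = model, inter = inter, intra = intra,
              recCoords = refCoords(receptor), torsdof = topo@torsdof)
  out$fast <- fastEnergyClosure(topo, out)
  out
}

## Compiled inner loop: genome -> total energy.  Identical by construction to
## scoreFromSetup(decodePose(genome, topo), setup)$total; the test suite
## asserts the two routes agree to 1e-9.
fastEnergyClosure <- function(topo, setup) {
  model <- setup$model
  w <- model@weights
  nl <- nAtoms(topo)
  zero <- function(m) if (is.null(m)) matrix(0, nl, 0) else m
  inter <- setup$inter
  A12 <- zero(inter$A12); B6 <- zero(inter$B6)
  C12 <- zero(inter$C12); D10 <- zero(inter$D10)
  qq <- zero(inter$qq); ds <- zero(inter$ds)
  if (!is.null(inter)) {          # 12-6 and 12-10 are mutually exclusive
    A12[inter$hb] <- 0
    B6[inter$hb] <- 0
  }
  rec <- setup$recCoords
  if (!nrow(rec)) rec <- matrix(0, 0, 3)
  intra <- setup$intra
  if (is.null(intra)) {
    ii <- jj <- integer()
    iA12 <- iB6 <- iC12 <- iD10 <- iQq <- iDs <- numeric()
  } else {
    ii <- intra$pairs[, 1]; jj <- intra$pairs[, 2]
    hb <- intra$pc$hb
    iA12 <- ifelse(hb, 0, intra$pc$A12); iB6 <- ifelse(hb, 0, intra$pc$B6)
    iC12 <- intra$pc$C12; iD10 <- intra$pc$D10
    iQq <- intra$pc$qq; iDs <- intra$pc$ds
  }
  d <- model@dielectric
  par <- c(model@cutoff, model@clashDist, model@clashSlope,
           d[["A"]], d[["eps0"]] - d[["A"]], d[["lambda"]], d[["k"]],
           model@sigma, w[["vdw"]], w[["hbond"]], w[["elec"]], w[["desolv"]],
           w[["tor"]] * topo@torsdof)
  refC <- topo@refCoords
  rootA <- topo@rootAtoms
  torsAxis <- if (nTorsions(topo))
    do.call(rbind, lapply(topo@torsions, `[[`, "axis")) else
    matrix(integer(), 0, 2)
  storage.mode(torsAxis) <- "integer"
  torsMoved <- lapply(topo@torsions, `[[`, "moved")
  function(genome)
    .cpp_eval(genome, refC, rootA, torsAxis, torsMoved, rec,
              A12, B6, C12, D10, qq, ds, ii, jj,
              iA12, iB6, iC12, iD10, iQq, iDs, par)
}

#' Score decoded ligand coordinates
#'
#' Computes the full energy breakdown of a ligand pose against a rigid
#' receptor.  `total` is the sum of all components to within 1e-9.
#'
#' @param coords ligand coordinates (n x 3, A), e.g. from [decodePose()].
#' @param topo the [LigandTopology-class] the coordinates belong to.
#' @param receptor a [ReceptorModel-class] (may contain zero atoms, in which
#'   case only the torsional penalty and intraligand terms remain).
#' @param model an [EnergyModel-class].
#' @param setup optionally a precomputed [scoringSetup()] for this system.
#' @return named list: `vdw`, `hbond`, `elec`, `desolv`, `intramolecular`,
#'   `torsional`, `total` (kcal/mol-scaled scoring units)
#' @export
scorePose <- function(coords, topo, receptor, model = defaultEnergyModel(),
                      setup = NULL) {
  if (is.null(setup)) setup <- scoringSetup(topo, receptor, model)
  scoreFromSetup(as.matrix(coords), setup)
}

scoreFromSetup <- function(coords, setup) {
  model <- setup$model
  w <- model@weights
  comp <- c(vdw = 0, hbond = 0, elec = 0, desolv = 0)
  if (!is.null(setup$inter)) {
    R <- setup$recCoords
    d2 <- outer(rowSums(coords^2), rowSums(R^2), "+") - 2 * tcrossprod(coords, R)
    r <- sqrt(pmax(d2, 0))
    comp <- pairEnergies(r, setup$inter, model)
  }
  intra <- 0
  if (!is.null(setup$intra)) {
    ip <- setup$intra$pairs
    dv <- coords[ip[, 1], , drop = FALSE] - coords[ip[, 2], , drop = FALSE]
    ri <- sqrt(rowSums(dv^2))
    ce <- pairEnergies(ri, setup$intra$pc, model)
    intra <- sum(w[c("vdw", "hbond", "elec", "desolv")] * ce)
  }
  tor <- unname(w["tor"]) * setup$torsdof
  out <- list(vdw = unname(w["vdw"] * comp["vdw"]),
              hbond = unname(w["hbond"] * comp["hbond"]),
              elec = unname(w["elec"] * comp["elec"]),
              desolv = unname(w["desolv"] * comp["desolv"]),
              intramolecular = unname(intra),
              torsional = tor)
  out$total <- out$vdw + out$hbond + out$elec + out$desolv +
    out$intramolecular + out$torsional
  out
}

#' Reference scorer: naive double loop
#'
#' Independent re-derivation of the pairwise energy by explicit iteration
#' over atom pairs, recomputing every mixing rule from the raw type table.
#' Used to validate the vectorized scorer; orders of magnitude slower.
#'
#' @inheritParams scorePose
#' @return as [scorePose()]
#' @export
scorePoseNaive <- function(coords, topo, receptor, model = defaultEnergyModel()) {
  coords <- as.matrix(coords)
  tt <- model@typeTable
  w <- model@weights
  la <- atomData(topo); ra <- atomData(receptor)
  R <- refCoords(receptor)
  d <- model@dielectric
  pair <- function(ti, qi, xi, tj, qj, xj) {
    ri <- tt[match(ti, tt$type), ]; rj <- tt[match(tj, tt$type), ]
    r <- sqrt(sum((xi - xj)^2))
    if (r > model@cutoff) return(c(0, 0, 0, 0))
    rc <- max(r, model@clashDist)
    isHB <- (ri$hb == "D" && rj$hb == "A") || (ri$hb == "A" && rj$hb == "D")
    vdw <- hbe <- 0
    if (isHB) {
      acc <- if (ri$hb == "A") ri else rj
      hbe <- 5 * acc$hbEps * acc$hbRij^12 / rc^12 - 6 * acc$hbEps * acc$hbRij^10 / rc^10
    } else {
      Rij <- (ri$Rii + rj$Rii) / 2
      eij <- sqrt(ri$epsii * rj$epsii)
      vdw <- eij * Rij^12 / rc^12 - 2 * eij * Rij^6 / rc^6
    }
    if (r < model@clashDist) vdw <- vdw + model@clashSlope * (model@clashDist - r)
    eps <- d[["A"]] + (d[["eps0"]] - d[["A"]]) /
      (1 + d[["k"]] * exp(-d[["lambda"]] * (d[["eps0"]] - d[["A"]]) * rc))
    elec <- model@elecScale * qi * qj / (eps * rc)
    si <- ri$solpar + model@qsolpar * abs(qi)
    sj <- rj$solpar + model@qsolpar * abs(qj)
    des <- (si * rj$vol + sj * ri$vol) * exp(-rc^2 / (2 * model@sigma^2))
    c(vdw, hbe, elec, des)
  }
  comp <- c(0, 0, 0, 0)
  for (i in seq_len(nrow(coords))) for (j in seq_len(nrow(R)))
    comp <- comp + pair(la$type[i], la$charge[i], coords[i, ],
                        ra$type[j], ra$charge[j], R[j, ])
  intra <- 0
  ip <- intraPairs(topo)
  for (k in seq_len(nrow(ip))) {
    i <- ip[k, 1]; j <- ip[k, 2]
    ce <- pair(la$type[i], la$charge[i], coords[i, ],
               la$type[j], la$charge[j], coords[j, ])
    intra <- intra + sum(w[c("vdw", "hbond", "elec", "desolv")] * ce)
  }
  tor <- unname(w["tor"]) * topo@torsdof
  out <- list(vdw = unname(w["vdw"] * comp[1]), hbond = unname(w["hbond"] * comp[2]),
              elec = unname(w["elec"] * comp[3]), desolv = unname(w["desolv"] * comp[4]),
              intramolecular = unname(intra), torsional = tor)
  out$total <- out$vdw + out$hbond + out$elec + out$desolv +
    out$intramolecular + out$torsional
  out
}
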