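## PDBQT input/output (AutoDock dialect).
##
## Fixed-width records: coordinates in columns 31-54, partial charge in
## 67-76, atom type code in 78-79.  The reader is tolerant of trailing
## whitespace and intolerant of shifted columns: a field that does not parse
## as a number is reported with its line number.  Ligand files carry the
## torsion tree as ROOT/ENDROOT, nested BRANCH/ENDBRANCH, and TORSDOF
## records; branch axis atoms are referenced by their file serials.

parseAtomLine <- function(line, lineNo) {
  get <- function(from, to) trimws(substr(line, from, to))
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(get(from, to)))
    if (is.na(v))
      stop(sprintf("line %d: malformed %s field in '%s'", lineNo, what,
                   trimws(line)), call. = FALSE)
    v
  }
  list(serial = as.integer(num(7, 11, "serial")),
       name = get(13, 16),
       resName = get(18, 21),
       chain = get(22, 22),
       resSeq = suppressWarnings(as.integer(get(23, 26))),
       x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
       charge = num(67, 76, "charge"),
       type = get(78, 79))
}

formatAtomLine <- function(record, serial, name, resName, chain, resSeq,
                           x, y, z, charge, type) {
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          record, serial, substr(name, 1, 4), "", substr(resName, 1, 4),
          chain, resSeq, x, y, z, 1.00, 0.00, charge, type)
}

#' Read a receptor PDBQT file
#'
#' Parses ATOM/HETATM records; water residues (HOH/WAT) are dropped with a
#' message stating the count; atoms whose type code is not in the energy
#' model's table are rejected with their line numbers.
#'
#' @param path PDBQT file.
#' @param model [EnergyModel-class] whose type table defines the known atom
#'   types.
#' @param boxCenter,boxHalf optional explicit search box (A); default is the
#'   receptor bounding box padded by 4 A.
#' @return a [ReceptorModel-class]
#' @export
readReceptorPdbqt <- function(path, model = defaultEnergyModel(),
                              boxCenter = NULL, boxHalf = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(isAtom)) stop("no atoms in ", path)
  recs <- lapply(which(isAtom), function(i) parseAtomLine(lines[i], i))
  resNames <- vapply(recs, `[[`, character(1), "resName")
  water <- resNames %in% c("HOH", "WAT")
  if (any(water))
    message(sprintf("dropped %d water atom(s) from %s", sum(water), basename(path)))
  recs <- recs[!water]
  lineNos <- which(isAtom)[!water]
  if (!length(recs)) stop("no atoms left after water removal in ", path)
  types <- vapply(recs, `[[`, character(1), "type")
  unknown <- !(types %in% model@typeTable$type)
  if (any(unknown))
    stop("unknown atom type(s) at line(s) ",
         paste(lineNos[unknown], collapse = ", "), ": ",
         paste(unique(types[unknown]), collapse = ", "))
  atoms <- data.frame(
    name = vapply(recs, `[[`, character(1), "name"),
    element = typeToElement(types),
    type = types,
    charge = vapply(recs, `[[`, numeric(1), "charge"),
    resName = vapply(recs, `[[`, character(1), "resName"),
    resSeq = vapply(recs, function(r) if (is.na(r$resSeq)) 1L else r$resSeq, integer(1)))
  coords <- t(vapply(recs, function(r) c(r$x, r$y, r$z), numeric(3)))
  ReceptorModel(atoms, coords, boxCenter = boxCenter, boxHalf = boxHalf)
}

#' Read a ligand PDBQT file
#'
#' Requires exactly one ROOT block.  The torsion tree is rebuilt from the
#' BRANCH nesting: each BRANCH a b defines a rotatable bond whose moved atom
#' set is every atom inside the branch block except the axis atom b itself.
#' Bonds are inferred from interatomic distances (heavy-heavy below 1.9 A,
#' X-H below 1.3 A) since PDBQT carries no explicit bond records.
#'
#' @param path PDBQT file.
#' @param model [EnergyModel-class] defining known atom types.
#' @return a [LigandTopology-class]
#' @export
readLigandPdbqt <- function(path, model = defaultEnergyModel()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  serialToIdx <- integer()
  recs <- list()
  rootAtoms <- integer()
  torsions <- list()
  stack <- integer()          # indices into `torsions` of open branches
  inRoot <- FALSE; rootSeen <- FALSE; rootClosed <- FALSE
  torsdof <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^(ATOM|HETATM)", ln)) {
      r <- parseAtomLine(ln, i)
      recs[[length(recs) + 1L]] <- r
      idx <- length(recs)
      serialToIdx[as.character(r$serial)] <- idx
      if (inRoot) rootAtoms <- c(rootAtoms, idx)
      if (length(stack))
        for (s in stack) torsions[[s]]$block <- c(torsions[[s]]$block, idx)
    } else if (grepl("^ROOT", ln)) {
      if (rootSeen) stop("line ", i, ": multiple ROOT blocks")
      inRoot <- TRUE; rootSeen <- TRUE
    } else if (grepl("^ENDROOT", ln)) {
      if (!inRoot) stop("line ", i, ": ENDROOT without ROOT")
      inRoot <- FALSE; rootClosed <- TRUE
    } else if (grepl("^BRANCH", ln)) {
      f <- as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]][2:3])
      if (anyNA(f)) stop("line ", i, ": malformed BRANCH record")
      torsions[[length(torsions) + 1L]] <-
        list(serials = f, block = integer(),
             parent = if (length(stack)) stack[length(stack)] else 0L)
      stack <- c(stack, length(torsions))
    } else if (grepl("^ENDBRANCH", ln)) {
      if (!length(stack)) stop("line ", i, ": ENDBRANCH without BRANCH")
      stack <- stack[-length(stack)]
    } else if (grepl("^TORSDOF", ln)) {
      torsdof <- as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]][2])
    }
  }
  if (length(stack)) stop("unbalanced BRANCH/ENDBRANCH: ",
                          length(stack), " branch(es) left open")
  if (!rootSeen) stop("no ROOT block in ", path)
  if (!length(rootAtoms)) stop("zero-atom ROOT block in ", path)
  if (!length(recs)) stop("no atoms in ", path)
  types <- vapply(recs, `[[`, character(1), "type")
  unknown <- !(types %in% model@typeTable$type)
  if (any(unknown))
    stop("unknown atom type(s): ", paste(unique(types[unknown]), collapse = ", "))
  coords <- t(vapply(recs, function(r) c(r$x, r$y, r$z), numeric(3)))
  atoms <- data.frame(
    name = vapply(recs, `[[`, character(1), "name"),
    element = typeToElement(types),
    type = types,
    charge = vapply(recs, `[[`, numeric(1), "charge"),
    resName = vapply(recs, `[[`, character(1), "resName"),
    resSeq = vapply(recs, function(r) if (is.na(r$resSeq)) 1L else r$resSeq, integer(1)))
  tors <- lapply(torsions, function(t) {
    a <- serialToIdx[as.character(t$serials[1])]
    b <- serialToIdx[as.character(t$serials[2])]
    if (is.na(a) || is.na(b))
      stop("BRANCH references unknown atom serial(s): ",
           paste(t$serials, collapse = " "))
    list(axis = c(a, b), moved = setdiff(t$block, b), parent = t$parent)
  })
  bonds <- inferBonds(coords, typeToElement(types))
  ## branch axes are bonds by definition; make sure they are present
  for (t in tors) {
    hit <- (bonds[, 1] == t$axis[1] & bonds[, 2] == t$axis[2]) |
           (bonds[, 1] == t$axis[2] & bonds[, 2] == t$axis[1])
    if (!any(hit)) bonds <- rbind(bonds, t$axis)
  }
  LigandTopology(atoms, coords, bonds, tors, rootAtoms = rootAtoms,
                 torsdof = if (is.na(torsdof)) length(tors) else torsdof)
}

## Distance-based bond inference; PDBQT has no bond records.
inferBonds <- function(coords, elements) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(max(0L, n - 1L))) for (j in seq.int(i + 1L, n)) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    lim <- if (elements[i] == "H" || elements[j] == "H") 1.3 else 1.9
    if (elements[i] == "H" && elements[j] == "H") lim <- 0
    if (d < lim) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) matrix(integer(), 0, 2) else do.call(rbind, out)
}

#' Write a ligand (or pose) as PDBQT
#'
#' Emits the full torsion tree (ROOT / nested BRANCH / TORSDOF).  Optional
#' REMARK lines can carry run metadata.
#'
#' @param topo a [LigandTopology-class].
#' @param path output file.
#' @param coords coordinates to write (default the template conformation).
#' @param remarks character vector of REMARK payloads.
#' @return invisibly, the path
#' @export
writeLigandPdbqt <- function(topo, path, coords = refCoords(topo),
                             remarks = character()) {
  atoms <- atomData(topo)
  n <- nrow(atoms)
  childrenOf <- function(parent)
    which(vapply(topo@torsions, function(t) t$parent == parent, logical(1)))
  ownAtoms <- function(k) {   # atoms of branch k not inside a child branch
    t <- topo@torsions[[k]]
    inChild <- unlist(lapply(childrenOf(k), function(c2)
      c(topo@torsions[[c2]]$axis[2], topo@torsions[[c2]]$moved)))
    c(t$axis[2], setdiff(t$moved, inChild))
  }
  atomLine <- function(i)
    formatAtomLine("ATOM", i, atoms$name[i], atoms$resName[i], "A",
                   atoms$resSeq[i], coords[i, 1], coords[i, 2], coords[i, 3],
                   atoms$charge[i], atoms$type[i])
  out <- c(sprintf("REMARK %s", remarks))
  out <- c(out, "ROOT", vapply(topo@rootAtoms, atomLine, character(1)), "ENDROOT")
  emitBranch <- function(k) {
    t <- topo@torsions[[k]]
    res <- sprintf("BRANCH %4d %4d", t$axis[1], t$axis[2])
    res <- c(res, vapply(sort(ownAtoms(k)), atomLine, character(1)))
    for (c2 in childrenOf(k)) res <- c(res, emitBranch(c2))
    c(res, sprintf("ENDBRANCH %4d %4d", t$axis[1], t$axis[2]))
  }
  for (k in childrenOf(0L)) out <- c(out, emitBranch(k))
  ## root-attached atoms that belong to no branch (rigid ligands)
  inTree <- c(topo@rootAtoms, unlist(lapply(seq_along(topo@torsions), ownAtoms)))
  loose <- setdiff(seq_len(n), inTree)
  if (length(loose)) {
    ## rigid appendage: emit within the ROOT block instead
    out <- c(sprintf("REMARK %s", remarks), "ROOT",
             vapply(sort(c(topo@rootAtoms, loose)), atomLine, character(1)),
             "ENDROOT")
    for (k in childrenOf(0L)) out <- c(out, emitBranch(k))
  }
  out <- c(out, sprintf("TORSDOF %d", topo@torsdof))
  writeLines(out, path)
  invisible(path)
}

#' Write a receptor as PDBQT
#'
#' @param receptor a [ReceptorModel-class].
#' @param path output file.
#' @return invisibly, the path
#' @export
writeReceptorPdbqt <- function(receptor, path) {
  atoms <- atomData(receptor)
  coords <- refCoords(receptor)
  out <- vapply(seq_len(nrow(atoms)), function(i)
    formatAtomLine("ATOM", i, atoms$name[i], atoms$resName[i], "A",
                   atoms$resSeq[i], coords[i, 1], coords[i, 2], coords[i, 3],
                   atoms$charge[i], atoms$type[i]), character(1))
  writeLines(out, path)
  invisible(path)
}

#' Write docking results
#'
#' Writes the best pose as `pose.pdbqt` (REMARK lines carry the energy, the
#' RMSD, the seed, the full-precision genome, and a configuration hash) and a
#' machine-readable run table `runs.tsv` with one row per run:
#' `run_id, algorithm, seed, final_energy, rmsd, evaluations`.  Output is
#' deterministic: rewriting the same results is byte-identical.
#'
#' @param runs a [DockingRun-class] or list of them.
#' @param topo the [LigandTopology-class] the runs docked.
#' @param dir output directory (created if missing).
#' @param config the `cepdock_config` used (hashed into the REMARKs).
#' @return invisibly, the directory
#' @export
writeResults <- function(runs, topo, dir, config = NULL) {
  if (is(runs, "DockingRun")) runs <- list(runs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  energies <- vapply(runs, bestEnergy, numeric(1))
  best <- runs[[which.min(energies)]]
  cfgHash <- configHash(if (is.null(config)) "default"
                        else paste(names(config), unlist(config),
                                   sep = "=", collapse = ";"))
  remarks <- c(
    sprintf("cepdock best pose (%s)", best@algorithm),
    sprintf("ENERGY %.6f", bestEnergy(best)),
    sprintf("RMSD %.6f", finalRmsd(best)),
    sprintf("SEED %d", best@seed),
    sprintf("CONFIG_HASH %s", cfgHash),
    sprintf("GENOME %s", paste(sprintf("%.17g", bestGenome(best)), collapse = " ")))
  writeLigandPdbqt(topo, file.path(dir, "pose.pdbqt"),
                   coords = decodePose(bestGenome(best), topo),
                   remarks = remarks)
  tab <- data.frame(
    run_id = seq_along(runs),
    algorithm = vapply(runs, function(r) r@algorithm, character(1)),
    seed = vapply(runs, function(r) r@seed, integer(1)),
    final_energy = sprintf("%.6f", energies),
    rmsd = sprintf("%.6f", vapply(runs, finalRmsd, numeric(1))),
    evaluations = vapply(runs, function(r) r@evaluations, integer(1)))
  write.table(tab, file.path(dir, "runs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Recover the genome stored in a pose PDBQT's REMARK
#'
#' @param path a `pose.pdbqt` written by [writeResults()].
#' @return numeric genome at full precision
#' @export
readPoseGenome <- function(path) {
  lines <- readLines(path)
  g <- grep("^REMARK GENOME ", lines, value = TRUE)
  if (!length(g)) stop("no GENOME remark in ", path)
  as.numeric(strsplit(sub("^REMARK GENOME ", "", g[1]), " +")[[1]])
}
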