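## Pose genome and kinematic decoder.
##
## A genome is a plain numeric vector of length 7 + T:
##   [1:3]  translation (A) applied to the whole ligand,
##   [4:7]  unit quaternion (w, x, y, z) rotating the ligand about the
##          centroid of its ROOT-block atoms,
##   [7+k]  torsion angle (radians, wrapped to (-pi, pi]) of rotatable bond k.

QUAT <- 4:7  # quaternion gene positions

#' Build a pose genome
#'
#' @param translation length-3 numeric (A).
#' @param orientation length-4 quaternion `(w, x, y, z)`; renormalized.
#' @param torsions numeric vector of torsion angles (radians), wrapped to
#'   `(-pi, pi]`.
#' @return numeric genome of length `7 + length(torsions)`
#' @export
newGenome <- function(translation = c(0, 0, 0),
                      orientation = c(1, 0, 0, 0),
                      torsions = numeric()) {
  stopifnot(length(translation) == 3L, length(orientation) == 4L)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation quaternion has zero norm")
  c(translation, orientation / nrm, wrapAngle(torsions))
}

#' Identity genome for a ligand (reproduces the template conformation)
#' @param topo a [LigandTopology-class]
#' @return numeric genome
#' @export
identityGenome <- function(topo)
  newGenome(torsions = numeric(nTorsions(topo)))

#' Wrap angles to the half-open interval (-pi, pi]
#' @param x numeric vector of angles (radians)
#' @return wrapped angles
#' @export
wrapAngle <- function(x) {
  w <- x %% (2 * pi)          # in [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

## quaternion (w,x,y,z) -> 3x3 rotation matrix
quatToMat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

## Hamilton product q1 * q2
quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

## axis (unit not required) + angle -> quaternion
axisAngleQuat <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

## Rodrigues rotation of points (m x 3) about the line through `origin` with
## unit direction `u` by `angle`.
rotatePoints <- function(pts, origin, u, angle) {
  V <- sweep(pts, 2, origin)
  cv <- cbind(u[2] * V[, 3] - u[3] * V[, 2],
              u[3] * V[, 1] - u[1] * V[, 3],
              u[1] * V[, 2] - u[2] * V[, 1])
  dv <- as.vector(V %*% u)
  W <- V * cos(angle) + cv * sin(angle) +
    tcrossprod(dv * (1 - cos(angle)), u)
  sweep(W, 2, origin, "+")
}

#' Decode a genome into ligand coordinates
#'
#' Applies the torsion genes depth-first from the ROOT outward (in PDBQT
#' record order), then rotates the whole ligand by the quaternion about the
#' centroid of the ROOT-block atoms, then translates.  Bond lengths and all
#' angles not spanning a rotatable bond are preserved to machine precision.
#'
#' @param genome numeric genome of length `7 + nTorsions(topo)`.
#' @param topo a [LigandTopology-class].
#' @return n x 3 coordinate matrix (A)
#' @export
decodePose <- function(genome, topo) {
  nt <- nTorsions(topo)
  if (length(genome) != 7L + nt)
    stop(sprintf("genome length %d does not match 7 + %d torsions",
                 length(genome), nt))
  q <- genome[QUAT]
  nrm <- sqrt(sum(q^2))
  if (nrm == 0) stop("zero-norm orientation quaternion")
  if (abs(nrm - 1) > 1e-9) {
    warning("non-unit orientation quaternion; renormalizing")
  }
  q <- q / nrm
  X <- topo@refCoords
  for (k in seq_len(nt)) {
    ang <- genome[7L + k]
    if (ang == 0) next
    tor <- topo@torsions[[k]]
    a <- tor$axis[1L]; b <- tor$axis[2L]
    u <- X[b, ] - X[a, ]
    u <- u / sqrt(sum(u^2))
    X[tor$moved, ] <- rotatePoints(X[tor$moved, , drop = FALSE], X[b, ], u, ang)
  }
  ctr <- colMeans(X[topo@rootAtoms, , drop = FALSE])
  R <- quatToMat(q)
  X <- sweep(X, 2, ctr) %*% t(R)
  sweep(X, 2, ctr + genome[1:3], "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Docking RMSD: computed in the fixed receptor frame, with no optimal
#' superposition and no symmetry correction.  Callers comparing ligand poses
#' should pass heavy-atom coordinates only (see [heavyAtoms()]); [ligandRmsd()]
#' does this for you.
#'
#' @param a,b n x 3 coordinate matrices in the same atom order (A).
#' @return RMSD in A (non-negative, symmetric in its arguments)
#' @export
poseRmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Heavy-atom RMSD between a genome (or pose) and reference coordinates
#'
#' @param pose either a genome vector or an n x 3 coordinate matrix.
#' @param reference n x 3 reference coordinates (all atoms, template order).
#' @param topo the [LigandTopology-class] (identifies hydrogens).
#' @return heavy-atom RMSD (A)
#' @export
ligandRmsd <- function(pose, reference, topo) {
  coords <- if (is.matrix(pose)) pose else decodePose(pose, topo)
  h <- heavyAtoms(topo)
  poseRmsd(coords[h, , drop = FALSE], reference[h, , drop = FALSE])
}

#' Docking validity criterion
#'
#' A docked pose is counted valid iff its heavy-atom RMSD to the reference
#' structure is strictly less than 2.0 A; a pose at exactly 2.0 A is invalid.
#'
#' @param rmsd non-negative RMSD value(s) in A.
#' @return logical
#' @export
isValidPose <- function(rmsd) {
  if (any(rmsd < 0)) stop("RMSD cannot be negative")
  rmsd < 2.0
}
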