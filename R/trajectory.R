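## Trajectory post-processing: mean-square fluctuations, pair-distance
## statistics and hydrogen-bond occupancy.

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame; the atom table is taken from the
#' first model and must be constant across frames.
#'
#' @param file path to a (multi-model) PDB file.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  atoms <- pdb$atom[, c("eleno", "elety", "resid", "chain", "resno")]
  atoms$elesy <- elementOf(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  new("Trajectory", atoms = atoms, xyz = unclass(xyz)[, , drop = FALSE])
}

#' Select atom indices
#'
#' Atoms can be addressed by any combination of chain, residue number and
#' atom name, or by a compact \code{"chain:resno:atomname"} string (empty
#' fields are wildcards, e.g. \code{"A:87:CA"} or \code{"::CA"}).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param spec optional selection string.
#' @param chain,resno,elety field filters.
#' @return integer atom indices.
#' @export
selectAtoms <- function(traj, spec = NULL, chain = NULL, resno = NULL,
                        elety = NULL) {
  at <- atomTable(traj)
  if (!is.null(spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    parts <- c(parts, rep("", 3L - length(parts)))
    if (nzchar(parts[1L])) chain <- parts[1L]
    if (nzchar(parts[2L])) resno <- as.integer(parts[2L])
    if (nzchar(parts[3L])) elety <- parts[3L]
  }
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & trimws(at$elety) %in% elety
  which(keep)
}

frameCoords <- function(traj, frame) {
  matrix(traj@xyz[frame, ], ncol = 3L, byrow = TRUE)
}

## Kabsch superposition: least-squares rotation + translation of P onto Q.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

applyFit <- function(X, fit) {
  sweep(sweep(X, 2L, fit$cp) %*% t(fit$R), 2L, fit$cq, "+")
}

#' Mean-square fluctuation relative to the first frame
#'
#' Optionally superposes every frame onto the first by least-squares
#' (Kabsch) over the fit selection (default: CA atoms), then computes per
#' selected atom the mean over frames of the squared displacement from its
#' first-frame position, in squared Angstrom.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param sel atom indices to report (default: CA atoms).
#' @param superpose remove rigid-body motion first.
#' @param fitSel atom indices used for the superposition (default: CA
#'   atoms, or all atoms if no CA present).
#' @return named numeric vector of MSF values (names \code{chain:resno:name}).
#' @export
msf <- function(traj, sel = NULL, superpose = TRUE, fitSel = NULL) {
  if (is.null(sel)) sel <- selectAtoms(traj, elety = "CA")
  if (!length(sel)) stop("selection matches 0 atoms")
  if (is.null(fitSel)) {
    fitSel <- selectAtoms(traj, elety = "CA")
    if (!length(fitSel)) fitSel <- seq_len(nrow(atomTable(traj)))
  }
  ref <- frameCoords(traj, 1L)
  nf <- nFrames(traj)
  acc <- numeric(length(sel))
  for (f in seq_len(nf)) {
    X <- frameCoords(traj, f)
    if (superpose) X <- applyFit(X, kabsch(X[fitSel, , drop = FALSE],
                                           ref[fitSel, , drop = FALSE]))
    d <- X[sel, , drop = FALSE] - ref[sel, , drop = FALSE]
    acc <- acc + rowSums(d^2)
  }
  at <- atomTable(traj)[sel, ]
  setNames(acc / nf,
           paste(at$chain, at$resno, trimws(at$elety), sep = ":"))
}

resolveOneAtom <- function(traj, spec) {
  idx <- if (is.numeric(spec)) as.integer(spec) else selectAtoms(traj, spec)
  if (length(idx) != 1L)
    stop("atom specification '", paste(spec, collapse = ":"),
         "' matches ", length(idx), " atoms (need exactly 1)")
  idx
}

#' Pair-distance statistics over a trajectory
#'
#' Per-frame Euclidean distance between two atoms (typically the CA atoms
#' of a residue pair), summarised as mean and population standard
#' deviation.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param atomA,atomB atom index or \code{"chain:resno:atomname"} string.
#' @return list with \code{mean}, \code{sd} and the per-frame
#'   \code{distances}.
#' @export
pairDistanceStats <- function(traj, atomA, atomB) {
  ia <- resolveOneAtom(traj, atomA)
  ib <- resolveOneAtom(traj, atomB)
  d <- vapply(seq_len(nFrames(traj)), function(f) {
    X <- frameCoords(traj, f)
    sqrt(sum((X[ia, ] - X[ib, ])^2))
  }, numeric(1))
  list(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)), distances = d)
}

#' Hydrogen-bond occupancy
#'
#' Fraction of frames in which the donor-acceptor heavy-atom distance is at
#' most \code{dMax} and the donor-hydrogen...acceptor angle (180 degrees =
#' linear, measured at the hydrogen) is at least \code{angleMin}; both
#' boundaries inclusive. The hydrogen must be present in the coordinates:
#' no implicit-hydrogen geometry is inferred.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param donor,hydrogen,acceptor atom index or selection string.
#' @param dMax donor-acceptor distance threshold (Angstrom).
#' @param angleMin D-H...A angle threshold (degrees).
#' @return occupancy in [0, 1], with the per-frame criteria in
#'   \code{attr(, "frames")}.
#' @export
hbondOccupancy <- function(traj, donor, hydrogen, acceptor, dMax = 3.4,
                           angleMin = 120) {
  id <- resolveOneAtom(traj, donor)
  ih <- tryCatch(resolveOneAtom(traj, hydrogen), error = function(e)
    stop("hydrogen atom not resolvable (", conditionMessage(e),
         "); explicit hydrogens are required"))
  ia <- resolveOneAtom(traj, acceptor)
  ok <- vapply(seq_len(nFrames(traj)), function(f) {
    X <- frameCoords(traj, f)
    da <- sqrt(sum((X[id, ] - X[ia, ])^2))
    v1 <- X[id, ] - X[ih, ]
    v2 <- X[ia, ] - X[ih, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    da <= dMax && ang >= angleMin
  }, logical(1))
  structure(mean(ok), frames = ok)
}
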