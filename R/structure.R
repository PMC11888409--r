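## Structure-based residue annotation: solvent accessibility (Shrake-Rupley),
## burial classes, interface detection and per-residue map painting.

## Van der Waals radii (Angstrom) for heavy atoms commonly seen in protein
## crystal structures, plus the metals relevant to metalloenzymes.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, CU = 1.40, ZN = 1.39, FE = 1.40, MG = 1.73,
               MN = 1.40, CA = 1.97, K = 2.75, "NA" = 2.27, CL = 1.75)

## Theoretical maximum accessible surface areas (Angstrom^2) per residue,
## from the extended Gly-X-Gly tripeptide reference (Tien et al. 2013,
## "theoretical" column), used to normalise ASA into relative solvent
## accessibility.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

## Deterministic quasi-uniform points on the unit sphere (golden spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

elementOf <- function(atom) {
  ele <- toupper(trimws(atom$elesy %||% ""))
  ele[is.na(ele)] <- ""
  guess <- function(name) {
    name <- gsub("[0-9'\\\"]", "", toupper(trimws(name)))
    two <- substr(name, 1L, 2L)
    ifelse(two %in% names(VDW_RADII) & nchar(name) > 1L &
             two %in% c("SE", "CU", "ZN", "FE", "MG", "MN", "CL", "NA"),
           two, substr(name, 1L, 1L))
  }
  ifelse(ele == "", guess(atom$elety), ele)
}

#' Shrake-Rupley accessible surface area
#'
#' Classic point-sampling algorithm: each atom's solvent-accessible sphere
#' (van der Waals radius plus probe radius) is sampled with a deterministic
#' quasi-uniform point set and the accessible fraction is the share of
#' points not buried inside any neighbouring atom's sphere.
#'
#' @param coords numeric matrix (n x 3) of heavy-atom coordinates.
#' @param elements character vector of element symbols (must be tabulated
#'   in the built-in van der Waals radius table, or supply \code{radii}).
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints sphere sample points per atom.
#' @param radii optional named radius overrides.
#' @return numeric vector of per-atom ASA in Angstrom^2.
#' @export
shrakeRupley <- function(coords, elements, probeRadius = 1.4,
                         nPoints = 960L, radii = VDW_RADII) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("no atoms supplied (atom count 0)")
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown))
    stop("no van der Waals radius tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(radii[elements]) + probeRadius
  pts <- spherePoints(nPoints)
  n <- nrow(coords)
  asa <- numeric(n)
  ## neighbour search on squared distances
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- pts * r[i] + matrix(coords[i, ], nPoints, 3L, byrow = TRUE)
    if (length(nb)) {
      buried <- rep(FALSE, nPoints)
      for (j in nb) {
        dx <- surf[, 1L] - coords[j, 1L]
        dy <- surf[, 2L] - coords[j, 2L]
        dz <- surf[, 3L] - coords[j, 3L]
        buried <- buried | (dx * dx + dy * dy + dz * dz < r[j]^2)
        if (all(buried)) break
      }
      frac <- mean(!buried)
    } else frac <- 1
    asa[i] <- frac * 4 * pi * r[i]^2
  }
  asa
}

pdbHeavyAtoms <- function(pdb, chain = NULL) {
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" | atoms$type == "HETATM", ]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, ]
  atoms$element <- elementOf(atoms)
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", ]
  atoms
}

#' Relative solvent accessibility per residue
#'
#' Computes Shrake-Rupley ASA over the heavy atoms of the selected chains
#' and normalises per-residue sums by the theoretical Gly-X-Gly maximum for
#' the residue type. Values may exceed 1 for extended conformations.
#' Residues are classified \code{core} (rsa < 0.20), \code{surface}
#' (rsa > 0.35) or \code{intermediate}.
#'
#' @param pdb a \code{bio3d} pdb object (see [bio3d::read.pdb()]) or a
#'   path to a PDB file.
#' @param chain optional chain selection; default all chains (complex
#'   context). Pass a single chain to get the monomer context.
#' @param probeRadius,nPoints see [shrakeRupley()].
#' @param coreBelow,surfaceAbove classification thresholds.
#' @return data.frame: \code{chain}, \code{resno}, \code{resid},
#'   \code{asa}, \code{rsa}, \code{sclass}.
#' @export
computeRsa <- function(pdb, chain = NULL, probeRadius = 1.4,
                       nPoints = 960L, coreBelow = 0.20,
                       surfaceAbove = 0.35) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  atoms <- pdbHeavyAtoms(pdb, chain)
  if (nrow(atoms) == 0L) stop("no atoms supplied (atom count 0)")
  asa <- shrakeRupley(as.matrix(atoms[, c("x", "y", "z")]), atoms$element,
                      probeRadius = probeRadius, nPoints = nPoints)
  ## hetero records (waters, metals, ligands) occlude but are not reported
  prot <- atoms$type == "ATOM"
  key <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "|")
  res_asa <- tapply(asa[prot], key[prot], sum)
  parts <- strsplit(names(res_asa), "|", fixed = TRUE)
  resid <- vapply(parts, `[[`, character(1), 3L)
  untab <- setdiff(unique(resid), names(MAX_ASA))
  if (length(untab))
    stop("no maximum ASA tabulated for residue type(s): ",
         paste(untab, collapse = ", "))
  rsa <- as.vector(res_asa) / unname(MAX_ASA[resid])
  out <- data.frame(
    chain = vapply(parts, `[[`, character(1), 1L),
    resno = as.integer(vapply(parts, `[[`, character(1), 2L)),
    resid = resid,
    asa = as.vector(res_asa),
    rsa = rsa,
    stringsAsFactors = FALSE)
  out$sclass <- ifelse(out$rsa < coreBelow, "core",
                       ifelse(out$rsa > surfaceAbove, "surface",
                              "intermediate"))
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Interface residues between two chains
#'
#' A residue is interfacial if any of its heavy atoms lies within
#' \code{cutoff} of any heavy atom of the partner chain.
#'
#' @param pdb bio3d pdb object or path.
#' @param chainA,chainB chain identifiers.
#' @param cutoff distance threshold in Angstrom.
#' @return list with the interfacial residue numbers of each chain
#'   (\code{chainA}, \code{chainB}) and the contact pair table
#'   (\code{pairs}).
#' @export
interfaceResidues <- function(pdb, chainA, chainB, cutoff = 5.0) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  atoms <- pdbHeavyAtoms(pdb)
  for (ch in c(chainA, chainB))
    if (!ch %in% atoms$chain) stop("unknown chain id: ", ch)
  a <- atoms[atoms$chain == chainA, ]
  b <- atoms[atoms$chain == chainB, ]
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  hit <- which(d2 <= cutoff^2 & cutoff > 0, arr.ind = TRUE)
  pairs <- data.frame(resno_a = a$resno[hit[, 1L]],
                      resno_b = b$resno[hit[, 2L]],
                      dist = sqrt(pmax(d2[hit], 0)))
  list(chainA = sort(unique(pairs$resno_a)),
       chainB = sort(unique(pairs$resno_b)),
       pairs = pairs)
}

#' Overlap of interface residue sets
#'
#' Membership of each residue across the homodimer interface and the two
#' chaperone-complex interfaces (Zn-bound and Zn-free), Venn region counts,
#' and the transient set: residues binding only when the metal is bound
#' (\code{ccs_zn} minus \code{ccs_apo}).
#'
#' @param homodimer,ccs_zn,ccs_apo integer vectors of residue numbers on a
#'   common numbering.
#' @return list with \code{membership} (data.frame), \code{regions} (named
#'   counts over the 7 Venn regions) and \code{transient}.
#' @export
interfaceSetOverlap <- function(homodimer, ccs_zn, ccs_apo) {
  all_res <- sort(unique(c(homodimer, ccs_zn, ccs_apo)))
  membership <- data.frame(
    resno = all_res,
    homodimer = all_res %in% homodimer,
    ccs_zn = all_res %in% ccs_zn,
    ccs_apo = all_res %in% ccs_apo)
  pattern <- paste0(ifelse(membership$homodimer, "H", ""),
                    ifelse(membership$ccs_zn, "Z", ""),
                    ifelse(membership$ccs_apo, "A", ""))
  regions <- table(factor(pattern,
                          levels = c("H", "Z", "A", "HZ", "HA", "ZA", "HZA")))
  list(membership = membership,
       regions = as.vector(regions) |> setNames(names(regions)),
       transient = sort(setdiff(ccs_zn, ccs_apo)))
}

#' Paint per-position values onto a structure
#'
#' Writes a per-residue scalar (typically the positional median functional
#' score) into the temperature-factor column of a structure and optionally
#' emits the painted PDB. Residues without a value receive the sentinel.
#'
#' @param pdb bio3d pdb object or path.
#' @param values named numeric vector; names are map positions.
#' @param offset added to map positions to obtain structure residue
#'   numbers.
#' @param sentinel B-factor for unscored residues.
#' @param file optional output PDB path.
#' @return the modified pdb object (invisibly if written to file).
#' @export
paintStructure <- function(pdb, values, offset = 0L, sentinel = -1,
                           file = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  target <- as.integer(names(values)) + offset
  hit <- pdb$atom$resno %in% target
  if (!any(hit))
    stop("no structure residues matched the painted positions ",
         "(check the numbering offset)")
  b <- rep(sentinel, nrow(pdb$atom))
  idx <- match(pdb$atom$resno, target)
  b[!is.na(idx)] <- unname(values)[idx[!is.na(idx)]]
  pdb$atom$b <- round(b, 2L)
  if (!is.null(file)) {
    bio3d::write.pdb(pdb, file = file)
    return(invisible(pdb))
  }
  pdb
}

#' Write a residue annotation table
#'
#' @param annotation data.frame from [computeRsa()] (optionally augmented
#'   with interface columns).
#' @param file TSV path.
#' @export
writeAnnotation <- function(annotation, file) {
  write.table(annotation, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
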