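## Shared fixtures, all built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

## One default-scale simulation + scoring run (the study conditions:
## L = 153, depth 1.3e6, 2 replicates), computed once per test session.
defaultRunFixture <- function() {
  if (!exists("run", envir = .fixture_cache)) {
    cfg <- simulationConfig(seed = 42L)
    orf <- randomOrf(cfg@L, seed = 42L)
    variants <- enumerateVariantSpace(orf)
    truth <- simulateTruth(variants, cfg)
    counts <- simulateCountTables(truth, cfg)
    scores <- scoreTileseq(counts)
    assign("run", list(cfg = cfg, orf = orf, variants = variants,
                       truth = truth, counts = counts, scores = scores),
           envir = .fixture_cache)
  }
  get("run", envir = .fixture_cache)
}

## Deterministic (not sampled) count fixture for the spreadsheet-style
## oracle: nVar variants, two replicates, counts set by explicit formulas.
oracleCountsFixture <- function(nVar = 40L, depth = 1e6) {
  pos <- seq_len(nVar)
  vclass <- rep(c("missense", "synonymous", "nonsense", "missense"),
                length.out = nVar)
  from <- rep("A", nVar)
  to <- ifelse(vclass == "synonymous", "A",
               ifelse(vclass == "nonsense", "*",
                      rep(c("V", "G"), length.out = nVar)))
  hp <- hgvsP(pos, from, to)
  ## pre counts rise with index; post depends on class; wt error flat-ish
  base <- 200 + 40 * pos
  enrich <- ifelse(vclass == "nonsense", 0.12,
                   ifelse(vclass == "synonymous", 1.1, 0.9))
  wt <- 5 + (pos %% 3)
  counts <- cbind(
    "pre.1" = base + wt,
    "pre.2" = base + 10 + wt,
    "post.1" = round((base + 2 * pos) * enrich) + wt,
    "post.2" = round((base + 25 - 2 * pos) * enrich) + wt,
    "wt_pre.1" = wt, "wt_pre.2" = wt + 1,
    "wt_post.1" = wt, "wt_post.2" = wt + 1)
  rownames(counts) <- hp
  depth_m <- matrix(depth, nVar, ncol(counts), dimnames = dimnames(counts))
  cd <- do.call(rbind, strsplit(colnames(counts), ".", fixed = TRUE))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, depth = depth_m),
    rowData = data.frame(hgvs_p = hp, position = pos, from_aa = from,
                         to_aa = to, vclass = vclass,
                         tile = rep(1L, nVar)),
    colData = S4Vectors::DataFrame(condition = cd[, 1],
                                   replicate = as.integer(cd[, 2]),
                                   row.names = colnames(counts)))
  new("TileseqCounts", se)
}

## Build a ScoreSet directly from a score vector (for map-level tests).
scoreSetFixture <- function(position, from_aa, to_aa, score, se = 0.05) {
  vclass <- variantClass(from_aa, to_aa)
  n <- length(score)
  tab <- data.frame(hgvs_p = if (n) hgvsP(position, from_aa, to_aa)
                      else character(0),
                    position = position, from_aa = from_aa, to_aa = to_aa,
                    vclass = vclass, score = score,
                    se = rep_len(se, n), df = rep_len(3, n),
                    flags = rep_len("", n), stringsAsFactors = FALSE)
  new("ScoreSet", table = tab, anchors = c(nonsense = 0, synonymous = 1),
      params = list())
}

## --- minimal PDB writing ----------------------------------------------

pdbAtomLine <- function(serial, name, resid, chain, resno, xyz,
                        element, record = "ATOM") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name)
    else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

## atoms: data.frame(name, resid, chain, resno, x, y, z, element)
writePdbFixture <- function(atoms, file, frames = NULL) {
  lines <- character()
  one_model <- function(coords) {
    vapply(seq_len(nrow(atoms)), function(i) {
      pdbAtomLine(i, atoms$name[i], atoms$resid[i], atoms$chain[i],
                  atoms$resno[i], unlist(coords[i, c("x", "y", "z")]),
                  atoms$element[i])
    }, character(1))
  }
  if (is.null(frames)) {
    lines <- c(one_model(atoms), "END")
  } else {
    for (f in seq_along(frames)) {
      co <- atoms
      co[, c("x", "y", "z")] <- frames[[f]]
      lines <- c(lines, sprintf("MODEL %8d", f), one_model(co), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, file)
  file
}

## Free glycine residue with idealised backbone geometry.
glycineAtoms <- function(chain = "A", resno = 1L, shift = c(0, 0, 0)) {
  data.frame(
    name = c("N", "CA", "C", "O"),
    resid = "GLY", chain = chain, resno = resno,
    x = c(0.000, 1.458, 2.009, 1.383) + shift[1],
    y = c(0.000, 0.000, 1.420, 2.390) + shift[2],
    z = c(0.000, 0.000, 0.000, 0.000) + shift[3],
    element = c("N", "C", "C", "O"),
    stringsAsFactors = FALSE)
}

## Alanine with CB at a controllable location.
alanineAtoms <- function(chain, resno, origin) {
  data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    resid = "ALA", chain = chain, resno = resno,
    x = origin[1] + c(0.000, 1.458, 2.009, 1.383, 1.988),
    y = origin[2] + c(0.000, 0.000, 1.420, 2.390, -0.773),
    z = origin[3] + c(0.000, 0.000, 0.000, 0.000, 1.205),
    element = c("N", "C", "C", "O", "C"),
    stringsAsFactors = FALSE)
}

## Independent grid-sampling ASA oracle (Shrake-Rupley at kx point
## density, re-implemented with plain loops).
gridAsaOracle <- function(coords, elements, probeRadius = 1.4,
                          nPoints = 9600L) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  r <- unname(radii[elements]) + probeRadius
  i_seq <- seq_len(nPoints) - 0.5
  phi <- acos(1 - 2 * i_seq / nPoints)
  theta <- pi * (1 + sqrt(5)) * i_seq
  unit <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  n <- nrow(coords)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0L
    for (p in seq_len(nPoints)) {
      pt <- coords[i, ] + r[i] * unit[p, ]
      buried <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - coords[j, ])^2) < r[j]^2) { buried <- TRUE; break }
      }
      if (!buried) acc <- acc + 1L
    }
    asa[i] <- acc / nPoints * 4 * pi * r[i]^2
  }
  asa
}
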