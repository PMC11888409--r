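## Trajectory fixtures shared between the trajectory and acceptance suites.

## Three-residue toy protein with CA atoms plus one donor/hydrogen/acceptor
## triplet for hydrogen-bond geometry.
trajAtoms <- function() {
  data.frame(
    name = c("CA", "CA", "CA", "N", "H", "O"),
    resid = c("GLY", "GLY", "GLY", "GLY", "GLY", "GLY"),
    chain = "A",
    resno = c(1L, 2L, 3L, 1L, 1L, 3L),
    x = c(0, 3.8, 7.6, 0.5, 1.5, 3.0),
    y = c(0, 0, 0, 2, 2, 2),
    z = 0,
    element = c("C", "C", "C", "N", "H", "O"),
    stringsAsFactors = FALSE)
}

makeTraj <- function(frames) {
  at <- trajAtoms()
  f <- tempfile(fileext = ".pdb")
  readTrajectory(writePdbFixture(at, f, frames = frames))
}

baseCoords <- function() as.matrix(trajAtoms()[, c("x", "y", "z")])

## donor at origin-ish, hydrogen on x; acceptor placed for a given D-A
## distance and D-H...A angle (degrees, at the hydrogen)
hbFrame <- function(dist_da, angle) {
  co <- baseCoords()
  co[4, ] <- c(0, 2, 0)              # donor N
  co[5, ] <- c(1, 2, 0)              # hydrogen
  th <- angle * pi / 180
  u <- c(-cos(th), sin(th), 0)       # direction H -> A
  h <- co[5, ]; dn <- co[4, ]
  f <- function(s) sqrt(sum((h + s * u - dn)^2)) - dist_da
  s <- uniroot(f, c(1e-6, 50))$root
  co[6, ] <- h + s * u
  co
}
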