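#' Construct simulation settings
#'
#' Defaults describe the study conditions the scoring pipeline is designed
#' for: a ~150-residue protein sequenced in five tiles at 1.3 million reads
#' per tile, two biological replicates, a mean of 0.64 codon substitutions
#' per clone and a bimodal missense effect distribution with ~15% of
#' missense variants in the damaged mode.
#'
#' @param L protein length (residues, excluding stop).
#' @param depth reads per tile per condition per replicate.
#' @param replicates biological replicates per condition.
#' @param cloneLambda mean codon substitutions per clone.
#' @param deleteriousFraction probability a missense effect comes from the
#'   damaged mode (centred at 0); the complement comes from the tolerated
#'   mode (centred at 1).
#' @param modeSd sd of each effect mode.
#' @param errorShape,errorScale gamma parameters of the per-variant
#'   sequencing-error frequency; defaults give a mean of 5 reads per million,
#'   the ballpark for duplex-sequencing residual error.
#' @param selectionFloor residual survival of a null variant.
#' @param replicateNoiseSd log-normal sd (natural log) on each variant's
#'   selection weight, drawn independently per replicate; emulates the
#'   replicate-to-replicate growth/sorting variability seen in real
#'   selections. See the vignette for how the default was chosen.
#' @param poolSize number of independent clones in the transformant pool.
#' @param tiles number of sequencing tiles.
#' @param seed root RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(L = 10, depth = 1e4)
#' @export
simulationConfig <- function(L = 153L, depth = 1.3e6, replicates = 2L,
                             cloneLambda = 0.64, deleteriousFraction = 0.15,
                             modeSd = 0.08, errorShape = 2,
                             errorScale = 2.5e-6, selectionFloor = 0.05,
                             replicateNoiseSd = 0.5, poolSize = 1e6,
                             tiles = 5L, seed = 42L) {
  tiles <- min(as.integer(tiles), as.integer(L))
  new("SimulationConfig", L = as.integer(L), depth = depth,
      replicates = as.integer(replicates), cloneLambda = cloneLambda,
      deleteriousFraction = deleteriousFraction, modeSd = modeSd,
      errorShape = errorShape, errorScale = errorScale,
      selectionFloor = selectionFloor, replicateNoiseSd = replicateNoiseSd,
      poolSize = poolSize, tiles = tiles, seed = as.integer(seed))
}

#' Scenario presets for the two assay flavours
#'
#' The activity (yeast growth selection) and abundance (VAMP-seq) scenarios
#' share the selection formalism and differ only in their defaults: mean
#' substitutions per clone (0.64 vs 0.83) and damaged-mode weight
#' (0.14 vs 0.18).
#'
#' @param ... overrides passed to [simulationConfig()].
#' @return a \linkS4class{SimulationConfig}.
#' @export
activityScenario <- function(...) {
  args <- list(...)
  defaults <- list(cloneLambda = 0.64, deleteriousFraction = 0.14)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

#' @rdname activityScenario
#' @export
abundanceScenario <- function(...) {
  args <- list(...)
  defaults <- list(cloneLambda = 0.83, deleteriousFraction = 0.18)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}
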