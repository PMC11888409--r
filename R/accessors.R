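#' @rdname ScoreSet-class
#' @aliases scoreTable,ScoreSet-method
setMethod("scoreTable", "ScoreSet", function(x) x@table)

#' @rdname ScoreSet-class
#' @aliases anchors,ScoreSet-method
setMethod("anchors", "ScoreSet", function(x) x@anchors)

#' @rdname EffectMap-class
#' @aliases scoreMatrix,EffectMap-method
setMethod("scoreMatrix", "EffectMap", function(x) x@score)

#' @rdname EffectMap-class
#' @aliases seMatrix,EffectMap-method
setMethod("seMatrix", "EffectMap", function(x) x@se)

#' @rdname EffectMap-class
#' @aliases classMatrix,EffectMap-method
setMethod("classMatrix", "EffectMap", function(x) x@classes)

#' @rdname EffectMap-class
#' @aliases wtSequence,EffectMap-method
setMethod("wtSequence", "EffectMap", function(x) x@wtSeq)

#' @rdname EffectMap-class
#' @aliases consensus,EffectMap-method
setMethod("consensus", "EffectMap", function(x) x@consensus)

#' @rdname CalibrationReport-class
#' @aliases aubprc,CalibrationReport-method
setMethod("aubprc", "CalibrationReport", function(x) x@aubprc)

#' @rdname CalibrationReport-class
#' @aliases r90bp,CalibrationReport-method
setMethod("r90bp", "CalibrationReport", function(x) x@r90bp)

#' @rdname CalibrationReport-class
#' @aliases curvePoints,CalibrationReport-method
setMethod("curvePoints", "CalibrationReport", function(x) x@curve)

#' @rdname CalibrationReport-class
#' @aliases llrTable,CalibrationReport-method
setMethod("llrTable", "CalibrationReport", function(x) x@llr)

#' @rdname Trajectory-class
#' @aliases nFrames,Trajectory-method
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' @rdname Trajectory-class
#' @aliases atomTable,Trajectory-method
setMethod("atomTable", "Trajectory", function(x) x@atoms)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@L, "residues,",
      object@replicates, "replicates, depth",
      format(object@depth, big.mark = ","), "\n")
  cat("  cloneLambda:", object@cloneLambda,
      " deleteriousFraction:", object@deleteriousFraction,
      " modeSd:", object@modeSd, "\n")
  cat("  selectionFloor:", object@selectionFloor,
      " replicateNoiseSd:", object@replicateNoiseSd,
      " tiles:", object@tiles, " seed:", object@seed, "\n")
})

setMethod("show", "ScoreSet", function(object) {
  tab <- object@table
  cat("ScoreSet with", nrow(tab), "variants (",
      sum(!is.na(tab$score)), "scored )\n")
  cat("  anchors (log2 scale): nonsense =",
      signif(object@anchors[["nonsense"]], 4),
      ", synonymous =", signif(object@anchors[["synonymous"]], 4), "\n")
})

setMethod("show", "EffectMap", function(object) {
  cat("EffectMap:", length(object@wtSeq), "positions x",
      ncol(object@score), "residues;",
      sum(!is.na(object@score)), "scored cells\n")
  cat("  damaging threshold:", object@threshold, "\n")
})

setMethod("show", "CalibrationReport", function(object) {
  cat("CalibrationReport: AUBPRC =", round(object@aubprc, 3),
      ", R90BP =", round(object@r90bp, 3), "\n")
  if (nrow(object@llr))
    cat(" ", nrow(object@llr), "variants with LLRp\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@xyz), "frames,",
      nrow(object@atoms), "atoms\n")
})
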