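#' @rdname ScoreSet-class
#' @param x a \code{ScoreSet}.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname ScoreSet-class
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname EffectMap-class
#' @param x an \code{EffectMap}.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname EffectMap-class
#' @export
setGeneric("seMatrix", function(x) standardGeneric("seMatrix"))

#' @rdname EffectMap-class
#' @export
setGeneric("classMatrix", function(x) standardGeneric("classMatrix"))

#' @rdname EffectMap-class
#' @export
setGeneric("wtSequence", function(x) standardGeneric("wtSequence"))

#' @rdname EffectMap-class
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname CalibrationReport-class
#' @param x a \code{CalibrationReport}.
#' @export
setGeneric("aubprc", function(x) standardGeneric("aubprc"))

#' @rdname CalibrationReport-class
#' @export
setGeneric("r90bp", function(x) standardGeneric("r90bp"))

#' @rdname CalibrationReport-class
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @rdname CalibrationReport-class
#' @export
setGeneric("llrTable", function(x) standardGeneric("llrTable"))

#' @rdname Trajectory-class
#' @param x a \code{Trajectory}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
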