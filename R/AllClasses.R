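#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation settings for a synthetic TileSeq selection experiment
#'
#' Holds the study conditions emulated by the synthetic-data generator:
#' library depth, replicate structure, clone statistics, the bimodal
#' true-effect model and the per-variant sequencing-error model.
#'
#' @slot L protein length in residues (excluding the stop codon).
#' @slot depth reads per tile per condition per replicate.
#' @slot replicates number of biological replicates per condition.
#' @slot cloneLambda mean codon substitutions per clone (Poisson mean).
#' @slot deleteriousFraction probability that a missense effect is drawn from
#'   the damaged mode.
#' @slot modeSd standard deviation of each true-effect mode.
#' @slot errorShape,errorScale gamma shape/scale of the per-variant
#'   sequencing-error frequency (reads/read).
#' @slot selectionFloor residual survival of a fully null variant.
#' @slot replicateNoiseSd log-normal sd (natural log) applied to each
#'   variant's selection weight independently per replicate, emulating
#'   growth/sorting stochasticity between biological replicates.
#' @slot poolSize number of clones in the transformant pool.
#' @slot tiles number of sequencing tiles the ORF is split into.
#' @slot seed root RNG seed; per-stage substreams are derived from it.
#' @seealso [simulationConfig()], [activityScenario()], [abundanceScenario()]
#' @export
setClass("SimulationConfig", representation(
  L = "integer",
  depth = "numeric",
  replicates = "integer",
  cloneLambda = "numeric",
  deleteriousFraction = "numeric",
  modeSd = "numeric",
  errorShape = "numeric",
  errorScale = "numeric",
  selectionFloor = "numeric",
  replicateNoiseSd = "numeric",
  poolSize = "numeric",
  tiles = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@L < 1) msg <- c(msg, "L must be >= 1")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (object@cloneLambda <= 0) msg <- c(msg, "cloneLambda must be > 0")
  if (object@deleteriousFraction < 0 || object@deleteriousFraction > 1)
    msg <- c(msg, "deleteriousFraction must be in [0, 1]")
  if (object@modeSd < 0) msg <- c(msg, "modeSd must be >= 0")
  if (object@errorShape <= 0 || object@errorScale < 0)
    msg <- c(msg, "error model parameters must be positive")
  if (object@selectionFloor < 0 || object@selectionFloor > 1)
    msg <- c(msg, "selectionFloor must be in [0, 1]")
  if (object@replicateNoiseSd < 0) msg <- c(msg, "replicateNoiseSd must be >= 0")
  if (object@poolSize < 1) msg <- c(msg, "poolSize must be >= 1")
  if (object@tiles < 1 || object@tiles > object@L)
    msg <- c(msg, "tiles must be in [1, L]")
  if (length(msg)) msg else TRUE
})

#' TileSeq variant count container
#'
#' A \linkS4class{SummarizedExperiment} with one row per variant and one
#' column per (condition, replicate) sample. Assay \code{"counts"} holds raw
#' read counts and assay \code{"depth"} the per-tile sequencing depth of the
#' sample the row's tile was counted in (so \code{counts/depth} is the allele
#' frequency). Row metadata carries the variant descriptors
#' (\code{hgvs_p}, \code{position}, \code{from_aa}, \code{to_aa},
#' \code{vclass}, \code{tile}); column metadata carries \code{condition}
#' (\code{pre}, \code{post}, \code{wt_pre}, \code{wt_post}) and
#' \code{replicate}. The per-tile wild-type reference counts (reads carrying
#' no variant in the tile) are kept in
#' \code{metadata(x)$wt_counts}.
#'
#' @export
setClass("TileseqCounts", contains = "SummarizedExperiment")

setValidity("TileseqCounts", function(object) {
  msg <- character()
  need_assays <- c("counts", "depth")
  if (!all(need_assays %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'counts' and 'depth' are required")
  need_row <- c("hgvs_p", "position", "from_aa", "to_aa", "vclass", "tile")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(need_row %in% colnames(rd)))
    msg <- c(msg, paste("rowData needs columns:",
                        paste(need_row, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData needs columns 'condition' and 'replicate'")
  else if (!all(cd$condition %in% c("pre", "post", "wt_pre", "wt_post")))
    msg <- c(msg, "condition must be pre/post/wt_pre/wt_post")
  if (length(msg)) msg else TRUE
})

#' Rescaled functional scores with uncertainties
#'
#' Result of the scoring pipeline: one row per variant with the rescaled
#' functional score (0 = nonsense median, 1 = synonymous median), its
#' standard error, degrees of freedom and filter flags. Variants excluded by
#' filters are retained with \code{NA} score and their flags.
#'
#' @slot table data.frame with columns \code{hgvs_p}, \code{position},
#'   \code{from_aa}, \code{to_aa}, \code{vclass}, \code{score}, \code{se},
#'   \code{df}, \code{flags} (comma-separated, \code{""} if none).
#' @slot anchors named numeric: the nonsense and synonymous medians on the
#'   combined log2-enrichment scale used for rescaling.
#' @slot params list of scoring parameters used.
#' @export
setClass("ScoreSet", representation(
  table = "data.frame",
  anchors = "numeric",
  params = "list"
))

setValidity("ScoreSet", function(object) {
  need <- c("hgvs_p", "position", "from_aa", "to_aa", "vclass",
            "score", "se", "df", "flags")
  if (!all(need %in% colnames(object@table)))
    return(paste("score table needs columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Position-by-residue variant effect map
#'
#' @slot score,se numeric matrices, positions x (20 residues + stop).
#' @slot classes character matrix of the same shape with entries
#'   \code{damaging}, \code{tolerated}, \code{hyper}, \code{missing} or
#'   \code{wt}.
#' @slot wtSeq one-letter wild-type residue per position.
#' @slot consensus per-position median of missense scores.
#' @slot threshold damaging-score threshold used for classification.
#' @export
setClass("EffectMap", representation(
  score = "matrix",
  se = "matrix",
  classes = "matrix",
  wtSeq = "character",
  consensus = "numeric",
  threshold = "numeric"
))

setValidity("EffectMap", function(object) {
  L <- length(object@wtSeq)
  dims_ok <- all(dim(object@score) == c(L, length(AA_COLUMNS)),
                 dim(object@se) == c(L, length(AA_COLUMNS)),
                 dim(object@classes) == c(L, length(AA_COLUMNS)))
  if (!dims_ok) return("matrices must be L x 21 (20 residues + stop)")
  ok_class <- object@classes %in%
    c("damaging", "tolerated", "hyper", "missing", "wt")
  if (!all(ok_class)) return("invalid cell class")
  wt_idx <- cbind(seq_len(L), match(object@wtSeq, AA_COLUMNS))
  if (any(!is.na(object@score[wt_idx]))) return("wt cells must carry no score")
  TRUE
})

#' Benchmarking and clinical-calibration report
#'
#' @slot curve data.frame of curve points (\code{threshold}, \code{recall},
#'   \code{fpr}, \code{balanced_precision}).
#' @slot aubprc area under the balanced precision vs recall curve.
#' @slot r90bp maximum recall at balanced precision >= 0.90 (0 if never).
#' @slot llr data.frame per scored variant: \code{hgvs_p}, \code{score},
#'   \code{llr}, \code{ci_lo}, \code{ci_hi}, \code{evidence}.
#' @slot params list (orientation, bandwidths, op_vst, ...).
#' @export
setClass("CalibrationReport", representation(
  curve = "data.frame",
  aubprc = "numeric",
  r90bp = "numeric",
  llr = "data.frame",
  params = "list"
))

#' Coordinate trajectory
#'
#' A light container for a multi-model (trajectory-style) structure: a fixed
#' atom table plus one coordinate row per frame.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety},
#'   \code{resid}, \code{chain}, \code{resno}, \code{elesy}.
#' @slot xyz numeric matrix, frames x (3 * n_atoms), ordered x,y,z per atom.
#' @export
setClass("Trajectory", representation(
  atoms = "data.frame",
  xyz = "matrix"
))

setValidity("Trajectory", function(object) {
  if (nrow(object@xyz) < 1) return("at least one frame is required")
  if (ncol(object@xyz) != 3L * nrow(object@atoms))
    return("xyz must have 3 columns per atom")
  TRUE
})
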