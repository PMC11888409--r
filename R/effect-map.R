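## Position x residue effect map assembly and tolerance classification.

#' Assemble a position-by-residue effect map
#'
#' Fills an L x 21 (20 residues + stop) matrix of scores and standard
#' errors. Cells are classified as \code{damaging} when the score falls
#' below the map-specific tolerance threshold, \code{hyper} when it exceeds
#' 1 + 2 se (above wild type beyond noise), \code{tolerated} otherwise,
#' \code{missing} where no score is available and \code{wt} on the
#' wild-type residue.
#'
#' @param scores a \linkS4class{ScoreSet} (or its \code{scoreTable()}
#'   data.frame).
#' @param wtSequence one-letter wild-type protein sequence (character
#'   vector or single string).
#' @param threshold damaging-score threshold; the customary values are 0.5
#'   for an activity map and -0.4 for an abundance map.
#' @param hyperSe number of standard errors above 1 required for the
#'   \code{hyper} call.
#' @return an \linkS4class{EffectMap}.
#' @export
buildEffectMap <- function(scores, wtSequence, threshold = 0.5,
                           hyperSe = 2) {
  tab <- if (is(scores, "ScoreSet")) scoreTable(scores) else scores
  if (length(wtSequence) == 1L && nchar(wtSequence[1L]) > 1L)
    wtSequence <- strsplit(wtSequence, "")[[1L]]
  L <- length(wtSequence)
  if (nrow(tab) && any(tab$position < 1L | tab$position > L))
    stop("scores reference positions outside [1, ", L, "]")
  mismatch <- tab$from_aa != wtSequence[tab$position]
  if (any(mismatch))
    stop("variant ", tab$hgvs_p[which(mismatch)[1L]],
         " disagrees with the wild-type residue at position ",
         tab$position[which(mismatch)[1L]], " (numbering mismatch?)")

  dims <- list(seq_len(L), AA_COLUMNS)
  score <- matrix(NA_real_, L, length(AA_COLUMNS), dimnames = dims)
  se <- score
  scored <- tab[!is.na(tab$score), ]
  idx <- cbind(scored$position, match(scored$to_aa, AA_COLUMNS))
  score[idx] <- scored$score
  se[idx] <- scored$se

  classes <- matrix("missing", L, length(AA_COLUMNS), dimnames = dims)
  classes[!is.na(score)] <- "tolerated"
  classes[!is.na(score) & score < threshold] <- "damaging"
  hyper <- !is.na(score) & !is.na(se) & score > 1 + hyperSe * se
  classes[hyper] <- "hyper"
  wt_idx <- cbind(seq_len(L), match(wtSequence, AA_COLUMNS))
  score[wt_idx] <- NA_real_
  se[wt_idx] <- NA_real_
  classes[wt_idx] <- "wt"

  mis_cols <- setdiff(AA_COLUMNS, AA_STOP)
  cons <- vapply(seq_len(L), function(p) {
    v <- score[p, mis_cols]
    v <- v[!is.na(v) & mis_cols != wtSequence[p]]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))

  new("EffectMap", score = score, se = se, classes = classes,
      wtSeq = wtSequence, consensus = cons, threshold = threshold)
}

#' Data-driven tolerance threshold from the bimodal score distribution
#'
#' Kernel-density estimate over missense scores; the threshold is the
#' location of the density minimum between the two modes. The valley is
#' chosen by prominence — among all interior minima, the one maximising the
#' ratio of the lower flanking peak to the valley density — so small
#' sampling wiggles on a single peak are not mistaken for modes. If no
#' valley reaches \code{minDepthRatio} the distribution is treated as
#' unimodal and the configured fallback is returned with a warning.
#'
#' @param scores numeric vector of missense scores (>= 100 required).
#' @param fallback value returned when no two modes are found; the
#'   customary defaults are 0.5 (activity) and -0.4 (abundance).
#' @param bw bandwidth selector passed to [stats::density()];
#'   Sheather-Jones by default (Silverman's rule oversmooths mixtures).
#' @param minDepthRatio minimum peak-to-valley density ratio required to
#'   call the distribution bimodal.
#' @return threshold (numeric scalar), with attributes \code{"modes"} (the
#'   two mode locations) and \code{"depth_ratio"} when found.
#' @export
findBimodalThreshold <- function(scores, fallback = 0.5, bw = "SJ",
                                 minDepthRatio = 1.5) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 100L)
    stop("need >= 100 missense scores to locate the bimodal minimum (",
         length(scores), " given)")
  d <- density(scores, bw = bw, n = 1024L)
  y <- d$y
  maxima <- which(diff(sign(diff(y))) == -2) + 1L
  minima <- which(diff(sign(diff(y))) == 2) + 1L
  best <- NULL
  for (v in minima) {
    left <- maxima[maxima < v]
    right <- maxima[maxima > v]
    if (!length(left) || !length(right)) next
    ratio <- min(max(y[left]), max(y[right])) / max(y[v], 1e-300)
    if (is.null(best) || ratio > best$ratio)
      best <- list(v = v, ratio = ratio,
                   il = left[which.max(y[left])],
                   ir = right[which.max(y[right])])
  }
  if (is.null(best) || best$ratio < minDepthRatio) {
    warning("score distribution appears unimodal; returning fallback ",
            fallback)
    return(fallback)
  }
  ## threshold: centre of the minimal-density plateau between the two
  ## modes (stable when the inter-mode density underflows to a flat zero)
  between <- seq(best$il, best$ir)
  ymin <- min(y[between])
  plateau <- between[y[between] <= ymin + 1e-8 * max(y)]
  thr <- d$x[plateau[ceiling(length(plateau) / 2)]]
  structure(thr, modes = c(d$x[best$il], d$x[best$ir]),
            depth_ratio = best$ratio)
}

#' Deleteriousness vectors by target and origin residue
#'
#' Median score over all substitutions \emph{to} each of the 20 amino acids
#' and \emph{from} each observed wild-type residue, optionally compared to
#' user-supplied reference vectors by Spearman correlation.
#'
#' @param map an \linkS4class{EffectMap}.
#' @param referenceTo,referenceFrom optional named numeric vectors to
#'   correlate against.
#' @return list with \code{to}, \code{from} (named numeric) and, when
#'   references are given, \code{to_cor}/\code{from_cor} (each a list with
#'   \code{rho} and \code{p}; \code{rho = NA} with note \code{"undefined"}
#'   for constant input).
#' @export
deleteriousnessVectors <- function(map, referenceTo = NULL,
                                   referenceFrom = NULL) {
  stopifnot(is(map, "EffectMap"))
  sc <- scoreMatrix(map)
  mis_cols <- setdiff(AA_COLUMNS, AA_STOP)
  wt <- wtSequence(map)
  ## missense cells only
  mm <- sc[, mis_cols, drop = FALSE]
  to_vec <- apply(mm, 2L, median, na.rm = TRUE)
  from_vec <- vapply(split(seq_along(wt), wt), function(rows) {
    median(mm[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  out <- list(to = to_vec, from = from_vec)
  if (!is.null(referenceTo))
    out$to_cor <- safeSpearman(to_vec, referenceTo)
  if (!is.null(referenceFrom))
    out$from_cor <- safeSpearman(from_vec, referenceFrom)
  out
}

safeSpearman <- function(x, ref) {
  common <- intersect(names(x), names(ref))
  x <- x[common]; ref <- ref[common]
  keep <- is.finite(x) & is.finite(ref)
  x <- x[keep]; ref <- ref[keep]
  if (length(x) < 3L || sd(x) == 0 || sd(ref) == 0)
    return(list(rho = NA_real_, p = NA_real_, note = "undefined"))
  ct <- suppressWarnings(cor.test(x, ref, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
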