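## Clinical calibration: balanced precision-recall benchmarking,
## kernel-density log-likelihood ratios of pathogenicity, bootstrap CIs and
## ACMG/AMP-style evidence strengths.

#' Confusion-matrix summary
#'
#' @param predictedPositive logical: called pathogenic/non-functional.
#' @param actualPositive logical: truly pathogenic.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{tn},
#'   \code{precision}, \code{recall}.
#' @examples
#' # five pathogenic of which two fail the assay, three controls all pass:
#' confusionStats(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
#'                c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
confusionStats <- function(predictedPositive, actualPositive) {
  stopifnot(length(predictedPositive) == length(actualPositive))
  tp <- sum(predictedPositive & actualPositive)
  fp <- sum(predictedPositive & !actualPositive)
  fn <- sum(!predictedPositive & actualPositive)
  tn <- sum(!predictedPositive & !actualPositive)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

resolveRefScores <- function(scores, refsets) {
  get_set <- function(set, label) {
    s <- scores[set]
    missing <- set[!set %in% names(scores) | is.na(s)]
    if (length(missing) == length(set))
      stop(label, " reference set has no scored variants; unscored: ",
           paste(head(missing, 10L), collapse = ", "))
    s[!is.na(s)]
  }
  list(pos = get_set(refsets$positives, "positive"),
       neg = get_set(refsets$negatives, "negative"))
}

#' Balanced precision vs recall curve
#'
#' Sweeps thresholds over the observed scores (lower score called
#' pathogenic by default; variants exactly at a threshold are called
#' pathogenic-side). Balanced precision re-weights the positive and
#' negative sets 50/50 via Bayes' rule,
#' \eqn{bp = recall / (recall + FPR)}, i.e. the precision that would be
#' observed under a balanced prior. The area under the curve (AUBPRC) uses
#' trapezoids over recall after keeping the maximum balanced precision per
#' distinct recall; R90BP is the maximum recall at balanced precision
#' >= 0.90 (0 if never reached).
#'
#' @param scores named numeric vector (names are variant labels).
#' @param refsets list with \code{positives} and \code{negatives} label
#'   vectors (see [simulateReferenceSets()]).
#' @param lowerIsPathogenic orientation; set \code{FALSE} for predictors
#'   whose high scores indicate pathogenicity.
#' @param minScored minimum scored variants required per set.
#' @return a \linkS4class{CalibrationReport} with the curve part filled in.
#' @export
balancedPrcCurve <- function(scores, refsets, lowerIsPathogenic = TRUE,
                             minScored = 5L) {
  rs <- resolveRefScores(scores, refsets)
  if (length(rs$pos) < minScored || length(rs$neg) < minScored)
    stop("need >= ", minScored, " scored variants per reference set")
  sp <- if (lowerIsPathogenic) rs$pos else -rs$pos
  sn <- if (lowerIsPathogenic) rs$neg else -rs$neg
  thr <- sort(unique(c(sp, sn)))
  P <- length(sp); N <- length(sn)
  recall <- vapply(thr, function(t) sum(sp <= t), numeric(1)) / P
  fpr <- vapply(thr, function(t) sum(sn <= t), numeric(1)) / N
  bp <- ifelse(recall + fpr == 0, 1, recall / (recall + fpr))
  curve <- data.frame(threshold = if (lowerIsPathogenic) thr else -thr,
                      recall = recall, fpr = fpr, balanced_precision = bp)

  ## one point per distinct recall: best achievable balanced precision
  best <- tapply(bp, recall, max)
  r <- as.numeric(names(best))
  o <- order(r)
  r <- r[o]; b <- as.vector(best)[o]
  if (r[1L] > 0) { r <- c(0, r); b <- c(b[1L], b) }
  auc <- sum(diff(r) * (head(b, -1L) + b[-1L]) / 2)
  hit90 <- r[b >= 0.90]
  new("CalibrationReport", curve = curve, aubprc = auc,
      r90bp = if (length(hit90)) max(hit90) else 0,
      llr = data.frame(),
      params = list(lowerIsPathogenic = lowerIsPathogenic,
                    n_pos = P, n_neg = N))
}

## Epanechnikov kernel density scaled so its sd equals `bw` (the same
## convention stats::density() uses), evaluated at arbitrary points.
epanechnikovDensity <- function(x, data, bw) {
  a <- bw * sqrt(5)
  u <- outer(x, data, "-") / a
  k <- 1 - u^2
  k[k < 0] <- 0
  rowMeans(0.75 * k) / a
}

fitKde <- function(data, label) {
  if (length(unique(data)) < 2L)
    stop("cannot fit a density for the ", label,
         " set: zero bandwidth (constant scores)")
  bw <- tryCatch(bw.SJ(data), error = function(e)
    stop("bandwidth selection failed for the ", label, " set: ",
         conditionMessage(e)))
  list(data = data, bw = bw, a = bw * sqrt(5))
}

#' Kernel-density log-likelihood ratio of pathogenicity
#'
#' Separate densities are fitted to the positive (pathogenic) and negative
#' (benign) reference score sets with an Epanechnikov kernel and
#' Sheather-Jones bandwidth per set. The log-likelihood ratio is the
#' natural log of the density ratio, \eqn{LLRp(s) = \ln f_P(s)/f_B(s)}.
#' Query scores outside the joint support are clamped to the nearest
#' support edge, and each density is floored at \code{floorFrac} of its
#' maximum before the ratio, so extreme scores yield large but finite
#' ratios.
#'
#' @param scores named numeric vector of query scores.
#' @param refsets list with \code{positives}/\code{negatives} labels.
#' @param minScored minimum scored reference variants per set.
#' @param floorFrac density floor, as a fraction of each density's maximum.
#' @return data.frame \code{hgvs_p}, \code{score}, \code{llr}; bandwidths
#'   in \code{attr(, "bandwidths")}.
#' @export
kdeLlr <- function(scores, refsets, minScored = 20L, floorFrac = 1e-6) {
  rs <- resolveRefScores(scores, refsets)
  if (length(rs$pos) < minScored || length(rs$neg) < minScored)
    stop("need >= ", minScored, " scored variants per reference set")
  kp <- fitKde(rs$pos, "positive")
  kb <- fitKde(rs$neg, "negative")
  query <- scores[!is.na(scores)]
  out <- data.frame(hgvs_p = names(query), score = unname(query),
                    llr = evalLlr(unname(query), kp, kb, floorFrac),
                    stringsAsFactors = FALSE)
  attr(out, "bandwidths") <- c(positive = kp$bw, negative = kb$bw)
  out
}

evalLlr <- function(x, kp, kb, floorFrac = 1e-6) {
  lo <- max(min(kp$data) - kp$a, min(kb$data) - kb$a)
  hi <- min(max(kp$data) + kp$a, max(kb$data) + kb$a)
  if (lo > hi) { lo <- min(kp$data, kb$data); hi <- max(kp$data, kb$data) }
  xc <- pmin(pmax(x, lo), hi)
  grid <- seq(lo, hi, length.out = 512L)
  fp <- epanechnikovDensity(xc, kp$data, kp$bw)
  fb <- epanechnikovDensity(xc, kb$data, kb$bw)
  fp_max <- max(epanechnikovDensity(grid, kp$data, kp$bw))
  fb_max <- max(epanechnikovDensity(grid, kb$data, kb$bw))
  fp <- pmax(fp, floorFrac * fp_max)
  fb <- pmax(fb, floorFrac * fb_max)
  ## difference of logs keeps set-swap antisymmetry exact
  log(fp) - log(fb)
}

#' Bootstrap confidence intervals for LLRp
#'
#' Case-resampling bootstrap over each reference set independently; both
#' densities are refitted per resample and percentile 95% intervals are
#' taken per query variant. Resamples where a density cannot be fitted
#' (degenerate set) are dropped and counted.
#'
#' @param scores named numeric query scores.
#' @param refsets reference sets.
#' @param nBoot number of bootstrap resamples (>= 200).
#' @param seed RNG seed.
#' @param level confidence level.
#' @param floorFrac density floor (see [kdeLlr()]).
#' @return data.frame \code{hgvs_p}, \code{score}, \code{llr},
#'   \code{ci_lo}, \code{ci_hi}; dropped-resample count in
#'   \code{attr(, "dropped")}.
#' @export
llrConfidenceIntervals <- function(scores, refsets, nBoot = 1000L,
                                   seed = 1L, level = 0.95,
                                   floorFrac = 1e-6) {
  if (nBoot < 200L) stop("nBoot must be >= 200")
  point <- kdeLlr(scores, refsets, floorFrac = floorFrac)
  rs <- resolveRefScores(scores, refsets)
  set.seed(stageSeed(seed, "boot"))
  q <- point$score
  boots <- matrix(NA_real_, nrow = nBoot, ncol = length(q))
  dropped <- 0L
  for (b in seq_len(nBoot)) {
    bp <- sample(rs$pos, replace = TRUE)
    bn <- sample(rs$neg, replace = TRUE)
    res <- tryCatch({
      kp <- fitKde(bp, "positive")
      kb <- fitKde(bn, "negative")
      evalLlr(q, kp, kb, floorFrac)
    }, error = function(e) NULL)
    if (is.null(res)) dropped <- dropped + 1L else boots[b, ] <- res
  }
  alpha <- (1 - level) / 2
  ci <- apply(boots, 2L, quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- point
  out$ci_lo <- ci[1L, ]
  out$ci_hi <- ci[2L, ]
  attr(out, "dropped") <- dropped
  attr(out, "bandwidths") <- attr(point, "bandwidths")
  out
}

#' ACMG/AMP-style evidence strength from LLRp
#'
#' Thresholds follow the log-odds ladder of the Tavtigian odds-of-
#' pathogenicity framework: with \code{opVst} the odds corresponding to
#' very-strong evidence, the pathogenic-side cutoffs are
#' \eqn{\ln opVst^{1/8}, \ln opVst^{1/4}, \ln opVst^{1/2}, \ln opVst} for
#' supporting / moderate / strong / very strong, mirrored with negated
#' thresholds on the benign side; values between the supporting cutoffs
#' are indeterminate. When confidence intervals are supplied, a category is
#' only assigned if the interval excludes the opposite side of zero
#' (conservative gating); disable by omitting the intervals.
#'
#' @param llr numeric LLRp values (natural log).
#' @param ciLo,ciHi optional confidence bounds for gating.
#' @param opVst odds of pathogenicity for very-strong evidence (> 1).
#' @return character vector of categories
#'   (\code{pathogenic_supporting} ... \code{pathogenic_very_strong},
#'   \code{benign_supporting} ... \code{benign_very_strong},
#'   \code{indeterminate}).
#' @examples
#' evidenceStrength(log(350^(1/4)))  # pathogenic_moderate
#' @export
evidenceStrength <- function(llr, ciLo = NULL, ciHi = NULL, opVst = 350) {
  if (opVst <= 1) stop("opVst must be > 1")
  steps <- log(opVst) / c(8, 4, 2, 1)
  lab <- c("supporting", "moderate", "strong", "very_strong")
  categorize <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= steps[1L]) {
      paste0("pathogenic_", lab[max(which(x >= steps))])
    } else if (x <= -steps[1L]) {
      paste0("benign_", lab[max(which(-x >= steps))])
    } else "indeterminate"
  }
  out <- vapply(llr, categorize, character(1))
  if (!is.null(ciLo) && !is.null(ciHi)) {
    gated <- !is.na(out) & ((grepl("^pathogenic", out) & ciLo <= 0) |
                            (grepl("^benign", out) & ciHi >= 0))
    out[gated] <- "indeterminate"
  }
  out
}

#' Full clinical calibration of a score map
#'
#' Benchmarks the scores against the reference sets (balanced PRC), fits
#' the density LLRp transform, bootstraps confidence intervals and assigns
#' evidence strengths.
#'
#' @param scores a \linkS4class{ScoreSet} or named numeric vector.
#' @param refsets reference sets (list of \code{positives} /
#'   \code{negatives}).
#' @param nBoot bootstrap resamples for the intervals.
#' @param seed RNG seed.
#' @param opVst very-strong odds of pathogenicity.
#' @param gateCI gate evidence on the interval excluding 0 on the opposite
#'   side.
#' @param lowerIsPathogenic score orientation.
#' @return a \linkS4class{CalibrationReport}.
#' @export
calibrateMap <- function(scores, refsets, nBoot = 1000L, seed = 1L,
                         opVst = 350, gateCI = TRUE,
                         lowerIsPathogenic = TRUE) {
  if (is(scores, "ScoreSet")) {
    tab <- scoreTable(scores)
    scores <- setNames(tab$score, tab$hgvs_p)
  }
  report <- balancedPrcCurve(scores, refsets,
                             lowerIsPathogenic = lowerIsPathogenic)
  ## the density ratio learns the orientation from the reference sets
  ci <- llrConfidenceIntervals(scores, refsets, nBoot = nBoot, seed = seed)
  ci$evidence <- if (gateCI)
    evidenceStrength(ci$llr, ci$ci_lo, ci$ci_hi, opVst = opVst)
  else evidenceStrength(ci$llr, opVst = opVst)
  report@llr <- ci
  report@params <- c(report@params,
                     list(opVst = opVst, nBoot = nBoot, gateCI = gateCI,
                          dropped_resamples = attr(ci, "dropped"),
                          bandwidths = attr(ci, "bandwidths")))
  report
}
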