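## TileSeq scoring: frequencies -> filters -> WT-corrected enrichment ->
## error regularisation -> replicate combination -> rescaled scores.

#' Per-sample variant allele frequencies
#'
#' @param x a \linkS4class{TileseqCounts}.
#' @return long data.frame with one row per (variant, condition, replicate):
#'   \code{hgvs_p}, \code{position}, \code{from_aa}, \code{to_aa},
#'   \code{vclass}, \code{tile}, \code{condition}, \code{replicate},
#'   \code{raw_count}, \code{depth}, \code{freq}, \code{cpm}.
#' @export
computeFrequencies <- function(x) {
  stopifnot(is(x, "TileseqCounts"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cnt <- SummarizedExperiment::assay(x, "counts")
  dep <- SummarizedExperiment::assay(x, "depth")
  if (any(dep <= 0)) stop("depth must be > 0 for every tile and sample")
  key <- paste(rep(rd$hgvs_p, times = nrow(cd)),
               rep(cd$condition, each = nrow(rd)),
               rep(cd$replicate, each = nrow(rd)))
  if (anyDuplicated(key))
    stop("duplicate (variant, condition, replicate) rows")
  out <- data.frame(
    hgvs_p = rep(rd$hgvs_p, times = nrow(cd)),
    position = rep(rd$position, times = nrow(cd)),
    from_aa = rep(rd$from_aa, times = nrow(cd)),
    to_aa = rep(rd$to_aa, times = nrow(cd)),
    vclass = rep(rd$vclass, times = nrow(cd)),
    tile = rep(rd$tile, times = nrow(cd)),
    condition = rep(cd$condition, each = nrow(rd)),
    replicate = rep(cd$replicate, each = nrow(rd)),
    raw_count = as.vector(cnt),
    depth = as.vector(dep),
    stringsAsFactors = FALSE)
  out$freq <- out$raw_count / out$depth
  out$cpm <- 1e6 * out$freq
  out
}

## Reshape the long frequency table into per-variant x replicate blocks for
## one condition.
condBlock <- function(freqs, cond, field) {
  sub <- freqs[freqs$condition == cond, ]
  reps <- sort(unique(sub$replicate))
  vars <- unique(freqs$hgvs_p)
  m <- matrix(NA_real_, nrow = length(vars), ncol = length(reps),
              dimnames = list(vars, reps))
  m[cbind(match(sub$hgvs_p, vars), match(sub$replicate, reps))] <- sub[[field]]
  m
}

#' Pre-selection quality filters
#'
#' Flags are assigned per replicate: \code{low_count} if the pre-selection
#' raw count is below 10 reads; \code{not_well_measured} if the
#' pre-selection frequency is below 10 counts per million (the threshold is
#' inclusive: exactly 10 cpm passes); \code{below_wt_p90} if the
#' pre-selection frequency does not exceed the 90th percentile of the
#' per-variant wild-type-control frequency distribution within the same
#' tile. A variant is excluded only if it is flagged in every replicate.
#'
#' @param freqs long frequency table from [computeFrequencies()] covering
#'   the \code{pre} and \code{wt_pre} conditions.
#' @param minCount,minCpm,wtPercentile filter parameters.
#' @return data.frame per (variant, replicate): logical columns
#'   \code{low_count}, \code{not_well_measured}, \code{below_wt_p90},
#'   \code{flagged}, plus per-variant \code{excluded} (flagged in all
#'   replicates).
#' @export
applyFilters <- function(freqs, minCount = 10, minCpm = 10,
                         wtPercentile = 0.9) {
  pre <- freqs[freqs$condition == "pre", ]
  wt <- freqs[freqs$condition == "wt_pre", ]
  if (nrow(wt) == 0L) stop("empty WT-control table (condition 'wt_pre')")
  ## 90th percentile of the WT-control frequency distribution per tile and
  ## replicate
  wt$grp <- paste(wt$tile, wt$replicate)
  p90 <- tapply(wt$freq, wt$grp, quantile, probs = wtPercentile,
                names = FALSE)
  out <- pre[, c("hgvs_p", "vclass", "tile", "replicate", "raw_count",
                 "freq", "cpm")]
  out$low_count <- out$raw_count < minCount
  out$not_well_measured <- out$cpm < minCpm
  out$below_wt_p90 <- as.vector(out$freq <=
                                  p90[paste(out$tile, out$replicate)])
  out$flagged <- out$low_count | out$not_well_measured | out$below_wt_p90
  all_flagged <- tapply(out$flagged, out$hgvs_p, all)
  out$excluded <- as.vector(all_flagged[out$hgvs_p])
  out
}

#' WT-corrected enrichment ratios
#'
#' Per replicate, corrected frequencies are obtained by subtracting the
#' wild-type-control frequency from the matching library frequency in both
#' conditions; the enrichment ratio is
#' \eqn{\phi = f'_{post} / f'_{pre}} and \code{log_phi} its log2. A
#' non-positive corrected pre-selection frequency makes the replicate
#' unscorable (\code{nonpositive_corrected_pre}); a non-positive corrected
#' post-selection frequency is floored at one pseudo-read (1/depth) so that
#' fully depleted variants remain scoreable.
#'
#' @param freqs long frequency table covering \code{pre}, \code{post},
#'   \code{wt_pre} and \code{wt_post}.
#' @param filters output of [applyFilters()]; flagged replicates are
#'   dropped (a variant survives if any replicate survives).
#' @return data.frame per (variant, replicate) with \code{phi},
#'   \code{log_phi}, \code{pre_cpm} (corrected, for the error model) and
#'   \code{flags}.
#' @export
correctAndEnrich <- function(freqs, filters = NULL) {
  for (cond in c("pre", "post", "wt_pre", "wt_post"))
    if (!any(freqs$condition == cond))
      stop("missing condition '", cond, "' in frequency table")
  vars <- unique(freqs$hgvs_p)
  pre <- condBlock(freqs, "pre", "freq")
  post <- condBlock(freqs, "post", "freq")
  wt_pre <- condBlock(freqs, "wt_pre", "freq")
  wt_post <- condBlock(freqs, "wt_post", "freq")
  dep_post <- condBlock(freqs, "post", "depth")
  if (anyNA(wt_pre) || anyNA(wt_post)) {
    bad <- vars[apply(is.na(wt_pre) | is.na(wt_post), 1L, any)]
    stop("missing matched WT-control row for variant(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  reps <- as.integer(colnames(pre))
  cpre <- pre - wt_pre
  cpost <- post - wt_post

  out <- expand.grid(hgvs_p = vars, replicate = reps,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  i <- match(out$hgvs_p, vars)
  j <- match(out$replicate, reps)
  idx <- cbind(i, j)
  out$cpre <- cpre[idx]
  out$cpost <- cpost[idx]
  out$pre_cpm <- out$cpre * 1e6
  out$flags <- ""

  if (!is.null(filters)) {
    fkey <- paste(filters$hgvs_p, filters$replicate)
    okey <- paste(out$hgvs_p, out$replicate)
    dropped <- filters$flagged[match(okey, fkey)]
    dropped[is.na(dropped)] <- FALSE
    out <- out[!dropped, ]
  }

  nonpos_pre <- out$cpre <= 0
  out$flags[nonpos_pre] <- "nonpositive_corrected_pre"
  floor_post <- !nonpos_pre & out$cpost <= 0
  out$cpost[floor_post] <- 1 / dep_post[
    cbind(match(out$hgvs_p[floor_post], vars),
          match(out$replicate[floor_post], reps))]
  out$phi <- ifelse(nonpos_pre, NA_real_, out$cpost / out$cpre)
  out$log_phi <- log2(out$phi)
  out$cpre <- out$cpost <- NULL
  rownames(out) <- NULL
  out
}

#' Regularised standard errors of replicate enrichment
#'
#' Empirical replicate-to-replicate standard deviations of \code{log_phi}
#' are noisy for any single variant; following the agreement-vs-frequency
#' trend across all variants, a linear model of log(empirical sd) on
#' log(corrected pre-selection cpm) is fitted over all unflagged variants
#' with replicate pairs, and each record's error is shrunk toward the model
#' prediction:
#' \deqn{se_{reg}^2 = (m \sigma_{model}^2 + (n-1) \sigma_{emp}^2) / (m+n-1)}
#' with pseudo-observation weight \code{m} (default 2), replicate count
#' \code{n}, and \code{df = m + n - 1}.
#'
#' @param enrich data.frame from [correctAndEnrich()].
#' @param m prior pseudo-observation weight; \code{m = 0} returns the
#'   empirical sd unshrunk.
#' @param minPairs minimum number of variants with replicate pairs needed to
#'   fit the trend.
#' @return \code{enrich} extended with \code{sd_emp}, \code{sd_model},
#'   \code{se_reg}, \code{df}, \code{n_rep}.
#' @export
regularizeErrors <- function(enrich, m = 2, minPairs = 30L) {
  ok <- is.finite(enrich$log_phi) & enrich$flags == ""
  scored <- enrich[ok, ]
  n_rep <- tapply(scored$log_phi, scored$hgvs_p, length)
  sd_emp <- tapply(scored$log_phi, scored$hgvs_p, sd)      # NA for n = 1
  mean_cpm <- tapply(scored$pre_cpm, scored$hgvs_p, mean)
  pairs <- names(n_rep)[n_rep >= 2L]
  if (length(pairs) < minPairs)
    stop("only ", length(pairs), " variants with replicate pairs (need >= ",
         minPairs, "); enlarge the simulation or supply more data")
  fit_ok <- pairs[sd_emp[pairs] > 0 & mean_cpm[pairs] > 0]
  fit <- lm(log(sd_emp[fit_ok]) ~ log(mean_cpm[fit_ok]))
  ab <- coef(fit)

  enrich$n_rep <- as.vector(n_rep[enrich$hgvs_p])
  enrich$n_rep[is.na(enrich$n_rep)] <- 0L
  enrich$sd_emp <- as.vector(sd_emp[enrich$hgvs_p])
  enrich$sd_model <- ifelse(enrich$pre_cpm > 0,
                            exp(ab[1L] + ab[2L] * log(enrich$pre_cpm)),
                            NA_real_)
  n <- enrich$n_rep
  if (m == 0) {
    enrich$se_reg <- enrich$sd_emp
    enrich$df <- pmax(n - 1L, 0L)
  } else {
    sd_emp2 <- ifelse(is.na(enrich$sd_emp), 0, enrich$sd_emp^2)
    enrich$se_reg <- sqrt((m * enrich$sd_model^2 + (n - 1L) * sd_emp2) /
                            (m + n - 1L))
    enrich$df <- m + n - 1L
  }
  enrich
}

#' Combine replicate enrichments
#'
#' Inverse-variance weighted average of the per-replicate log2 enrichment,
#' with combined standard error \eqn{\sqrt{1/\sum w}} and degrees of
#' freedom by Welch-Satterthwaite over the replicate variances. Variants
#' measured in a single replicate pass through with that replicate's
#' regularised error and df and the \code{single_replicate} flag.
#'
#' @param enrich data.frame from [regularizeErrors()].
#' @return data.frame per variant: \code{hgvs_p}, \code{log_phi},
#'   \code{se}, \code{df}, \code{n_rep}, \code{flags}.
#' @export
combineReplicates <- function(enrich) {
  ok <- is.finite(enrich$log_phi) & !is.na(enrich$se_reg) &
    enrich$se_reg > 0 & enrich$flags == ""
  scored <- enrich[ok, ]
  combine_one <- function(d) {
    if (nrow(d) == 1L) {
      return(data.frame(hgvs_p = d$hgvs_p, log_phi = d$log_phi, se = d$se_reg,
                        df = d$df, n_rep = 1L, flags = "single_replicate",
                        stringsAsFactors = FALSE))
    }
    w <- 1 / d$se_reg^2
    mu <- sum(w * d$log_phi) / sum(w)
    se <- sqrt(1 / sum(w))
    df <- sum(w)^2 / sum(w^2 / d$df)   # Welch-Satterthwaite
    data.frame(hgvs_p = d$hgvs_p[1L], log_phi = mu, se = se, df = df,
               n_rep = nrow(d), flags = "", stringsAsFactors = FALSE)
  }
  parts <- lapply(split(scored, scored$hgvs_p), combine_one)
  combined <- do.call(rbind, parts)
  rownames(combined) <- NULL

  ## variants with no surviving replicate: keep flags for reporting
  lost <- enrich[!enrich$hgvs_p %in% combined$hgvs_p, ]
  if (nrow(lost)) {
    lost_flags <- vapply(split(lost$flags, lost$hgvs_p), function(f) {
      f <- unique(f[f != ""])
      paste(f, collapse = ",")
    }, character(1))
    combined <- rbind(combined, data.frame(
      hgvs_p = names(lost_flags), log_phi = NA_real_, se = NA_real_,
      df = NA_real_, n_rep = 0L, flags = unname(lost_flags),
      stringsAsFactors = FALSE))
  }
  combined
}

#' Rescale combined enrichments to the nonsense/synonymous anchor scale
#'
#' Scores are linearly rescaled on the combined log2-enrichment scale so
#' that the median of nonsense variants is exactly 0 and the median of
#' synonymous variants exactly 1; standard errors scale by the same factor.
#'
#' @param combined data.frame from [combineReplicates()].
#' @param variants variant descriptor data.frame (for \code{vclass} and
#'   coordinates).
#' @param minAnchors minimum number of scored nonsense and synonymous
#'   variants required.
#' @return a \linkS4class{ScoreSet}.
#' @export
rescaleScores <- function(combined, variants, minAnchors = 10L) {
  tab <- merge(variants[, c("hgvs_p", "position", "from_aa", "to_aa",
                            "vclass")],
               combined, by = "hgvs_p", all.x = TRUE)
  tab$flags[is.na(tab$flags)] <- "not_measured"
  scored <- !is.na(tab$log_phi)
  non <- tab$log_phi[scored & tab$vclass == "nonsense"]
  syn <- tab$log_phi[scored & tab$vclass == "synonymous"]
  if (length(non) < minAnchors || length(syn) < minAnchors)
    stop("need >= ", minAnchors, " scored nonsense and synonymous variants (",
         length(non), " and ", length(syn), " available)")
  med_non <- median(non)
  med_syn <- median(syn)
  if (med_syn <= med_non)
    stop("synonymous median (", signif(med_syn, 4),
         ") <= nonsense median (", signif(med_non, 4),
         "): selection failed or inverted")
  span <- med_syn - med_non
  tab$score <- (tab$log_phi - med_non) / span
  tab$se <- tab$se / span
  tab <- tab[order(tab$position, tab$to_aa),
             c("hgvs_p", "position", "from_aa", "to_aa", "vclass",
               "score", "se", "df", "flags")]
  rownames(tab) <- NULL
  new("ScoreSet", table = tab,
      anchors = c(nonsense = med_non, synonymous = med_syn),
      params = list(minAnchors = minAnchors))
}

#' Score a TileSeq experiment end to end
#'
#' Convenience wrapper chaining [computeFrequencies()], [applyFilters()],
#' [correctAndEnrich()], [regularizeErrors()], [combineReplicates()] and
#' [rescaleScores()].
#'
#' @param x a \linkS4class{TileseqCounts}.
#' @param m regularisation pseudo-weight.
#' @param minCount,minCpm,wtPercentile filter parameters
#'   (see [applyFilters()]).
#' @param minAnchors see [rescaleScores()].
#' @return a \linkS4class{ScoreSet}.
#' @examples
#' cfg <- simulationConfig(L = 30, depth = 5e4, seed = 7)
#' truth <- simulateTruth(enumerateVariantSpace(randomOrf(30, 7)), cfg)
#' counts <- simulateCountTables(truth, cfg)
#' scoreTileseq(counts)
#' @export
scoreTileseq <- function(x, m = 2, minCount = 10, minCpm = 10,
                         wtPercentile = 0.9, minAnchors = 10L) {
  freqs <- computeFrequencies(x)
  filters <- applyFilters(freqs, minCount = minCount, minCpm = minCpm,
                          wtPercentile = wtPercentile)
  enrich <- correctAndEnrich(freqs, filters)
  enrich <- regularizeErrors(enrich, m = m)
  combined <- combineReplicates(enrich)
  variants <- unique(freqs[, c("hgvs_p", "position", "from_aa", "to_aa",
                               "vclass")])
  ss <- rescaleScores(combined, variants, minAnchors = minAnchors)
  ## variants dropped by the pre-selection filters: report their flags
  tab <- ss@table
  unmeasured <- tab$flags == "not_measured"
  if (any(unmeasured)) {
    fl <- filters[filters$flagged, ]
    per_var <- vapply(split(fl, fl$hgvs_p), function(d) {
      f <- c("low_count", "not_well_measured", "below_wt_p90")
      paste(f[vapply(f, function(x) any(d[[x]]), logical(1))],
            collapse = ",")
    }, character(1))
    hit <- match(tab$hgvs_p[unmeasured], names(per_var))
    tab$flags[unmeasured][!is.na(hit)] <- per_var[hit[!is.na(hit)]]
    ss@table <- tab
  }
  ss@params <- c(ss@params, list(m = m, minCount = minCount, minCpm = minCpm,
                                 wtPercentile = wtPercentile))
  ss
}

#' Export scores
#'
#' \code{writeScores} writes the full score table as TSV;
#' \code{writeMavedbScores} writes the three-column CSV
#' (\code{hgvs_pro}, \code{score}, \code{se}) used by public MAVE score
#' repositories.
#'
#' @param x a \linkS4class{ScoreSet}.
#' @param file output path.
#' @export
writeScores <- function(x, file) {
  stopifnot(is(x, "ScoreSet"))
  write.table(scoreTable(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeScores
#' @export
writeMavedbScores <- function(x, file) {
  stopifnot(is(x, "ScoreSet"))
  tab <- scoreTable(x)
  out <- data.frame(hgvs_pro = tab$hgvs_p, score = tab$score, se = tab$se)
  write.table(out, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}
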