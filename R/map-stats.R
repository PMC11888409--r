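## Map-level statistics: property-group contrasts, counter-selection,
## stability discordance and phenotype correlations.

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' U counts the pairs where the first group exceeds the second (ties count
#' one half). For combined sizes up to \code{exactMax}, the two-sided
#' p-value is computed exactly by enumerating all group assignments of the
#' observed values (handling ties correctly); larger samples use the
#' normal approximation with tie correction via [stats::wilcox.test()].
#'
#' @param x,y numeric vectors.
#' @param exactMax maximum combined size for exact enumeration.
#' @return list with \code{U}, \code{p}, \code{method}.
#' @export
mannWhitneyU <- function(x, y, exactMax = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- u_stat(x, y)
  m <- length(x); n <- length(y)
  if (m + n <= exactMax) {
    pool <- c(x, y)
    picks <- combn(m + n, m)
    us <- apply(picks, 2L, function(ix) u_stat(pool[ix], pool[-ix]))
    p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
    list(U = U, p = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value,
         method = "normal approximation")
  }
}

## Extract missense score vectors from a map for predicate-defined groups.
mapMissenseCells <- function(map) {
  sc <- scoreMatrix(map)
  wt <- wtSequence(map)
  cells <- which(!is.na(sc), arr.ind = TRUE)
  data.frame(position = cells[, 1L],
             to_aa = AA_COLUMNS[cells[, 2L]],
             from_aa = wt[cells[, 1L]],
             score = sc[cells],
             stringsAsFactors = FALSE)
}

conservativeSub <- function(from_aa, to_aa) {
  grp <- function(a) {
    hit <- vapply(AA_EXCHANGE_GROUPS, function(g) a %in% g, logical(1))
    names(AA_EXCHANGE_GROUPS)[hit][1L]
  }
  mapply(function(f, t) identical(grp(f), grp(t)), from_aa, to_aa)
}

#' Compare substitution-property groups on a map
#'
#' Runs two-sided Mann-Whitney contrasts over the built-in grouping
#' families — wild-type residue character (hydrophobic vs polar, hydrophobic
#' vs charged), proline introduction, negative-charge introduction,
#' conservative substitutions at uncharged positions — plus, when a
#' structural annotation is supplied, core/surface/interface/metal-binding
#' position classes. P-values are Benjamini-Hochberg adjusted across the
#' family actually run. Groups with fewer than 3 observations are skipped
#' with a notice.
#'
#' @param map an \linkS4class{EffectMap}.
#' @param annotation optional data.frame with columns \code{position} and
#'   \code{sclass} (\code{core}/\code{surface}/\code{intermediate}),
#'   optionally \code{interface} (logical) and \code{metal} (logical).
#' @param minN minimum group size.
#' @return data.frame: \code{contrast}, \code{n1}, \code{n2},
#'   \code{median1}, \code{median2}, \code{delta_median} (group1 - group2),
#'   \code{U}, \code{p}, \code{p_adj}.
#' @export
comparePropertyGroups <- function(map, annotation = NULL, minN = 3L) {
  cells <- mapMissenseCells(map)
  cells <- cells[cells$to_aa != AA_STOP, ]  # missense only

  groups <- list(
    "hydrophobic_wt vs polar_wt" = list(
      cells$score[cells$from_aa %in% AA_HYDROPHOBIC],
      cells$score[cells$from_aa %in% AA_POLAR]),
    "hydrophobic_wt vs charged_wt" = list(
      cells$score[cells$from_aa %in% AA_HYDROPHOBIC],
      cells$score[cells$from_aa %in% AA_CHARGED]),
    "proline_introduced vs other" = list(
      cells$score[cells$to_aa == "P"],
      cells$score[cells$to_aa != "P"]),
    "negative_introduced vs other" = list(
      cells$score[cells$to_aa %in% AA_NEGATIVE & !(cells$from_aa %in% AA_NEGATIVE)],
      cells$score[!(cells$to_aa %in% AA_NEGATIVE)]),
    "conservative_at_uncharged vs other_at_uncharged" = local({
      unch <- !(cells$from_aa %in% AA_CHARGED)
      cons <- conservativeSub(cells$from_aa, cells$to_aa)
      list(cells$score[unch & cons], cells$score[unch & !cons])
    })
  )
  if (!is.null(annotation)) {
    pos_class <- function(cls) {
      annotation$position[annotation$sclass == cls]
    }
    core <- cells$score[cells$position %in% pos_class("core")]
    surf_pos <- pos_class("surface")
    if (!is.null(annotation$interface))
      surf_pos <- setdiff(surf_pos,
                          annotation$position[annotation$interface])
    surf <- cells$score[cells$position %in% surf_pos]
    groups[["core vs surface"]] <- list(core, surf)
    if (!is.null(annotation$interface)) {
      iface <- cells$score[cells$position %in%
                             annotation$position[annotation$interface]]
      groups[["interface vs surface"]] <- list(iface, surf)
    }
    if (!is.null(annotation$metal)) {
      met <- cells$score[cells$position %in%
                           annotation$position[annotation$metal]]
      groups[["metal_binding vs surface"]] <- list(met, surf)
    }
  }

  rows <- lapply(names(groups), function(nm) {
    g1 <- groups[[nm]][[1L]]; g2 <- groups[[nm]][[2L]]
    if (length(g1) < minN || length(g2) < minN) {
      message("skipping contrast '", nm, "' (group with n < ", minN, ")")
      return(NULL)
    }
    mw <- mannWhitneyU(g1, g2)
    data.frame(contrast = nm, n1 = length(g1), n2 = length(g2),
               median1 = median(g1), median2 = median(g2),
               delta_median = median(g1) - median(g2),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Counter-selection of damaging variants in an observed cohort
#'
#' Cross-classifies scored map variants as damaging vs tolerated and
#' observed vs unobserved in a supplied variant list, then tests the 2x2
#' table by Fisher's exact test. The log-odds ratio is the natural log of
#' the sample odds ratio \eqn{(ad)/(bc)}.
#'
#' @param map an \linkS4class{EffectMap}.
#' @param observed character vector of observed variant labels
#'   (\code{hgvs_p}) or a data.frame with \code{position}/\code{to_aa}.
#' @return list with \code{table}, \code{log_or}, \code{p}.
#' @export
counterSelectionTest <- function(map, observed) {
  cells <- mapMissenseCells(map)
  cells$hgvs_p <- hgvsP(cells$position, cells$from_aa, cells$to_aa)
  if (is.data.frame(observed))
    observed <- hgvsP(observed$position,
                      cells$from_aa[match(observed$position, cells$position)],
                      observed$to_aa)
  damaging <- cells$score < map@threshold
  obs <- cells$hgvs_p %in% observed
  if (!any(obs))
    stop("observed variant list shares no variants with the map ",
         "(empty margin)")
  tab <- matrix(c(sum(damaging & obs), sum(damaging & !obs),
                  sum(!damaging & obs), sum(!damaging & !obs)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("damaging", "tolerated"),
                                c("observed", "unobserved")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("empty margin in the 2x2 table")
  ft <- fisher.test(tab)
  log_or <- log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  list(table = tab, log_or = log_or, p = ft$p.value)
}

#' Score vs predicted-stability discordance
#'
#' Compares per-position median map scores with per-position median
#' predicted stability changes, flags stable-but-inactive positions (median
#' score below the damaging threshold while the median ddG sits above the
#' destabilisation cutoff), reports the overall Spearman correlation and a
#' moving-window median track of both signals.
#'
#' @param map an \linkS4class{EffectMap}.
#' @param ddg data.frame with columns \code{position}, \code{to_aa},
#'   \code{ddg}.
#' @param window moving-window width in residues (step 1).
#' @param destabilizingBelow ddG cutoff below which a substitution counts
#'   as destabilising; positions with median ddG at or above it are "not
#'   destabilised". Both the -0.5 default and the alternative -0.1
#'   convention are in use; pick per your ddG sign convention.
#' @return list with \code{positions} (per-position data.frame including
#'   \code{stable_but_inactive}), \code{spearman}, \code{windows}.
#' @export
ddgDiscordance <- function(map, ddg, window = 10L,
                           destabilizingBelow = -0.5) {
  stopifnot(all(c("position", "to_aa", "ddg") %in% colnames(ddg)))
  cells <- mapMissenseCells(map)
  cells <- cells[cells$to_aa != AA_STOP, ]
  med_score <- tapply(cells$score, cells$position, median)
  med_ddg <- tapply(ddg$ddg, ddg$position, median)
  common <- intersect(names(med_score), names(med_ddg))
  if (!length(common)) stop("no position overlap between map and ddG table")
  pos <- as.integer(common)
  df <- data.frame(position = pos,
                   median_score = as.vector(med_score[common]),
                   median_ddg = as.vector(med_ddg[common]))
  df <- df[order(df$position), ]
  df$stable_but_inactive <- df$median_score < map@threshold &
    df$median_ddg >= destabilizingBelow
  sp <- safeSpearman(setNames(df$median_score, df$position),
                     setNames(df$median_ddg, df$position))
  win <- NULL
  if (nrow(df) >= window) {
    starts <- seq(min(df$position), max(df$position) - window + 1L)
    win <- do.call(rbind, lapply(starts, function(s) {
      in_win <- df$position >= s & df$position < s + window
      data.frame(start = s, end = s + window - 1L,
                 median_score = median(df$median_score[in_win]),
                 median_ddg = median(df$median_ddg[in_win]))
    }))
  }
  list(positions = df, spearman = sp, windows = win)
}

#' Correlate map summaries with variant-level phenotypes
#'
#' Multi-study phenotype values are collapsed per variant by a sample-size
#' weighted mean, then each phenotype is correlated (Spearman) with the
#' supplied map summary; p-values are BH-adjusted across the phenotype
#' family. All-missing phenotypes are skipped with a notice.
#'
#' @param summaries named numeric vector of map summaries (names are
#'   variant or position labels matching \code{phenotypes$variant}).
#' @param phenotypes data.frame with columns \code{variant},
#'   \code{phenotype}, \code{value}, \code{study_n}.
#' @return data.frame per phenotype: \code{phenotype}, \code{n},
#'   \code{rho}, \code{p}, \code{p_adj}.
#' @export
phenotypeCorrelations <- function(summaries, phenotypes) {
  stopifnot(all(c("variant", "phenotype", "value", "study_n") %in%
                colnames(phenotypes)))
  rows <- lapply(split(phenotypes, phenotypes$phenotype), function(d) {
    collapsed <- vapply(split(d, d$variant), function(v) {
      weighted.mean(v$value, v$study_n)
    }, numeric(1))
    x <- summaries[names(collapsed)]
    keep <- is.finite(x) & is.finite(collapsed)
    if (sum(keep) < 3L) {
      message("skipping phenotype '", d$phenotype[1L],
              "' (fewer than 3 paired values)")
      return(NULL)
    }
    sp <- safeSpearman(x[keep], collapsed[keep])
    data.frame(phenotype = d$phenotype[1L], n = sum(keep),
               rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Sample-size weighted collapse of multi-study values
#'
#' @param values numeric vector of study values.
#' @param study_n study sample sizes (weights).
#' @return weighted mean.
#' @examples
#' collapseStudies(c(61, 88), c(1, 1))  # 74.5
#' @export
collapseStudies <- function(values, study_n) {
  weighted.mean(values, study_n)
}
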