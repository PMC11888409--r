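## Synthetic-data generator: ground-truth effects, clone pools, selection,
## and multinomial sequencing counts with per-variant error frequencies.

#' Simulate ground-truth variant effects
#'
#' Missense effects are drawn from a two-mode Gaussian mixture: a damaged
#' mode centred at 0 and a tolerated mode centred at 1, each with sd
#' \code{modeSd}, with mixture weight \code{deleteriousFraction} on the
#' damaged mode. Synonymous variants are fixed at 1 and nonsense at 0.
#' Each variant also receives an i.i.d. gamma-distributed sequencing-error
#' frequency, shared by design between library and wild-type-control
#' samples so that WT subtraction is unbiased in expectation.
#'
#' @param variants data.frame from [enumerateVariantSpace()].
#' @param config a \linkS4class{SimulationConfig}.
#' @return the variant table extended with \code{true_effect}, \code{mode}
#'   (\code{damaged}/\code{tolerated}/\code{synonymous}/\code{nonsense}) and
#'   \code{error_freq}.
#' @export
simulateTruth <- function(variants, config) {
  validObject(config)
  set.seed(stageSeed(config@seed, "truth"))
  n <- nrow(variants)
  truth <- variants
  truth$true_effect <- NA_real_
  truth$mode <- NA_character_

  mis <- which(truth$vclass == "missense")
  damaged <- rbinom(length(mis), 1L, config@deleteriousFraction) == 1L
  centre <- ifelse(damaged, 0, 1)
  truth$true_effect[mis] <- rnorm(length(mis), centre, config@modeSd)
  truth$mode[mis] <- ifelse(damaged, "damaged", "tolerated")

  syn <- truth$vclass == "synonymous"
  truth$true_effect[syn] <- 1
  truth$mode[syn] <- "synonymous"
  non <- truth$vclass == "nonsense"
  truth$true_effect[non] <- 0
  truth$mode[non] <- "nonsense"

  truth$error_freq <- rgamma(n, shape = config@errorShape,
                             scale = config@errorScale)
  truth
}

## Selection weight: residual floor plus linear survival in the clamped
## true effect.
selectionWeight <- function(effect, floor) {
  floor + (1 - floor) * pmin(pmax(effect, 0), 1)
}

tileOf <- function(position, L, tiles) {
  as.integer(pmin(ceiling(position * tiles / L), tiles))
}

#' Simulate TileSeq count tables
#'
#' Generates a finite clone pool (substitutions per clone ~
#' Poisson(\code{cloneLambda}), variants assigned uniformly), applies
#' selection with per-replicate log-normal weight noise, renormalises over
#' the pool, adds the per-variant sequencing-error frequency to both library
#' conditions (and uses it alone for the wild-type control), and draws
#' multinomial read counts per tile, condition and replicate at the
#' configured depth. Only marginal variant frequencies are modelled; linkage
#' between co-occurring variants in a clone is not (tiles cannot observe
#' distal variants).
#'
#' @param truth data.frame from [simulateTruth()].
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{TileseqCounts}; per-tile wild-type reference
#'   counts are in \code{metadata(x)$wt_counts} and the realised clone
#'   carriage fractions in \code{metadata(x)$carriage}.
#' @export
simulateCountTables <- function(truth, config) {
  validObject(config)
  need <- c("hgvs_p", "position", "vclass", "true_effect", "error_freq")
  if (!all(need %in% colnames(truth)))
    stop("truth must cover all variants with columns: ",
         paste(need, collapse = ", "))
  set.seed(stageSeed(config@seed, "counts"))
  n <- nrow(truth)
  tile <- tileOf(truth$position, config@L, config@tiles)

  ## clone pool: expected occurrences per variant are uniform
  occ <- rpois(n, config@poolSize * config@cloneLambda / n)
  carriage <- occ / config@poolSize
  if (sum(carriage) >= 0.95)
    stop("clone pool over-saturated: variant carriage fails to normalize")

  conds <- c("pre", "post", "wt_pre", "wt_post")
  reps <- seq_len(config@replicates)
  samples <- expand.grid(replicate = reps, condition = conds,
                         stringsAsFactors = FALSE)[, c("condition", "replicate")]
  sample_id <- paste(samples$condition, samples$replicate, sep = ".")

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(truth$hgvs_p, sample_id))
  wt_counts <- matrix(0L, nrow = config@tiles, ncol = nrow(samples),
                      dimnames = list(paste0("tile", seq_len(config@tiles)),
                                      sample_id))

  ## expected marginal frequencies per condition/replicate
  freq_of <- function(cond, rep) {
    if (cond == "pre") return(carriage + truth$error_freq)
    if (cond == "post") {
      s <- selectionWeight(truth$true_effect, config@selectionFloor) *
        sel_noise[, rep]
      z <- sum(carriage * s) + (1 - sum(carriage))
      return(carriage * s / z + truth$error_freq)
    }
    truth$error_freq  # wt_pre / wt_post: sequencing error only
  }
  sel_noise <- matrix(
    rlnorm(n * config@replicates,
           meanlog = -config@replicateNoiseSd^2 / 2,
           sdlog = config@replicateNoiseSd),
    nrow = n)

  for (j in seq_len(nrow(samples))) {
    f <- freq_of(samples$condition[j], samples$replicate[j])
    for (t in seq_len(config@tiles)) {
      idx <- which(tile == t)
      ft <- f[idx]
      wt_f <- 1 - sum(ft)
      if (wt_f < 0)
        stop("tile ", t, ": variant frequencies fail to normalize")
      draw <- rmultinom(1L, size = as.integer(round(config@depth)),
                        prob = c(ft, wt_f))
      counts[idx, j] <- draw[seq_along(idx), 1L]
      wt_counts[t, j] <- draw[length(idx) + 1L, 1L]
    }
  }

  depth <- matrix(round(config@depth), nrow = n, ncol = nrow(samples),
                  dimnames = dimnames(counts))
  rd <- truth[, c("hgvs_p", "position", "from_aa", "to_aa", "vclass")]
  rd$tile <- tile
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, depth = depth),
    rowData = rd,
    colData = S4Vectors::DataFrame(condition = samples$condition,
                                   replicate = samples$replicate,
                                   row.names = sample_id),
    metadata = list(wt_counts = wt_counts, carriage = carriage,
                    seed = config@seed))
  new("TileseqCounts", se)
}

#' Simulate labelled reference variant sets
#'
#' Positives are sampled from damaged-mode missense variants and negatives
#' (proxy-benign) from tolerated-mode missense variants; a \code{labelNoise}
#' fraction of pairs is swapped between the sets. Default sizes follow the
#' realistic clinical-benchmarking regime of 85 pathogenic/likely-pathogenic
#' and 100 proxy-benign variants.
#'
#' @param truth data.frame from [simulateTruth()].
#' @param nPos,nNeg requested set sizes.
#' @param labelNoise fraction of labels swapped (pairs exchanged between
#'   sets, so sizes are preserved).
#' @param seed RNG seed (defaults to a substream of the truth seed if the
#'   truth carries one; otherwise 1).
#' @return list with \code{positives} and \code{negatives} (HGVS labels) and
#'   a \code{provenance} note.
#' @export
simulateReferenceSets <- function(truth, nPos = 85L, nNeg = 100L,
                                  labelNoise = 0, seed = 1L) {
  stopifnot(labelNoise >= 0, labelNoise <= 1)
  set.seed(stageSeed(seed, "refsets"))
  damaged <- truth$hgvs_p[truth$vclass == "missense" &
                          truth$mode == "damaged"]
  tolerated <- truth$hgvs_p[truth$vclass == "missense" &
                            truth$mode == "tolerated"]
  if (length(damaged) < nPos)
    stop("requested ", nPos, " positives but only ", length(damaged),
         " damaged-mode missense variants are available")
  if (length(tolerated) < nNeg)
    stop("requested ", nNeg, " negatives but only ", length(tolerated),
         " tolerated-mode missense variants are available")
  pos <- sample(damaged, nPos)
  neg <- sample(tolerated, nNeg)
  k <- round(labelNoise * min(nPos, nNeg))
  if (k > 0) {
    ip <- sample.int(nPos, k)
    in_ <- sample.int(nNeg, k)
    swapped <- pos[ip]
    pos[ip] <- neg[in_]
    neg[in_] <- swapped
  }
  list(positives = pos, negatives = neg,
       provenance = sprintf("synthetic (label_noise=%g)", labelNoise))
}

#' Write / read TileSeq count tables
#'
#' Long TSV with one row per (condition, replicate, variant):
#' columns \code{condition}, \code{replicate}, \code{tile}, \code{hgvs_p},
#' \code{position}, \code{from_aa}, \code{to_aa}, \code{vclass},
#' \code{count}, \code{depth}. The same schema is accepted for real data.
#'
#' @param x a \linkS4class{TileseqCounts}.
#' @param file path to the TSV.
#' @return \code{writeCountTables} returns \code{file} invisibly;
#'   \code{readCountTables} returns a \linkS4class{TileseqCounts}.
#' @export
writeCountTables <- function(x, file) {
  stopifnot(is(x, "TileseqCounts"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cnt <- SummarizedExperiment::assay(x, "counts")
  dep <- SummarizedExperiment::assay(x, "depth")
  long <- do.call(rbind, lapply(seq_len(nrow(cd)), function(j) {
    data.frame(condition = cd$condition[j], replicate = cd$replicate[j],
               tile = rd$tile, hgvs_p = rd$hgvs_p, position = rd$position,
               from_aa = rd$from_aa, to_aa = rd$to_aa, vclass = rd$vclass,
               count = cnt[, j], depth = dep[, j],
               stringsAsFactors = FALSE)
  }))
  write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCountTables
#' @export
readCountTables <- function(file) {
  long <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "tile", "hgvs_p", "position",
            "from_aa", "to_aa", "vclass", "count", "depth")
  if (!all(need %in% colnames(long)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  long$sample <- paste(long$condition, long$replicate, sep = ".")
  samples <- unique(long[, c("condition", "replicate", "sample")])
  variants <- unique(long[, c("hgvs_p", "position", "from_aa", "to_aa",
                              "vclass", "tile")])
  if (anyDuplicated(variants$hgvs_p))
    stop("inconsistent variant descriptors across samples")
  key <- paste(long$hgvs_p, long$sample)
  if (anyDuplicated(key))
    stop("duplicate (variant, condition, replicate) rows")
  counts <- matrix(0, nrow = nrow(variants), ncol = nrow(samples),
                   dimnames = list(variants$hgvs_p, samples$sample))
  depth <- counts
  i <- match(long$hgvs_p, variants$hgvs_p)
  j <- match(long$sample, samples$sample)
  counts[cbind(i, j)] <- long$count
  depth[cbind(i, j)] <- long$depth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, depth = depth),
    rowData = variants[, c("hgvs_p", "position", "from_aa", "to_aa",
                           "vclass", "tile")],
    colData = S4Vectors::DataFrame(condition = samples$condition,
                                   replicate = samples$replicate,
                                   row.names = samples$sample))
  new("TileseqCounts", se)
}

#' Write a truth table as TSV
#'
#' @param truth data.frame from [simulateTruth()].
#' @param file path.
#' @export
writeTruthTable <- function(truth, file) {
  write.table(truth, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
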