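#' @importFrom stats median sd quantile lm coef predict rnorm rbinom rgamma
#'   rpois rlnorm rmultinom density bw.SJ fisher.test wilcox.test cor cor.test
#'   p.adjust weighted.mean setNames complete.cases dnorm runif
#' @importFrom utils read.delim write.table write.csv head combn
#' @importFrom methods new validObject is slot show
NULL

## Residue alphabet used throughout: 20 amino acids + the stop symbol "*".
AA_STOP <- "*"
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_COLUMNS <- c(AA_ALPHABET, AA_STOP)

AA_THREE <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr", `*` = "Ter"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

## Physicochemical property sets (documented constants; see the vignette).
AA_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")
AA_POLAR <- c("G", "S", "T", "N", "Q", "Y", "P")
AA_CHARGED <- c("D", "E", "K", "R", "H")
AA_NEGATIVE <- c("D", "E")

## Exchange groups used to call a substitution "conservative".
AA_EXCHANGE_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic  = c("F", "W", "Y"),
  hydroxyl  = c("S", "T"),
  amide     = c("N", "Q"),
  acidic    = c("D", "E"),
  basic     = c("K", "R", "H"),
  special   = c("G", "P"),
  thiol     = c("C")
)

#' Protein-level HGVS label for a substitution
#'
#' Builds the customary \code{p.Xaa123Yaa} label, using \code{Ter} for the
#' stop symbol and \code{=} for synonymous changes.
#'
#' @param position 1-based residue position(s).
#' @param from_aa,to_aa one-letter residue codes (\code{"*"} for stop).
#' @return character vector of HGVS protein labels.
#' @examples
#' hgvsP(5, "A", "V")
#' hgvsP(5, "A", "A")
#' @export
hgvsP <- function(position, from_aa, to_aa) {
  n <- max(length(position), length(from_aa), length(to_aa))
  position <- rep_len(position, n)
  from_aa <- rep_len(from_aa, n)
  to_aa <- rep_len(to_aa, n)
  bad <- !(from_aa %in% names(AA_THREE)) | !(to_aa %in% names(AA_THREE))
  if (any(bad)) {
    stop("unknown residue code(s): ",
         paste(unique(c(from_aa[bad], to_aa[bad])), collapse = ", "))
  }
  suffix <- ifelse(from_aa == to_aa, "=", AA_THREE[to_aa])
  paste0("p.", AA_THREE[from_aa], position, suffix)
}

#' Classify a substitution
#'
#' @param from_aa,to_aa one-letter residue codes.
#' @return \code{"synonymous"}, \code{"nonsense"} or \code{"missense"}.
#' @export
variantClass <- function(from_aa, to_aa) {
  ifelse(from_aa == to_aa, "synonymous",
         ifelse(to_aa == AA_STOP, "nonsense", "missense"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sub-seeds: one root seed, fixed per-stage offsets, kept
## well below .Machine$integer.max.
stageSeed <- function(seed, stage) {
  offsets <- c(truth = 101L, counts = 211L, refsets = 307L, orf = 401L,
               boot = 503L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}
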