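## NNK saturation-mutagenesis variant space.

NNK_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("G", "T"), paste0))

translateCodon <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(codons[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Enumerate the amino-acid outcomes of NNK codon mutagenesis
#'
#' Saturation mutagenesis replaces each codon of the open reading frame with
#' an NNK degenerate codon (N = A/C/G/T, K = G/T). This enumerates, for each
#' requested residue position, every amino-acid-level outcome reachable by
#' any of the 32 NNK codons, de-duplicated by (position, target residue) and
#' classified as missense, synonymous or nonsense.
#'
#' @param codonSequence DNA string of the reference ORF including the
#'   terminal stop codon (length a multiple of 3).
#' @param positions residue positions to mutagenise; default all of
#'   \code{1..L} where \code{L} is the number of sense codons.
#' @return data.frame with columns \code{position}, \code{from_aa},
#'   \code{to_aa}, \code{vclass}, \code{hgvs_p}.
#' @examples
#' enumerateVariantSpace("ATGGCTTAA")
#' @export
enumerateVariantSpace <- function(codonSequence, positions = NULL) {
  codonSequence <- toupper(gsub("[[:space:]]", "", codonSequence))
  if (grepl("[^ACGT]", codonSequence))
    stop("codonSequence contains non-DNA characters")
  n <- nchar(codonSequence)
  if (n %% 3L != 0L || n < 6L)
    stop("codonSequence length must be a multiple of 3 and include a stop codon")
  codons <- substring(codonSequence, seq(1L, n - 2L, by = 3L),
                      seq(3L, n, by = 3L))
  aa <- translateCodon(codons)
  L <- length(codons) - 1L
  if (aa[L + 1L] != AA_STOP)
    stop("codonSequence must end in a stop codon (found ", codons[L + 1L], ")")
  internal_stop <- which(aa[seq_len(L)] == AA_STOP)
  if (length(internal_stop))
    stop("internal stop codon ", codons[internal_stop[1L]],
         " at position ", internal_stop[1L])
  if (is.null(positions)) positions <- seq_len(L)
  if (any(positions < 1L | positions > L))
    stop("positions must be in [1, ", L, "]")

  nnk_aa <- translateCodon(NNK_CODONS)
  out <- do.call(rbind, lapply(positions, function(p) {
    to <- sort(unique(nnk_aa))
    data.frame(position = p, from_aa = aa[p], to_aa = to,
               stringsAsFactors = FALSE)
  }))
  out$vclass <- variantClass(out$from_aa, out$to_aa)
  out$hgvs_p <- hgvsP(out$position, out$from_aa, out$to_aa)
  rownames(out) <- NULL
  out
}

#' Generate a random reference ORF
#'
#' Builds a synthetic open reading frame of \code{L} sense codons plus a stop
#' codon, sampling uniformly from the 61 sense codons (ATG start). This is a
#' synthetic stand-in reference sequence for simulation studies; any real ORF
#' of the same layout can be supplied instead.
#'
#' @param L number of residues.
#' @param seed RNG seed.
#' @return DNA string of length \code{3 * (L + 1)}.
#' @export
randomOrf <- function(L, seed = 1L) {
  stopifnot(L >= 1)
  set.seed(stageSeed(seed, "orf"))
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  body <- sample(sense, L - 1L, replace = TRUE)
  paste0(paste(c("ATG", body), collapse = ""), "TAA")
}
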