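#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings DNAStringSet reverseComplement readBStringSet
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table modifyList
NULL

# round half away from zero (reports print 0.235, not banker's 0.234)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of nucleotide strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' `N` is preserved as `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

is_valid_seq <- function(x) !grepl("[^ACGTN]", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
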