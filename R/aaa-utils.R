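#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet GENETIC_CODE
#' @importFrom tibble tibble as_tibble
#' @importFrom stats runif
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

# Three-letter amino-acid codes keyed by the one-letter code; "*" is Ter.
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#'
#' @param x A character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return A character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code; trailing bases that do not fill a codon are ignored.
#'
#' @param x Character scalar of nucleotides.
#' @return Character scalar of one-letter amino acids ("*" for stop).
#' @export
translate_cds <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(x, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

aa3 <- function(aa1) {
  out <- unname(AA_THREE[aa1])
  out[is.na(out)] <- "Xaa"
  out
}

is_dna_string <- function(x, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  is.character(x) && length(x) == 1L && nchar(x) > 0L &&
    !grepl(sprintf("[^%s]", alphabet), x)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is_dna_string(x, allow_n = allow_n)) {
    stop(sprintf("%s must be a non-empty string over {A,C,G,T%s}",
                 what, if (allow_n) ",N" else ""), call. = FALSE)
  }
  invisible(x)
}

# Deterministic child seed derived from a parent seed (kept below 2^31).
child_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

random_dna <- function(n, gc = 0.40) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}
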