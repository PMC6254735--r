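#' Codon usage of Escherichia coli K-12
#'
#' Genomic codon usage frequencies (occurrences per 1000 codons) for
#' *E. coli* K-12, the host in which saturation libraries are designed.
#' These frequencies drive the choice of "preferred" codons for mutagenesis
#' designs and of the fallback codon used for synonymous (wild-type
#' amino-acid) designs.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter amino-acid code,
#'   `*` for stop) and `per_1000`.
#' @export
#' @examples
#' head(ecoli_codon_usage())
ecoli_codon_usage <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  aa <- unname(Biostrings::GENETIC_CODE)
  per_1000 <- c(
    TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7,
    CTT = 11.0, CTC = 11.0, CTA = 3.9, CTG = 52.6,
    ATT = 30.3, ATC = 25.1, ATA = 4.4, ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
    TCT = 8.5, TCC = 8.6, TCA = 7.2, TCG = 8.9,
    CCT = 7.0, CCC = 5.5, CCA = 8.4, CCG = 23.2,
    ACT = 9.0, ACC = 23.4, ACA = 7.1, ACG = 14.4,
    GCT = 15.3, GCC = 25.5, GCA = 20.3, GCG = 33.6,
    TAT = 16.2, TAC = 12.2, TAA = 2.0, TAG = 0.2,
    CAT = 12.9, CAC = 9.7, CAA = 15.3, CAG = 28.8,
    AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
    GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
    TGT = 5.2, TGC = 6.4, TGA = 0.9, TGG = 15.2,
    CGT = 20.9, CGC = 22.0, CGA = 3.6, CGG = 5.4,
    AGT = 8.8, AGC = 16.1, AGA = 2.1, AGG = 1.2,
    GGT = 24.7, GGC = 29.6, GGA = 8.0, GGG = 11.1
  )
  tibble(codon = codons, aa = aa, per_1000 = unname(per_1000[codons]))
}

#' Preferred codon per amino acid
#'
#' Ranks the codons of each amino acid by usage frequency and returns the
#' codon at the requested rank. Rank 1 is the most frequent ("preferred")
#' codon used for all missense designs; rank 2 is the fallback used for the
#' synonymous design when the preferred codon is the wild-type codon itself.
#'
#' @param rank Codon rank within each amino acid (1 = most frequent).
#' @param usage Codon usage tibble, as from [ecoli_codon_usage()].
#' @return A named character vector mapping the 20 amino acids to codons.
#'   Amino acids with fewer than `rank` codons (Met and Trp at rank 2) are
#'   `NA`.
#' @export
#' @examples
#' preferred_codon_table()[["L"]]  # CTG
preferred_codon_table <- function(rank = 1, usage = ecoli_codon_usage()) {
  usage <- usage[usage$aa != "*", ]
  usage <- usage[order(usage$aa, -usage$per_1000, usage$codon), ]
  out <- vapply(split(usage$codon, usage$aa), function(cs) {
    if (length(cs) >= rank) cs[[rank]] else NA_character_
  }, character(1))
  out[AMINO_ACIDS]
}

## the 20 proteinogenic amino acids, one-letter codes, fixed order
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Translate an in-frame coding sequence
#'
#' @param cds Character scalar, nucleotide sequence with length a multiple
#'   of 3.
#' @return Character scalar of one-letter amino-acid codes (`*` = stop).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3L != 0L) stop("coding sequence length is not a multiple of 3")
  codons <- substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
  paste(unname(Biostrings::GENETIC_CODE[toupper(codons)]), collapse = "")
}

## reverse complement of character vectors, via Biostrings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## replace a substring in place (1-based, inclusive)
str_sub_replace <- function(x, start, end, value) {
  paste0(substr(x, 1L, start - 1L), value, substr(x, end + 1L, nchar(x)))
}

codon_at <- function(seq, codon_index) {
  substring(seq, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
}

aa_of_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}
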