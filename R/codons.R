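#' @keywords internal
"_PACKAGE"

## Codon-level constants shared across the package. The 61 sense codons are
## kept in fixed lexicographic order so that score vectors and dwell-time
## grids from different runs align without re-matching.

.codon_alphabet <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Stop codons of the standard genetic code
#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons in lexicographic order
#'
#' @format Character vector of length 61.
#' @export
SENSE_CODONS <- setdiff(.codon_alphabet(), STOP_CODONS)

#' Human codon usage (frequency per thousand codons)
#'
#' Aggregate human codon usage frequencies (GenBank/Kazusa-style per-thousand
#' values) over the 61 sense codons. Used to order simulated dwell-time grids
#' by codon rarity and as the default composition of synthetic transcripts.
#'
#' @format Named numeric vector of length 61 (names are sense codons).
#' @export
human_codon_usage <- c(
  TTT = 17.6, TTC = 20.3, TTA = 7.7,  TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA = 7.2,  CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA = 7.5,  ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA = 7.1,  GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
  TAT = 12.2, TAC = 15.3, CAT = 10.9, CAC = 15.1,
  CAA = 12.3, CAG = 34.2, AAT = 17.0, AAC = 19.1,
  AAA = 24.4, AAG = 31.9, GAT = 21.8, GAC = 25.1,
  GAA = 29.0, GAG = 39.6, TGT = 10.6, TGC = 12.6,
  TGG = 13.2, CGT = 4.5,  CGC = 10.4, CGA = 6.2,
  CGG = 11.4, AGT = 12.1, AGC = 19.5, AGA = 12.2,
  AGG = 12.0, GGT = 10.8, GGC = 22.2, GGA = 16.5,
  GGG = 16.5)[SENSE_CODONS]

## one-letter amino acid per codon (standard code), "*" for stops
.codon_to_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  aa <- as.character(gc)
  names(aa) <- names(gc)
  aa
})

#' Translate a vector of codons to one-letter amino acids
#'
#' Stop codons translate to `"*"`; codons containing characters other than
#' A/C/G/T (e.g. N) translate to `NA`.
#'
#' @param codons Character vector of 3-letter codons (DNA alphabet).
#' @return Character vector of one-letter amino acid codes.
#' @export
translate_codons <- function(codons) {
  unname(.codon_to_aa[codons])
}

## Physicochemical residue classes
.AA_POSITIVE <- c("H", "K", "R")
.AA_NEGATIVE <- c("D", "E")
.AA_HYDROPHOBIC <- c("A", "V", "I", "L", "M", "F", "Y", "W")

#' Reference minimum-free-energy percentile thresholds for the human
#' transcriptome
#'
#' Published thresholds (kcal/mol) of 80-nt sliding-window minimum free
#' energy for the most stable human mRNA secondary structures: the top 1st,
#' 5th and 10th percentiles. Shipped as documented constants for use with
#' [structure_window_profile()] when dataset-level percentiles are not
#' recomputed.
#'
#' @format Named numeric vector (`p1`, `p5`, `p10`), kcal/mol.
#' @export
human_mfe_thresholds <- c(p1 = -40.1, p5 = -32.8, p10 = -29.0)
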