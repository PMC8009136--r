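# Genetic-code tables shared by the codon-model, context and amino-acid
# modules. Plastid protein-coding genes use the standard code.

NT_STATES <- c("A", "C", "G", "T")

# IUPAC ambiguity -> compatible base sets; gap and N are missing data
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T")
)

GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
AA_LEVELS <- sort(unique(GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]))

#' Translate a codon under the standard (plastid) code
#' @param codon character vector of 3-letter codons (T, not U).
#' @return amino-acid one-letter codes; `NA` for codons containing gaps or
#'   ambiguity codes, `"*"` for stops.
#' @export
translate_codon <- function(codon) {
  unname(GENETIC_CODE_STD[toupper(codon)])
}

#' Average AT content of the codons encoding each amino acid
#'
#' For each amino acid, the mean over its (sense) codons of the number of
#' A/T bases divided by 3.
#' @return named numeric vector over the 20 amino acids.
#' @export
codon_at_content <- function() {
  at <- vapply(SENSE_CODONS, function(cd) {
    sum(strsplit(cd, "")[[1L]] %in% c("A", "T")) / 3
  }, 0)
  tapply(at, GENETIC_CODE_STD[SENSE_CODONS], mean)[AA_LEVELS]
}

#' Reverse complement of a nucleotide string
#' @param x character vector of nucleotide strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}
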