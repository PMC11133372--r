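## Standard genetic code. Kept in-package (rather than delegated) because the
## read pipeline's translation step is part of the method itself: reads are
## translated and assigned to clones by exact amino-acid-window identity.
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

## One representative (human-preferred) codon per amino acid, used when
## reverse-translating synthetic amino-acid windows into DNA inserts.
.aa_to_codon <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "CGG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC"
)

#' Translate DNA with the standard genetic code
#'
#' Translates each element of a character vector of DNA sequences starting at
#' `frame` (1-based). Incomplete trailing codons are dropped; codons containing
#' characters other than A, C, G, T translate to `"X"`; stop codons to `"*"`.
#'
#' @param x Character vector of DNA sequences.
#' @param frame 1-based position of the first translated base.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_dna("ATGGCT")  # "MA"
#' @export
translate_dna <- function(x, frame = 1L) {
  stopifnot(is.character(x), frame >= 1L)
  x <- toupper(x)
  vapply(x, function(s) {
    s <- substr(s, frame, nchar(s))
    nc <- nchar(s) %/% 3L
    if (nc == 0L) return("")
    starts <- seq(1L, by = 3L, length.out = nc)
    aa <- .codon_table[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Fast path: translate many equal-length in-frame segments (n_codons each).
translate_fixed <- function(segs, n_codons) {
  if (length(segs) == 0L) return(character(0L))
  starts <- seq(1L, by = 3L, length.out = n_codons)
  cols <- lapply(starts, function(s) {
    aa <- .codon_table[substr(segs, s, s + 2L)]
    aa[is.na(aa)] <- "X"
    aa
  })
  do.call(paste0, cols)
}

reverse_translate <- function(aa) {
  vapply(strsplit(aa, "", fixed = TRUE), function(res) {
    cod <- .aa_to_codon[res]
    if (anyNA(cod)) stop("cannot reverse-translate residue(s): ",
                         paste(res[is.na(cod)], collapse = ", "), call. = FALSE)
    paste0(cod, collapse = "")
  }, character(1L))
}
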