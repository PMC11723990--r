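## IUPAC nucleotide utilities shared by the sequence and CAPS machinery.

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Validate a DNA string against the IUPAC alphabet
#'
#' @param seq character scalar, DNA sequence (case-insensitive).
#' @param allow_gap allow the alignment gap character `-`.
#' @return the uppercased sequence, invisibly unchanged otherwise.
#' @keywords internal
check_dna <- function(seq, allow_gap = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  alphabet <- names(IUPAC_MAP)
  if (allow_gap) alphabet <- c(alphabet, "-")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L) {
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  }
  seq
}

#' Expand an IUPAC pattern into a regular expression
#'
#' Each ambiguity code becomes a character class, e.g. `GANTC` ->
#' `GA[ACGT]TC`. Used to locate restriction sites on concrete sequences.
#'
#' @param pattern IUPAC string.
#' @return a regex character scalar.
#' @keywords internal
iupac_regex <- function(pattern) {
  pattern <- check_dna(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_MAP[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

#' Reverse-complement an IUPAC string
#'
#' @param seq DNA string, possibly with ambiguity codes.
#' @return the reverse complement.
#' @keywords internal
revcomp <- function(seq) {
  seq <- check_dna(seq)
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}
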