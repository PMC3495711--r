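## Nucleotide primitives shared by every other module. Sequences are plain
## uppercase character strings over {A,C,G,T}; Biostrings does the heavy
## lifting where it applies. Ambiguity codes are rejected everywhere:
## allele-specific design needs exact base identity at and near the 3' end.

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## stop() with a condition class so callers can branch on failure kinds
.err <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "ASPrimerError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.checkSeq <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    .err("invalidAlphabet", paste(what, "must be a single character string"))
  if (!allowEmpty && nchar(x) == 0L)
    .err("emptySequence", paste(what, "must be non-empty"))
  if (grepl("[^ACGT]", x))
    .err("invalidAlphabet",
         paste0(what, " contains characters outside {A,C,G,T}: ", x))
  invisible(x)
}

.checkBase <- function(b, what = "base") {
  if (!is.character(b) || length(b) != 1L || is.na(b) || !b %in% .BASES)
    .err("invalidAlphabet", paste(what, "must be one of A, C, G, T"))
  invisible(b)
}

#' Watson-Crick complement of a single base
#'
#' @param base one of "A", "C", "G", "T" (ambiguity codes are rejected)
#' @return the complementary base
#' @examples
#' complementBase("A")  # "T"
#' @export
complementBase <- function(base) {
  .checkBase(base)
  unname(.COMPLEMENT[base])
}

#' Reverse complement of a DNA sequence
#'
#' Strict wrapper around \code{Biostrings::reverseComplement} that accepts
#' and returns plain character strings and rejects ambiguity codes.
#'
#' @param seq a non-empty A/C/G/T string, 5'->3'
#' @return the reverse complement, 5'->3'
#' @examples
#' revComp("AAGATT")  # "AATCTT"
#' @export
revComp <- function(seq) {
  .checkSeq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC content of a sequence
#'
#' @param seq a non-empty A/C/G/T string
#' @return fraction of G+C in [0, 1]
#' @export
gcContent <- function(seq) {
  .checkSeq(seq)
  s <- Biostrings::DNAString(seq)
  unname(Biostrings::letterFrequency(s, "GC", as.prob = TRUE)[1L])
}

## SantaLucia unified nearest-neighbor parameters (kcal/mol; cal/mol/K),
## keyed by the top-strand dimer. Both orientations of each duplex step are
## listed so a single pass over the sequence suffices.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature of a perfectly matched duplex
#'
#' Two-state nearest-neighbor model with the SantaLucia unified parameter
#' set, terminal A/T and G/C initiation terms, and the entropic salt
#' correction 0.368 (N-1) ln[Na+]. For a non-self-complementary primer in a
#' two-strand reaction at total strand concentration CT the effective
#' concentration term is CT/4; for a self-complementary primer the symmetry
#' entropy is added and CT is used directly.
#'
#' @param seq primer sequence, 5'->3', at least 8 bases
#' @param naMillimolar monovalent cation concentration in mM (default 50)
#' @param primerConcMicromolar total primer strand concentration in uM
#'   (default 0.5)
#' @return melting temperature in degrees Celsius
#' @examples
#' meltingTemperature("AGTTACATAGGTCCACAATC")
#' @export
meltingTemperature <- function(seq, naMillimolar = 50,
                               primerConcMicromolar = 0.5) {
  .checkSeq(seq, "primer")
  n <- nchar(seq)
  if (n < 8L)
    .err("sequenceTooShort",
         "melting temperature needs at least 8 bases for the two-state model")
  if (!is.finite(naMillimolar) || naMillimolar <= 0)
    .err("invalidThermoParams", "naMillimolar must be positive")
  if (!is.finite(primerConcMicromolar) || primerConcMicromolar <= 0)
    .err("invalidThermoParams", "primerConcMicromolar must be positive")

  steps <- substring(seq, 1:(n - 1L), 2:n)
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  ends <- substring(seq, c(1L, n), c(1L, n))
  dH <- dH + sum(ifelse(ends %in% c("A", "T"), 2.3, 0.1))
  dS <- dS + sum(ifelse(ends %in% c("A", "T"), 4.1, -2.8))

  ct <- primerConcMicromolar * 1e-6
  if (identical(seq, revComp(seq))) {
    dS <- dS - 1.4
    k <- ct
  } else {
    k <- ct / 4
  }
  dS <- dS + 0.368 * (n - 1L) * log(naMillimolar / 1000)
  1000 * dH / (dS + 1.987 * log(k)) - 273.15
}

#' Positions at which two equal-length sequences differ, counted from the 3' end
#'
#' Position 1 is the 3'-terminal base, matching the convention "the 2nd/3rd/
#' 4th base closest to the 3' end" used throughout primer annotation.
#'
#' @param a,b equal-length A/C/G/T strings (5'->3')
#' @return sorted integer vector of differing positions from the 3' end
#' @examples
#' differencePositions("AACGT", "ATCGA")  # c(1, 4)
#' @export
differencePositions <- function(a, b) {
  .checkSeq(a, "first sequence")
  .checkSeq(b, "second sequence")
  n <- nchar(a)
  if (n != nchar(b))
    .err("lengthMismatch", "sequences must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  sort(n - which(av != bv) + 1L)
}
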