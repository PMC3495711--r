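## SNP typing: the 12 ordered types, the terminal-mismatch mapping with
## destabilization strengths, and compression into the 4 analysis groups.

## compressed group for each ordered type
.COMPRESS <- c("A/G" = "TRANSITION", "G/A" = "TRANSITION",
               "C/T" = "TRANSITION", "T/C" = "TRANSITION",
               "A/C" = "AC_GT", "C/A" = "AC_GT",
               "G/T" = "AC_GT", "T/G" = "AC_GT",
               "A/T" = "AT_TA", "T/A" = "AT_TA",
               "C/G" = "CG_GC", "G/C" = "CG_GC")

.checkSnpType <- function(x) {
  if (!is.character(x) || length(x) != 1L || !x %in% SNP_TYPES)
    .err("invalidSNPType",
         paste0("invalid SNP type '", as.character(x)[1L],
                "'; expected one of ", paste(SNP_TYPES, collapse = ", ")))
  invisible(x)
}

#' Classify a biallelic site into its ordered SNP type
#'
#' The type is written line-1 allele / line-2 allele; order matters because
#' the forward primer is allele-specific for one line and the 3'-terminal
#' mismatch it forms on the other line depends on which allele is which.
#'
#' @param alleleLine1,alleleLine2 single distinct bases
#' @return the SNP type string, e.g. "A/G"
#' @examples
#' classifySnp("T", "A")  # "T/A"
#' @export
classifySnp <- function(alleleLine1, alleleLine2) {
  .checkBase(alleleLine1, "line-1 allele")
  .checkBase(alleleLine2, "line-2 allele")
  if (alleleLine1 == alleleLine2)
    .err("notASNP", "alleles are identical; site is monomorphic")
  paste0(alleleLine1, "/", alleleLine2)
}

#' Canonical mismatch class of a template/primer base pairing
#'
#' The class is the unordered pair of the two bases facing each other at a
#' mismatched position; Watson-Crick pairings are rejected. The returned
#' label uses the published spelling (CA, GA, TC, TG for hetero-pairs).
#'
#' @param templateBase,primerBase single bases
#' @return one of \code{\link{MISMATCH_CLASSES}}
#' @examples
#' mismatchClassFor("C", "A")  # "CA"
#' @export
mismatchClassFor <- function(templateBase, primerBase) {
  .checkBase(templateBase, "template base")
  .checkBase(primerBase, "primer base")
  if (complementBase(templateBase) == primerBase)
    .err("notAMismatch",
         paste0(templateBase, ":", primerBase,
                " is a Watson-Crick match, not a mismatch"))
  key <- paste(sort(c(templateBase, primerBase)), collapse = "")
  unname(.CLASS_BY_SORTED[key])
}

#' Normalize a mismatch-class spelling onto the canonical label
#'
#' Published tables spell the same unordered class in both letter orders
#' (e.g. CT in running text vs TC in the class table, AC vs CA). Any valid
#' spelling is mapped to the canonical display label; AT/TA and CG/GC are
#' rejected as Watson-Crick pairs.
#'
#' @param x a two-letter class string
#' @return one of \code{\link{MISMATCH_CLASSES}}
#' @examples
#' canonicalMismatchClass("CT")  # "TC"
#' @export
canonicalMismatchClass <- function(x) {
  if (!is.character(x) || length(x) != 1L || nchar(x) != 2L)
    .err("invalidMismatchClass", "mismatch class must be a two-letter string")
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  .checkBase(b[1L], "mismatch class base")
  .checkBase(b[2L], "mismatch class base")
  key <- paste(sort(b), collapse = "")
  if (!key %in% names(.CLASS_BY_SORTED))
    .err("invalidMismatchClass",
         paste0("'", x, "' is a Watson-Crick pair, not a mismatch class"))
  unname(.CLASS_BY_SORTED[key])
}

## Terminal-mismatch table (class + destabilization strength per SNP type),
## shipped as packaged data and cached at first use.
.snpModelCache <- new.env(parent = emptyenv())

.terminalTable <- function() {
  if (is.null(.snpModelCache$table2)) {
    path <- system.file("extdata", "table2_terminal_mismatch.tsv",
                        package = "ASPrimer", mustWork = TRUE)
    .snpModelCache$table2 <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .snpModelCache$table2
}

#' Terminal mismatch formed on the non-target allele, with strength label
#'
#' When the primer's 3'-terminal base equals the line-2 (target) allele, the
#' primer forms a mismatch with the line-1 template at its very terminus.
#' The class equals the unordered pair \{complement(line-1 allele), line-2
#' allele\}; the qualitative destabilization strength label (after the
#' mismatch thermodynamics literature) is carried verbatim from the packaged
#' table and is informational only -- site and substitution selection are
#' driven purely by the empirical rate tables.
#'
#' @param snpType one of the 12 ordered SNP types
#' @return list with elements \code{class} (canonical label) and
#'   \code{strength} ("Strong", "Weak" or "Strong_and_Medium")
#' @examples
#' terminalMismatch("A/G")  # class "TG", strength "Strong"
#' @export
terminalMismatch <- function(snpType) {
  .checkSnpType(snpType)
  tab <- .terminalTable()
  row <- tab[tab$snp_type == snpType, ]
  list(class = canonicalMismatchClass(row$terminal_class),
       strength = row$strength)
}

#' Compress an ordered SNP type into its 4-way analysis group
#'
#' @param snpType one of the 12 ordered SNP types
#' @return one of \code{\link{COMPRESSED_GROUPS}}
#' @examples
#' compressType("G/A")  # "TRANSITION"
#' @export
compressType <- function(snpType) {
  .checkSnpType(snpType)
  unname(.COMPRESS[snpType])
}

#' Is a SNP type a transition?
#' @param snpType one of the 12 ordered SNP types
#' @return TRUE for A/G, G/A, C/T, T/C
#' @export
isTransition <- function(snpType) {
  compressType(snpType) == "TRANSITION"
}
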