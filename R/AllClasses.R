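#' @import methods
NULL

#' The four compressed SNP groups used for mismatch-site selection
#'
#' The 12 ordered SNP types collapse into four analysis groups according to
#' the destabilization behaviour of the 3'-terminal mismatch they produce:
#' transitions (A/G, G/A, C/T, T/C), the A/C-G/T transversions (A/C, C/A,
#' G/T, T/G), the A/T-T/A pair and the C/G-G/C pair.
#'
#' @export
COMPRESSED_GROUPS <- c("TRANSITION", "AC_GT", "AT_TA", "CG_GC")

#' The 12 admissible ordered SNP types (line-1 allele / line-2 allele)
#' @export
SNP_TYPES <- c("A/G", "C/T", "G/A", "T/C",
               "A/C", "G/T", "C/A", "T/G",
               "A/T", "T/A", "G/C", "C/G")

#' The 8 canonical non-complementary mismatch classes (display spelling)
#'
#' Labels follow the published two-letter spelling (CA, GA, TC, TG for the
#' hetero-pairs); \code{\link{canonicalMismatchClass}} normalizes either
#' letter order onto these labels. The Watson-Crick pairs AT and CG are not
#' mismatches and are never admissible.
#' @export
MISMATCH_CLASSES <- c("TC", "GA", "CA", "AA", "TG", "GG", "CC", "TT")

## unordered sorted pair -> display label
.CLASS_BY_SORTED <- c(AA = "AA", AC = "CA", AG = "GA", CC = "CC",
                      CT = "TC", GG = "GG", GT = "TG", TT = "TT")

#' RuleTable: empirical polymorphism-rate tables driving primer design
#'
#' Holds success/total counts of validated allele-specific primers indexed
#' two ways: by (mismatch site, compressed SNP group) -- used to pick the
#' mismatch site -- and by (mismatch site, mismatch class) -- used to pick
#' the substituted base. Sites are 2, 3, 4 counted from the 3' end
#' (terminal = 1). Marginal counts are carried separately so that tables
#' loaded from published counts can preserve the printed margins even when
#' those margins are not the exact cell sums.
#'
#' @slot sgNum,sgDen 3 x 4 integer matrices (sites x compressed groups).
#' @slot scNum,scDen 3 x 8 integer matrices (sites x mismatch classes).
#' @slot siteMarginNum,siteMarginDen named length-3 numerics.
#' @slot groupMarginNum,groupMarginDen named length-4 numerics.
#' @slot grandNum,grandDen overall polymorphic / tested counts.
#'
#' @seealso \code{\link{defaultRuleTables}}, \code{\link{deriveRuleTables}},
#'   \code{\link{readRuleTables}}
#' @export
setClass("RuleTable",
  representation(
    sgNum = "matrix", sgDen = "matrix",
    scNum = "matrix", scDen = "matrix",
    siteMarginNum = "numeric", siteMarginDen = "numeric",
    groupMarginNum = "numeric", groupMarginDen = "numeric",
    grandNum = "numeric", grandDen = "numeric"
  )
)

setValidity("RuleTable", function(object) {
  msg <- character()
  chk <- function(num, den, what) {
    if (!identical(dim(num), dim(den)))
      return(paste(what, "numerator/denominator dimensions differ"))
    if (any(den < 0) || any(num < 0)) return(paste(what, "counts negative"))
    if (any(num > den)) return(paste(what, "numerator exceeds denominator"))
    NULL
  }
  for (m in list(chk(object@sgNum, object@sgDen, "site-by-group"),
                 chk(object@scNum, object@scDen, "site-by-class")))
    if (!is.null(m)) msg <- c(msg, m)
  if (!identical(rownames(object@sgNum), c("2", "3", "4")))
    msg <- c(msg, "site rows must be 2, 3, 4")
  if (!identical(colnames(object@sgNum), COMPRESSED_GROUPS))
    msg <- c(msg, "group columns must be the 4 compressed groups")
  if (!identical(colnames(object@scNum), MISMATCH_CLASSES))
    msg <- c(msg, "class columns must be the 8 mismatch classes")
  if (object@grandNum > object@grandDen)
    msg <- c(msg, "grand numerator exceeds denominator")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RuleTable", function(object) {
  cat("RuleTable:", object@grandNum, "/", object@grandDen,
      "polymorphic primer pairs overall (",
      pctFmt(object@grandNum, object@grandDen), "%)\n", sep = " ")
  cat("  site x group percentages:\n")
  print(siteGroupPercent(object))
  cat("  site x class percentages:\n")
  print(siteClassPercent(object))
})

#' RuleDecision: the deterministic design choice for one SNP
#'
#' Records the compressed group, the selected mismatch site, the original
#' and substituted primer bases, the resulting mismatch class, and the two
#' empirical percentages the selection was based on.
#'
#' @export
setClass("RuleDecision",
  representation(
    snpType = "character", compressedType = "character",
    chosenSite = "integer", originalBase = "character",
    substitutedBase = "character", mismatchClass = "character",
    sitePercent = "numeric", classPercent = "numeric"
  )
)

setValidity("RuleDecision", function(object) {
  if (!object@snpType %in% SNP_TYPES) return("invalid SNP type")
  if (!object@chosenSite %in% 2:4) return("chosen site must be 2, 3 or 4")
  if (object@substitutedBase == object@originalBase)
    return("substitution must change the base")
  if (!object@mismatchClass %in% MISMATCH_CLASSES)
    return("invalid mismatch class")
  TRUE
})

setMethod("show", "RuleDecision", function(object) {
  cat(sprintf(
    "RuleDecision: SNP %s [%s] -> site %d (%.1f%%), %s>%s giving %s (%.1f%%)\n",
    object@snpType, object@compressedType, object@chosenSite,
    object@sitePercent, object@originalBase, object@substitutedBase,
    object@mismatchClass, object@classPercent))
})

#' DesignConfig: primer and amplicon constraints
#'
#' @slot primerLenMin,primerLenMax allowed primer lengths (bases).
#' @slot tmMin,tmMax allowed melting temperature window (deg C).
#' @slot tmDiffMax maximum |forward Tm - reverse Tm| (deg C).
#' @slot ampMin,ampMax allowed amplicon lengths (bases).
#' @slot targetAllele "line2" (default) or "line1": which allele the
#'   forward primer's 3'-terminal base matches.
#' @slot strand "plus" or "minus" design strand.
#' @slot uniquenessK k-mer length for the 3'-end uniqueness screen.
#' @slot naMillimolar,primerConcMicromolar thermodynamic settings passed to
#'   \code{\link{meltingTemperature}}.
#'
#' @seealso \code{\link{designConfig}}
#' @export
setClass("DesignConfig",
  representation(
    primerLenMin = "integer", primerLenMax = "integer",
    tmMin = "numeric", tmMax = "numeric", tmDiffMax = "numeric",
    ampMin = "integer", ampMax = "integer",
    targetAllele = "character", strand = "character",
    uniquenessK = "integer",
    naMillimolar = "numeric", primerConcMicromolar = "numeric"
  )
)

setValidity("DesignConfig", function(object) {
  msg <- character()
  if (object@primerLenMin > object@primerLenMax)
    msg <- c(msg, "primerLenMin > primerLenMax")
  if (object@tmMin > object@tmMax) msg <- c(msg, "tmMin > tmMax")
  if (object@ampMin > object@ampMax) msg <- c(msg, "ampMin > ampMax")
  if (!object@targetAllele %in% c("line1", "line2"))
    msg <- c(msg, "targetAllele must be 'line1' or 'line2'")
  if (!object@strand %in% c("plus", "minus"))
    msg <- c(msg, "strand must be 'plus' or 'minus'")
  if (object@uniquenessK > object@primerLenMin)
    msg <- c(msg, "uniquenessK must not exceed primerLenMin")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignConfig
#'
#' Defaults: primer length 18-36 nt (the published validated primers span
#' 24-36 nt), Tm window 53-65 deg C (annealing was run at 55-65 deg C),
#' amplicon 100-600 bp (sized for agarose detection), forward primer
#' specific for the line-2 allele, plus-strand design, 15-mer uniqueness
#' screen.
#'
#' @param primerLenMin,primerLenMax primer length bounds (bases)
#' @param tmMin,tmMax primer melting temperature window (deg C)
#' @param tmDiffMax maximum forward/reverse Tm difference (deg C)
#' @param ampMin,ampMax amplicon length bounds (bases)
#' @param targetAllele "line2" (default) or "line1"
#' @param strand "plus" (default) or "minus"
#' @param uniquenessK k-mer size for the 3'-end uniqueness screen
#' @param naMillimolar monovalent cation concentration (mM)
#' @param primerConcMicromolar total primer strand concentration (uM)
#' @return a validated \code{DesignConfig}
#' @examples
#' designConfig(tmMin = 55, tmMax = 62)
#' @export
designConfig <- function(primerLenMin = 18L, primerLenMax = 36L,
                         tmMin = 53, tmMax = 65, tmDiffMax = 5,
                         ampMin = 100L, ampMax = 600L,
                         targetAllele = "line2", strand = "plus",
                         uniquenessK = 15L,
                         naMillimolar = 50, primerConcMicromolar = 0.5) {
  new("DesignConfig",
      primerLenMin = as.integer(primerLenMin),
      primerLenMax = as.integer(primerLenMax),
      tmMin = tmMin, tmMax = tmMax, tmDiffMax = tmDiffMax,
      ampMin = as.integer(ampMin), ampMax = as.integer(ampMax),
      targetAllele = targetAllele, strand = strand,
      uniquenessK = as.integer(uniquenessK),
      naMillimolar = naMillimolar,
      primerConcMicromolar = primerConcMicromolar)
}

setMethod("show", "DesignConfig", function(object) {
  cat(sprintf(
    paste0("DesignConfig: primer %d-%d nt, Tm %.1f-%.1f C (pair diff <= %.1f),",
           " amplicon %d-%d bp,\n  target allele %s, %s strand, uniqueness k=%d,",
           " %.0f mM Na+, %.2f uM primer\n"),
    object@primerLenMin, object@primerLenMax, object@tmMin, object@tmMax,
    object@tmDiffMax, object@ampMin, object@ampMax, object@targetAllele,
    object@strand, object@uniquenessK, object@naMillimolar,
    object@primerConcMicromolar))
})

#' PrimerPair: one designed (or failed) allele-specific primer pair
#'
#' The forward primer is allele-specific: its 3'-terminal base is the target
#' allele and it carries one artificial mismatch at the rule-selected site.
#' Amplicon coordinates are stored 0-based half-open on the reference;
#' user-facing tables report them 1-based inclusive.
#'
#' @slot status "designed" or "failed"; failed pairs carry a \code{reason}
#'   code and empty sequences.
#' @export
setClass("PrimerPair",
  representation(
    primerName = "character", contig = "character", position = "integer",
    snpType = "character", decision = "RuleDecision",
    forwardSeq = "character", reverseSeq = "character",
    forwardTm = "numeric", reverseTm = "numeric",
    ampliconStart = "integer", ampliconEnd = "integer",
    ampliconLength = "integer",
    status = "character", reason = "character", flags = "character"
  )
)

setValidity("PrimerPair", function(object) {
  if (!object@status %in% c("designed", "failed"))
    return("status must be 'designed' or 'failed'")
  if (object@status == "failed" && !nzchar(object@reason))
    return("failed pairs must carry a reason code")
  TRUE
})

setMethod("show", "PrimerPair", function(object) {
  if (object@status == "designed") {
    cat(sprintf(
      "PrimerPair %s (%s:%d, SNP %s, site %d, class %s)\n  F 5'-%s-3' (Tm %.1f)\n  R 5'-%s-3' (Tm %.1f)\n  amplicon %d bp [%d, %d) %s\n",
      object@primerName, object@contig, object@position, object@snpType,
      object@decision@chosenSite, object@decision@mismatchClass,
      object@forwardSeq, object@forwardTm, object@reverseSeq,
      object@reverseTm, object@ampliconLength, object@ampliconStart,
      object@ampliconEnd,
      if (length(object@flags)) paste0("[", paste(object@flags, collapse = ","), "]") else ""))
  } else {
    cat(sprintf("PrimerPair %s (%s:%d, SNP %s): FAILED (%s)\n",
                object@primerName, object@contig, object@position,
                object@snpType, object@reason))
  }
})
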