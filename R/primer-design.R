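## Construction of the allele-specific forward primer and the plain reverse
## primer under Tm / length / amplicon constraints, plus the k-mer
## uniqueness screen. All scans are deterministic (shortest satisfying
## primer, smallest satisfying amplicon) so identical input yields
## byte-identical output.

.getContig <- function(reference, contig = NULL) {
  if (is(reference, "DNAStringSet")) {
    if (is.null(contig)) {
      if (length(reference) != 1L)
        .err("invalidInput", "contig must be named for a multi-sequence reference")
      return(as.character(reference[[1L]]))
    }
    if (!contig %in% names(reference))
      .err("invalidInput", paste0("contig '", contig, "' not in reference"))
    return(as.character(reference[[contig]]))
  }
  if (is.character(reference)) {
    if (!is.null(contig) && !is.null(names(reference))) {
      if (!contig %in% names(reference))
        .err("invalidInput", paste0("contig '", contig, "' not in reference"))
      return(unname(reference[[contig]]))
    }
    return(unname(reference[[1L]]))
  }
  .err("invalidInput", "reference must be a DNAStringSet or character vector")
}

.asSnp <- function(snp) {
  need <- c("contig", "position", "allele_line1", "allele_line2")
  if (!all(need %in% names(snp)))
    .err("invalidInput",
         paste("SNP needs fields", paste(need, collapse = ", ")))
  list(contig = as.character(snp[["contig"]]),
       position = as.integer(snp[["position"]]),
       allele_line1 = as.character(snp[["allele_line1"]]),
       allele_line2 = as.character(snp[["allele_line2"]]))
}

#' Build the allele-specific forward primer
#'
#' The primer lies on the plus strand of the reference, ends exactly at the
#' SNP with the target allele as its 3'-terminal base, and carries the
#' rule-selected artificial mismatch: the base at \code{decision@chosenSite}
#' from the 3' end is replaced by \code{decision@substitutedBase}. The 5'
#' end is extended from \code{primerLenMin} upward until the melting
#' temperature enters the configured window; the shortest satisfying length
#' wins.
#'
#' @param snp list/row with \code{contig}, \code{position},
#'   \code{allele_line1}, \code{allele_line2}
#' @param referenceSeq the contig sequence (character)
#' @param decision a \code{\link{RuleDecision}}
#' @param config a \code{\link{DesignConfig}}
#' @param targetBase the allele placed at the 3' terminus
#' @return list with \code{seq}, \code{tm} and \code{start} (1-based 5'
#'   position on the reference)
#' @export
buildAsForward <- function(snp, referenceSeq, decision, config,
                           targetBase = snp$allele_line2) {
  snp <- c(snp, list())  # tolerate data.frame rows
  pos <- as.integer(snp$position)
  if (pos - config@primerLenMin + 1L < 1L)
    .err("insufficientFlank",
         "not enough 5' flank for the minimum primer length")
  s <- decision@chosenSite
  for (len in config@primerLenMin:config@primerLenMax) {
    start <- pos - len + 1L
    if (start < 1L) break
    core <- paste0(substr(referenceSeq, start, pos - 1L), targetBase)
    idx <- len - s + 1L
    orig <- substr(core, idx, idx)
    if (orig != decision@originalBase)
      .err("invalidInput",
           "decision's original base does not match the reference context")
    primer <- paste0(substr(core, 1L, idx - 1L), decision@substitutedBase,
                     substr(core, idx + 1L, len))
    tm <- meltingTemperature(primer, config@naMillimolar,
                             config@primerConcMicromolar)
    if (tm >= config@tmMin && tm <= config@tmMax)
      return(list(seq = primer, tm = tm, start = start))
  }
  .err("tmUnsatisfiable",
       "no primer length places the forward Tm inside the configured window")
}

#' Pick a non-allele-specific reverse primer
#'
#' Scans amplicon lengths from \code{ampMin} upward and, within each
#' candidate amplicon end, reverse-primer lengths from \code{primerLenMin}
#' upward, returning the first (smallest amplicon, then shortest primer)
#' whose Tm lies in the window and within \code{tmDiffMax} of the forward
#' Tm. The reverse primer is the reverse complement of a plus-strand window
#' strictly downstream of the SNP.
#'
#' @param referenceSeq the contig sequence (character)
#' @param forwardStart 1-based 5' position of the forward primer
#' @param snpPosition 1-based SNP position (forward 3' end)
#' @param forwardTm forward primer Tm (deg C)
#' @param config a \code{\link{DesignConfig}}
#' @return list with \code{seq}, \code{tm}, \code{ampliconEnd} (1-based
#'   inclusive) and \code{ampliconLength}
#' @export
pickReverse <- function(referenceSeq, forwardStart, snpPosition, forwardTm,
                        config) {
  refLen <- nchar(referenceSeq)
  ampLo <- max(config@ampMin,
               snpPosition - forwardStart + 1L + config@primerLenMin)
  for (ampLen in ampLo:config@ampMax) {
    e <- forwardStart + ampLen - 1L
    if (e > refLen) break
    for (rl in config@primerLenMin:config@primerLenMax) {
      s2 <- e - rl + 1L
      if (s2 <= snpPosition) break  # longer primers only reach further left
      rev <- revComp(substr(referenceSeq, s2, e))
      tm <- meltingTemperature(rev, config@naMillimolar,
                               config@primerConcMicromolar)
      if (tm >= config@tmMin && tm <= config@tmMax &&
          abs(tm - forwardTm) <= config@tmDiffMax)
        return(list(seq = rev, tm = tm, ampliconEnd = e,
                    ampliconLength = ampLen))
    }
  }
  .err("ampliconUnsatisfiable",
       "no downstream window satisfies the amplicon/Tm constraints")
}

#' Screen a primer's 3'-terminal k-mer for uniqueness in the reference
#'
#' Counts occurrences of the primer's 3'-terminal k-mer and of its reverse
#' complement in the reference; more than one hit flags likely mis-priming
#' at repetitive sequence.
#'
#' @param primer primer sequence (character)
#' @param reference a \code{DNAStringSet} or character vector of contigs
#' @param config a \code{\link{DesignConfig}} (supplies \code{uniquenessK})
#' @return list with \code{pass} (logical) and \code{count}
#' @export
screenUniqueness <- function(primer, reference, config = designConfig()) {
  .checkSeq(primer, "primer")
  k <- config@uniquenessK
  if (k > nchar(primer))
    .err("invalidConfig", "uniquenessK exceeds the primer length")
  kmer <- substr(primer, nchar(primer) - k + 1L, nchar(primer))
  subject <- if (is(reference, "DNAStringSet")) reference else
    Biostrings::DNAStringSet(unlist(reference, use.names = FALSE))
  cnt <- sum(Biostrings::vcountPattern(kmer, subject)) +
    sum(Biostrings::vcountPattern(revComp(kmer), subject))
  list(pass = cnt <= 1L, count = as.integer(cnt))
}

.nullDecision <- function() {
  new("RuleDecision", snpType = "A/G", compressedType = "TRANSITION",
      chosenSite = 2L, originalBase = "A", substitutedBase = "G",
      mismatchClass = "TG", sitePercent = NA_real_, classPercent = NA_real_)
}

.failedPair <- function(name, snp, reason) {
  new("PrimerPair", primerName = name, contig = snp$contig,
      position = snp$position,
      snpType = tryCatch(classifySnp(snp$allele_line1, snp$allele_line2),
                         error = function(e) NA_character_),
      decision = .nullDecision(), forwardSeq = "", reverseSeq = "",
      forwardTm = NA_real_, reverseTm = NA_real_,
      ampliconStart = NA_integer_, ampliconEnd = NA_integer_,
      ampliconLength = NA_integer_, status = "failed", reason = reason,
      flags = character())
}

## condition class -> reason code for failure rows
.REASONS <- c(insufficientFlank = "flank",
              tmUnsatisfiable = "tm_unsatisfiable",
              ampliconUnsatisfiable = "amplicon_unsatisfiable",
              refMismatch = "ref_mismatch",
              notASNP = "not_a_snp",
              invalidAlphabet = "invalid_alphabet",
              contextTooShort = "flank",
              invalidInput = "invalid_input",
              incompleteTable = "incomplete_table")

.reasonOf <- function(e) {
  hit <- intersect(class(e), names(.REASONS))
  if (length(hit)) .REASONS[[hit[1L]]] else "error"
}

#' Design the allele-specific primer pair for one SNP
#'
#' Composes the design rule, forward-primer construction, reverse-primer
#' scan and uniqueness screen. Any failure yields a structured failed
#' \code{\link{PrimerPair}} with a reason code instead of an error, so batch
#' design never aborts on a single bad SNP.
#'
#' On the minus strand the whole locus is reverse-complemented (alleles
#' complemented, coordinates mirrored), the plus-strand logic applied, and
#' amplicon coordinates mapped back. With \code{targetAllele = "line1"} the
#' allele roles swap and the SNP type reverses accordingly.
#'
#' @param snp list/row with \code{contig}, \code{position},
#'   \code{allele_line1}, \code{allele_line2}
#' @param reference a \code{DNAStringSet} or named character vector
#' @param config a \code{\link{DesignConfig}}
#' @param table a \code{\link{RuleTable}}
#' @param name primer name; default derived from contig and position
#' @return a \code{\link{PrimerPair}}
#' @examples
#' ref <- simulateReference(2000, seed = 7)
#' snps <- simulateSnpPanel(ref, nSnps = 3, seed = 8)
#' designPair(snps[1, ], ref)
#' @export
designPair <- function(snp, reference, config = designConfig(),
                       table = defaultRuleTables(), name = NULL) {
  snp <- tryCatch(.asSnp(snp), ASPrimerError = function(e) e)
  if (is(snp, "condition"))
    return(.failedPair(if (is.null(name)) "NA" else name,
                       list(contig = NA_character_, position = NA_integer_,
                            allele_line1 = "A", allele_line2 = "A"),
                       .reasonOf(snp)))
  if (is.null(name)) name <- paste0("AS_", snp$contig, "_", snp$position)

  tryCatch({
    refSeq <- .getContig(reference, snp$contig)
    refLen <- nchar(refSeq)
    pos <- snp$position
    if (is.na(pos) || pos < 1L || pos > refLen)
      .err("invalidInput", "SNP position outside the reference")
    .checkBase(snp$allele_line1); .checkBase(snp$allele_line2)

    ## minus-strand design: mirror the locus, run plus-strand logic
    if (config@strand == "minus") {
      refSeq <- revComp(refSeq)
      pos <- refLen - pos + 1L
      snp <- list(contig = snp$contig, position = pos,
                  allele_line1 = complementBase(snp$allele_line1),
                  allele_line2 = complementBase(snp$allele_line2))
    }

    if (substr(refSeq, pos, pos) != snp$allele_line1)
      .err("refMismatch",
           "reference base does not equal the line-1 allele at the SNP")

    if (config@targetAllele == "line2") {
      effType <- classifySnp(snp$allele_line1, snp$allele_line2)
      targetBase <- snp$allele_line2
    } else {
      effType <- classifySnp(snp$allele_line2, snp$allele_line1)
      targetBase <- snp$allele_line1
    }

    if (pos < 4L) .err("insufficientFlank", "fewer than 3 bases of 5' flank")
    context <- paste0(substr(refSeq, pos - 3L, pos - 1L), targetBase)
    decision <- designRule(effType, context, table)

    snp$position <- pos
    fwd <- buildAsForward(snp, refSeq, decision, config, targetBase)
    rev <- pickReverse(refSeq, fwd$start, pos, fwd$tm, config)

    flags <- character()
    if (!screenUniqueness(fwd$seq, refSeq, config)$pass)
      flags <- c(flags, "forward_kmer_nonunique")
    if (!screenUniqueness(rev$seq, refSeq, config)$pass)
      flags <- c(flags, "reverse_kmer_nonunique")

    ## 0-based half-open amplicon on the design strand; map back for minus
    a0 <- fwd$start - 1L
    a1 <- rev$ampliconEnd
    if (config@strand == "minus") {
      tmp0 <- refLen - a1
      a1 <- refLen - a0
      a0 <- tmp0
    }
    new("PrimerPair", primerName = name, contig = snp$contig,
        position = snp$position, snpType = effType, decision = decision,
        forwardSeq = fwd$seq, reverseSeq = rev$seq,
        forwardTm = fwd$tm, reverseTm = rev$tm,
        ampliconStart = a0, ampliconEnd = a1,
        ampliconLength = rev$ampliconLength,
        status = "designed", reason = "", flags = flags)
  }, ASPrimerError = function(e) .failedPair(name, snp, .reasonOf(e)))
}

#' Batch primer design
#'
#' @param snps data.frame of SNPs (columns \code{contig}, \code{position},
#'   \code{allele_line1}, \code{allele_line2})
#' @param reference a \code{DNAStringSet} or named character vector
#' @param config a \code{\link{DesignConfig}}
#' @param table a \code{\link{RuleTable}}
#' @return list of \code{\link{PrimerPair}} objects, one per input row, in
#'   input order
#' @seealso \code{\link{primerTable}} to flatten the result
#' @export
designPrimers <- function(snps, reference, config = designConfig(),
                          table = defaultRuleTables()) {
  stopifnot(is.data.frame(snps))
  lapply(seq_len(nrow(snps)), function(i)
    designPair(snps[i, , drop = FALSE], reference, config, table,
               name = sprintf("AS%04d_%s_%s", i, snps$contig[i],
                              snps$position[i])))
}

#' Flatten designed pairs into the standard primer table
#'
#' One row per input SNP with the annotation schema of published AS-PCR
#' primer tables (SNP type, mismatch site, mismatch class, sequences) plus
#' provenance columns; failed designs keep their row with empty sequences
#' and a reason code.
#'
#' @param pairs list of \code{\link{PrimerPair}} objects
#' @return data.frame with stable column order
#' @export
primerTable <- function(pairs) {
  if (is(pairs, "PrimerPair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    ok <- p@status == "designed"
    data.frame(
      primer_name = p@primerName, contig = p@contig, position = p@position,
      snp_type = p@snpType,
      compressed_type = if (ok) p@decision@compressedType else NA_character_,
      mismatch_site = if (ok) p@decision@chosenSite else NA_integer_,
      mismatch_class = if (ok) p@decision@mismatchClass else NA_character_,
      substituted_base = if (ok) p@decision@substitutedBase else NA_character_,
      forward_seq = p@forwardSeq, reverse_seq = p@reverseSeq,
      forward_tm = if (ok) round(p@forwardTm, 2) else NA_real_,
      reverse_tm = if (ok) round(p@reverseTm, 2) else NA_real_,
      amplicon_length = p@ampliconLength,
      status = p@status,
      reason = p@reason,
      flags = paste(p@flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
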