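## Readers and writers: FASTA references, SNPs from VCF or TSV, the primer
## output table, and amplicon BED. Internal coordinates are 0-based
## half-open; user tables are 1-based inclusive; BED is 0-based half-open.

#' Read an indexed reference from FASTA
#'
#' Sequence names are truncated at the first whitespace, sequences are
#' uppercased, and anything outside A/C/G/T/N is rejected.
#'
#' @param path FASTA file
#' @return a named \code{Biostrings::DNAStringSet}
#' @export
readReference <- function(path) {
  if (!file.exists(path)) .err("invalidInput", paste("no such file:", path))
  raw <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    .err("invalidInput",
         paste("duplicate sequence ids in", path, ":",
               paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    .err("invalidAlphabet",
         paste("non-ACGTN characters in sequence(s):",
               paste(ids[bad], collapse = ", ")))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

.readSnpTsv <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\S+\\t\\d+\\t", first)
  tab <- utils::read.delim(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    .err("invalidInput", "SNP TSV needs 4 columns: contig, position, allele_line1, allele_line2")
  tab <- tab[, 1:4]
  names(tab) <- c("contig", "position", "allele_line1", "allele_line2")
  tab$position <- as.integer(tab$position)
  tab
}

.readSnpVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "custom")
  gr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  alt1 <- rep(NA_character_, length(nAlt))
  alt1[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr),
             allele_line1 = ref, allele_line2 = alt1,
             n_alt = nAlt, stringsAsFactors = FALSE)
}

#' Read biallelic SNVs from VCF or TSV
#'
#' Keeps biallelic single-nucleotide records whose REF (line-1 allele)
#' matches the reference base when a reference is supplied; skips indels,
#' multi-allelic records, non-ACGT alleles and reference mismatches with a
#' per-reason tally. VCF positions are 1-based.
#'
#' @param path a \code{.vcf} file or a 4-column TSV (contig, 1-based
#'   position, line-1 allele, line-2 allele; header optional)
#' @param reference optional \code{DNAStringSet} for REF checking
#' @return list with \code{snps} (data.frame with \code{contig},
#'   \code{position}, \code{allele_line1}, \code{allele_line2},
#'   \code{snp_type}) and \code{skipped} (named tally)
#' @export
readSnps <- function(path, reference = NULL) {
  if (!file.exists(path)) .err("invalidInput", paste("no such file:", path))
  isVcf <- grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)
  tab <- if (isVcf) .readSnpVcf(path) else .readSnpTsv(path)
  tab$allele_line1 <- toupper(tab$allele_line1)
  tab$allele_line2 <- toupper(tab$allele_line2)

  reason <- rep("kept", nrow(tab))
  if ("n_alt" %in% names(tab))
    reason[tab$n_alt != 1L] <- "multiallelic"
  ok <- reason == "kept"
  len1 <- nchar(tab$allele_line1) == 1L & nchar(tab$allele_line2) == 1L &
    !is.na(tab$allele_line2)
  reason[ok & !len1] <- "indel"
  ok <- reason == "kept"
  valid <- tab$allele_line1 %in% .BASES & tab$allele_line2 %in% .BASES
  reason[ok & !valid] <- "invalid_alphabet"
  ok <- reason == "kept"
  mono <- valid & tab$allele_line1 == tab$allele_line2
  reason[ok & mono] <- "monomorphic"
  ok <- reason == "kept"
  if (!is.null(reference)) {
    refBase <- rep(NA_character_, nrow(tab))
    for (i in which(ok)) {
      if (tab$contig[i] %in% names(reference)) {
        sq <- reference[[tab$contig[i]]]
        if (tab$position[i] >= 1L && tab$position[i] <= length(sq))
          refBase[i] <- as.character(Biostrings::subseq(
            sq, tab$position[i], tab$position[i]))
      }
    }
    reason[ok & (is.na(refBase) | refBase != tab$allele_line1)] <-
      "ref_mismatch"
  }

  kept <- tab[reason == "kept",
              c("contig", "position", "allele_line1", "allele_line2")]
  kept$snp_type <- paste0(kept$allele_line1, "/", kept$allele_line2)
  rownames(kept) <- NULL
  skipReasons <- c("indel", "multiallelic", "monomorphic",
                   "invalid_alphabet", "ref_mismatch")
  tally <- vapply(skipReasons, function(r) sum(reason == r), integer(1))
  list(snps = kept, skipped = tally)
}

#' Write the primer table as TSV
#'
#' One row per input SNP in input order, stable column order, byte-identical
#' across runs on identical input.
#'
#' @param pairs list of \code{\link{PrimerPair}} objects (or a prebuilt
#'   \code{\link{primerTable}} data.frame)
#' @param path output TSV path
#' @return invisibly, the written data.frame
#' @export
writePrimerTable <- function(pairs, path) {
  tab <- if (is.data.frame(pairs)) pairs else primerTable(pairs)
  if (is.null(tab))
    tab <- primerTable(list())  # not reached; keep type stable
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(tab)
}

#' Write designed amplicons as BED
#'
#' 0-based half-open intervals from the forward primer's 5' start to the
#' reverse primer's 5' start, named by primer; failed designs are omitted.
#'
#' @param pairs list of \code{\link{PrimerPair}} objects
#' @param path output BED path
#' @return invisibly, the path
#' @export
writeAmpliconBed <- function(pairs, path) {
  if (is(pairs, "PrimerPair")) pairs <- list(pairs)
  ok <- Filter(function(p) p@status == "designed", pairs)
  if (length(ok) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(ok, function(p) p@contig, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(ok, function(p) p@ampliconStart + 1L, integer(1)),
      end = vapply(ok, function(p) p@ampliconEnd, integer(1))),
    name = vapply(ok, function(p) p@primerName, character(1)),
    score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
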