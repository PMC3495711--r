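## Synthetic data: references, SNP panels with a realistic type spectrum,
## and Bernoulli primer-validation outcomes at the empirical cell rates.
## Every simulator takes an explicit seed and leaves the caller's RNG state
## untouched.

.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    .err("invalidInput", "a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a random reference sequence
#'
#' Bases are drawn i.i.d. with the requested GC content, split evenly
#' between G and C (and A and T).
#'
#' @param length sequence length in bases (> 0)
#' @param gc GC fraction in (0, 1); default 0.5
#' @param seed RNG seed (required)
#' @param name sequence name used in FASTA/VCF output
#' @return a single-sequence \code{Biostrings::DNAStringSet}
#' @examples
#' ref <- simulateReference(1000, seed = 1)
#' @export
simulateReference <- function(length, gc = 0.5, seed, name = "sim1") {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    .err("invalidInput", "length must be a positive integer")
  if (!is.finite(gc) || gc <= 0 || gc >= 1)
    .err("invalidInput", "gc must lie strictly between 0 and 1")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- .withSeed(seed,
    sample(names(probs), length, replace = TRUE, prob = probs))
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- name
  out
}

## normalized per-type frequencies from the packaged SNP spectrum counts
defaultTypeFrequencies <- function() {
  path <- system.file("extdata", "table1_snp_counts.tsv",
                      package = "ASPrimer", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(tab$count / sum(tab$count), names = tab$snp_type)[SNP_TYPES]
}

#' Default per-(site, class) polymorphism probabilities
#'
#' The packaged empirical cell percentages divided by 100, used as Bernoulli
#' success rates by \code{\link{simulateOutcomes}}.
#'
#' @return 3 x 8 matrix (sites 2-4 x mismatch classes)
#' @export
defaultOutcomeRates <- function() {
  rt <- defaultRuleTables()
  rt@scNum / rt@scDen
}

#' Simulate a biallelic SNP panel on a reference
#'
#' Positions are drawn uniformly subject to a minimum spacing; the line-1
#' allele always equals the reference base, and the ordered SNP type is
#' drawn from \code{typeFrequencies} conditioned on compatibility with that
#' base (types whose line-1 allele differs from the reference base are
#' excluded and the remaining mass renormalized, equivalent to resampling).
#' Defaults reproduce the genome-scale spectrum in which 56.7 percent of
#' substitutions are transitions.
#'
#' @param reference a \code{DNAStringSet} (first sequence is used) or
#'   character string
#' @param nSnps number of SNPs to place
#' @param typeFrequencies named 12-vector of ordered-type probabilities
#'   summing to 1; default the packaged genome spectrum
#' @param minSpacing minimum distance between consecutive SNPs (default 100,
#'   of the order of the one-SNP-per-360-bp genome average)
#' @param buffer keep SNPs at least this many bases from either reference
#'   end (room for primers and amplicons)
#' @param seed RNG seed (required)
#' @return data.frame with columns \code{contig}, \code{position},
#'   \code{allele_line1}, \code{allele_line2}, \code{snp_type}
#' @examples
#' ref <- simulateReference(10000, seed = 1)
#' panel <- simulateSnpPanel(ref, nSnps = 20, seed = 2)
#' @export
simulateSnpPanel <- function(reference, nSnps,
                             typeFrequencies = defaultTypeFrequencies(),
                             minSpacing = 100L, buffer = 0L, seed) {
  refSeq <- .getContig(reference)
  contig <- if (is(reference, "DNAStringSet") && !is.null(names(reference)))
    names(reference)[1L] else "sim1"
  nSnps <- as.integer(nSnps)
  minSpacing <- max(1L, as.integer(minSpacing))
  lo <- 1L + as.integer(buffer)
  hi <- nchar(refSeq) - as.integer(buffer)
  width <- hi - lo + 1L
  if (nSnps < 1L) .err("invalidInput", "nSnps must be >= 1")
  if (abs(sum(typeFrequencies) - 1) > 1e-9)
    .err("invalidInput", "typeFrequencies must sum to 1")
  if (!all(SNP_TYPES %in% names(typeFrequencies)))
    .err("invalidInput", "typeFrequencies must be named by the 12 SNP types")
  ## uniform sample of spaced positions: shrink, sample, re-expand
  effWidth <- width - (nSnps - 1L) * (minSpacing - 1L)
  if (effWidth < nSnps)
    .err("invalidInput",
         "cannot place nSnps positions with the requested spacing")
  .withSeed(seed, {
    pos <- sort(sample.int(effWidth, nSnps)) +
      (seq_len(nSnps) - 1L) * (minSpacing - 1L) + lo - 1L
    a1 <- substring(refSeq, pos, pos)
    a2 <- vapply(a1, function(b) {
      ok <- startsWith(SNP_TYPES, b)
      ty <- sample(SNP_TYPES[ok], 1L, prob = typeFrequencies[SNP_TYPES[ok]])
      substr(ty, 3L, 3L)
    }, character(1), USE.NAMES = FALSE)
    data.frame(contig = contig, position = pos, allele_line1 = a1,
               allele_line2 = a2,
               snp_type = paste0(a1, "/", a2),
               stringsAsFactors = FALSE)
  })
}

#' Simulate binary primer-validation outcomes
#'
#' One independent Bernoulli draw per design decision at the per-(site,
#' class) success probability.
#'
#' @param decisions list of \code{\link{RuleDecision}} objects, or a
#'   data.frame with columns \code{snp_type}, \code{mismatch_site} and
#'   \code{mismatch_class}
#' @param rates 3 x 8 matrix of probabilities (rows "2","3","4", columns the
#'   mismatch classes); default \code{\link{defaultOutcomeRates}}
#' @param seed RNG seed (required)
#' @return data.frame with columns \code{primer_id}, \code{snp_type},
#'   \code{mismatch_site}, \code{mismatch_class}, \code{polymorphic}
#' @export
simulateOutcomes <- function(decisions, rates = defaultOutcomeRates(), seed) {
  if (is.data.frame(decisions)) {
    df <- data.frame(
      snp_type = as.character(decisions$snp_type),
      mismatch_site = as.integer(decisions$mismatch_site),
      mismatch_class = vapply(as.character(decisions$mismatch_class),
                              canonicalMismatchClass, character(1),
                              USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(decisions, function(d) {
      stopifnot(is(d, "RuleDecision"))
      data.frame(snp_type = d@snpType, mismatch_site = d@chosenSite,
                 mismatch_class = d@mismatchClass, stringsAsFactors = FALSE)
    }))
  }
  idx <- cbind(as.character(df$mismatch_site), df$mismatch_class)
  p <- rates[idx]
  if (anyNA(p))
    .err("incompleteTable", "missing outcome rate for some (site, class) cell")
  poly <- .withSeed(seed, stats::rbinom(nrow(df), 1L, p))
  data.frame(primer_id = sprintf("sim%05d", seq_len(nrow(df))), df,
             polymorphic = poly, stringsAsFactors = FALSE)
}

#' Write a SNP panel as a minimal VCF
#'
#' Emits a VCFv4.2 file with CHROM/POS/ID/REF/ALT columns (REF = line-1
#' allele, ALT = line-2 allele, 1-based positions) readable by standard VCF
#' parsers, including \code{\link{readSnps}}.
#'
#' @param panel data.frame as returned by \code{\link{simulateSnpPanel}}
#' @param path output file path
#' @param reference optional \code{DNAStringSet} used to emit contig header
#'   lines with lengths
#' @return invisibly, the path
#' @export
writeSnpVcf <- function(panel, path, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ASPrimer.simulateSnpPanel")
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          Biostrings::width(reference)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  body <- sprintf("%s\t%d\tsnp%05d\t%s\t%s\t.\t.\t.",
                  panel$contig, panel$position, seq_len(nrow(panel)),
                  panel$allele_line1, panel$allele_line2)
  writeLines(c(hdr, body), path)
  invisible(path)
}
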