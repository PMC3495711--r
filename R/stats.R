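## Empirical summaries: SNP-type spectrum, candidate filtering, proportions
## with Wilson intervals, and full polymorphism summaries of outcome tables.

#' SNP-type spectrum with transition/transversion totals
#'
#' Accepts either per-SNP data (a character vector of ordered SNP types, or
#' a data.frame with \code{allele_line1}/\code{allele_line2} or
#' \code{snp_type} columns) or a named count vector giving the number of
#' SNPs per type -- convenient when only published per-type totals are
#' available.
#'
#' @param x SNP types, SNP table, or named per-type counts
#' @return list with \code{perType} (data.frame of counts and shares),
#'   \code{transitions}, \code{transversions}, \code{total},
#'   \code{transitionPercent}, \code{transversionPercent} (1-decimal;
#'   NA when total is zero)
#' @examples
#' snpSpectrum(c("A/G", "A/G", "T/A"))
#' @export
snpSpectrum <- function(x) {
  if (is.data.frame(x)) {
    if ("snp_type" %in% names(x)) {
      types <- as.character(x$snp_type)
    } else {
      types <- mapply(classifySnp, as.character(x$allele_line1),
                      as.character(x$allele_line2), USE.NAMES = FALSE)
    }
    counts <- table(factor(types, SNP_TYPES))
  } else if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% SNP_TYPES))
      .err("invalidSNPType", "count vector must be named by SNP type")
    counts <- structure(rep(0, 12), names = SNP_TYPES)
    counts[names(x)] <- x
  } else if (is.character(x)) {
    for (t in x) .checkSnpType(t)
    counts <- table(factor(x, SNP_TYPES))
  } else {
    .err("invalidInput", "unsupported input to snpSpectrum")
  }
  counts <- as.numeric(counts[SNP_TYPES])
  names(counts) <- SNP_TYPES
  isTi <- vapply(SNP_TYPES, isTransition, logical(1))
  ti <- sum(counts[isTi]); tv <- sum(counts[!isTi]); tot <- ti + tv
  perType <- data.frame(
    snp_type = SNP_TYPES, count = counts,
    change = ifelse(isTi, "transition", "transversion"),
    percent = if (tot > 0) pctFmt(counts, tot) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  list(perType = perType, transitions = ti, transversions = tv, total = tot,
       transitionPercent = if (tot > 0) pctFmt(ti, tot) else NA_real_,
       transversionPercent = if (tot > 0) pctFmt(tv, tot) else NA_real_)
}

#' Filter raw SNP candidates before primer design
#'
#' Retains candidates that are strictly biallelic (exactly two observed
#' alleles), covered by at least \code{minDepth} reads, and mapped to a
#' unique site; everything else is rejected with a per-reason tally.
#' Tri-allelic (or more polymorphic) sites are the operational reading of
#' "high degree of polymorphism"; the depth default of 8 keeps the minimal
#' retained class at exactly 8 reads.
#'
#' @param candidates data.frame with columns \code{contig}, \code{position},
#'   \code{alleles_observed} (comma-separated string or list of base
#'   vectors), \code{read_depth} and \code{maps_uniquely}
#' @param minDepth minimum read depth (default 8, inclusive)
#' @return list with \code{retained} (subset of \code{candidates}) and
#'   \code{tally} (named counts: retained, not_biallelic, low_depth,
#'   non_unique)
#' @export
filterSnpCandidates <- function(candidates, minDepth = 8) {
  stopifnot(is.data.frame(candidates))
  nAlleles <- if (is.list(candidates$alleles_observed)) {
    lengths(lapply(candidates$alleles_observed, unique))
  } else {
    lengths(lapply(strsplit(as.character(candidates$alleles_observed),
                            "[,;/ ]+"), unique))
  }
  reason <- rep("retained", nrow(candidates))
  reason[candidates$read_depth < minDepth] <- "low_depth"
  reason[!as.logical(candidates$maps_uniquely)] <- "non_unique"
  reason[nAlleles != 2L] <- "not_biallelic"
  tally <- vapply(c("retained", "not_biallelic", "low_depth", "non_unique"),
                  function(r) sum(reason == r), integer(1))
  list(retained = candidates[reason == "retained", , drop = FALSE],
       tally = tally, reasons = reason)
}

#' Binomial proportion with Wilson score interval
#'
#' @param numerator,denominator non-negative counts, numerator <=
#'   denominator, denominator > 0
#' @param level confidence level (default 0.95)
#' @return list with \code{percent} (1-decimal, half-up), \code{ciLow} and
#'   \code{ciHigh} (percent scale, unrounded)
#' @examples
#' proportionWithCI(37, 79)   # 46.8
#' proportionWithCI(158, 193) # 81.9
#' @export
proportionWithCI <- function(numerator, denominator, level = 0.95) {
  if (denominator <= 0) .err("invalidInput", "denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    .err("invalidInput", "numerator must lie in [0, denominator]")
  ci <- if (numerator %in% c(0, denominator)) {
    ## prop.test warns at the boundary; Wilson closed form is exact there
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- numerator / denominator; n <- denominator
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(ctr - hw, ctr + hw)
  } else {
    suppressWarnings(stats::prop.test(numerator, denominator,
                                      conf.level = level,
                                      correct = FALSE))$conf.int
  }
  list(percent = pctFmt(numerator, denominator),
       ciLow = 100 * ci[1L], ciHigh = 100 * ci[2L])
}

#' Full polymorphism summary of an outcome table
#'
#' Aggregates raw primer-validation outcomes into the two rule tables,
#' and reports every cell and margin with its Wilson interval. Margins are
#' computed by summation.
#'
#' @param outcomes data.frame as for \code{\link{deriveRuleTables}}
#' @param level confidence level for the intervals
#' @return list with \code{ruleTable} (a \code{\link{RuleTable}}),
#'   \code{siteGroup}, \code{siteClass}, \code{siteMargins},
#'   \code{groupMargins} and \code{overall} data.frames
#' @export
polymorphismSummary <- function(outcomes, level = 0.95) {
  rt <- deriveRuleTables(outcomes)
  cellDf <- function(num, den) {
    df <- expand.grid(site = rownames(num), key = colnames(num),
                      stringsAsFactors = FALSE)
    df$numerator <- num[cbind(df$site, df$key)]
    df$denominator <- den[cbind(df$site, df$key)]
    ciCols(df, level)
  }
  marginDf <- function(num, den, keyName) {
    df <- data.frame(key = names(num), numerator = unname(num),
                     denominator = unname(den), stringsAsFactors = FALSE)
    names(df)[1L] <- keyName
    ciCols(df, level)
  }
  list(ruleTable = rt,
       siteGroup = cellDf(rt@sgNum, rt@sgDen),
       siteClass = cellDf(rt@scNum, rt@scDen),
       siteMargins = marginDf(rt@siteMarginNum, rt@siteMarginDen, "site"),
       groupMargins = marginDf(rt@groupMarginNum, rt@groupMarginDen, "group"),
       overall = ciCols(data.frame(numerator = rt@grandNum,
                                   denominator = rt@grandDen), level))
}

## attach percent/ci columns to a counts data.frame; NA where untested
ciCols <- function(df, level) {
  res <- lapply(seq_len(nrow(df)), function(i) {
    if (df$denominator[i] == 0)
      return(c(NA_real_, NA_real_, NA_real_))
    p <- proportionWithCI(df$numerator[i], df$denominator[i], level)
    c(p$percent, p$ciLow, p$ciHigh)
  })
  res <- do.call(rbind, res)
  df$percent <- res[, 1L]; df$ci_low <- res[, 2L]; df$ci_high <- res[, 3L]
  df
}
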