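## RuleTable construction, packaged defaults, derivation from raw
## primer-validation outcomes, and percentage accessors.

#' Round half-up
#'
#' Plain decimal rounding with ties away from zero, matching how the
#' published percentages are printed (base \code{round} rounds half to
#' even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## percentage at 1 decimal, the table-printing convention
pctFmt <- function(num, den) roundHalfUp(100 * num / den, 1)

.emptyMat <- function(cols) {
  matrix(0, nrow = 3, ncol = length(cols),
         dimnames = list(c("2", "3", "4"), cols))
}

#' Construct a RuleTable from count matrices
#'
#' @param sgNum,sgDen 3 x 4 matrices of polymorphic / tested counts per
#'   (site, compressed group); rownames "2","3","4", colnames the groups.
#' @param scNum,scDen 3 x 8 matrices per (site, mismatch class).
#' @param siteMarginNum,siteMarginDen,groupMarginNum,groupMarginDen,grandNum,grandDen
#'   optional marginal counts; computed by summation over cells when absent.
#'   Supplying them explicitly preserves published margins that differ from
#'   the cell sums.
#' @return a validated \code{\link{RuleTable}}
#' @export
ruleTable <- function(sgNum, sgDen, scNum, scDen,
                      siteMarginNum = NULL, siteMarginDen = NULL,
                      groupMarginNum = NULL, groupMarginDen = NULL,
                      grandNum = NULL, grandDen = NULL) {
  if (is.null(siteMarginNum)) siteMarginNum <- rowSums(sgNum)
  if (is.null(siteMarginDen)) siteMarginDen <- rowSums(sgDen)
  if (is.null(groupMarginNum)) groupMarginNum <- colSums(sgNum)
  if (is.null(groupMarginDen)) groupMarginDen <- colSums(sgDen)
  if (is.null(grandNum)) grandNum <- sum(sgNum)
  if (is.null(grandDen)) grandDen <- sum(sgDen)
  new("RuleTable", sgNum = sgNum, sgDen = sgDen, scNum = scNum,
      scDen = scDen,
      siteMarginNum = siteMarginNum, siteMarginDen = siteMarginDen,
      groupMarginNum = groupMarginNum, groupMarginDen = groupMarginDen,
      grandNum = grandNum, grandDen = grandDen)
}

.readCountFile <- function(path, keys, what) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  need <- c("site", "key", "numerator", "denominator")
  if (!all(need %in% names(tab)))
    .err("incompleteTable",
         paste0(what, " must have columns ", paste(need, collapse = ", ")))
  num <- .emptyMat(keys)
  den <- .emptyMat(keys)
  marg <- list(siteNum = NULL, siteDen = NULL, keyNum = NULL, keyDen = NULL,
               grandNum = NULL, grandDen = NULL)
  for (i in seq_len(nrow(tab))) {
    s <- tab$site[i]; k <- tab$key[i]
    if (s == "ALL" && k == "ALL") {
      marg$grandNum <- tab$numerator[i]; marg$grandDen <- tab$denominator[i]
    } else if (s == "ALL") {
      marg$keyNum[k] <- tab$numerator[i]; marg$keyDen[k] <- tab$denominator[i]
    } else if (k == "ALL") {
      marg$siteNum[s] <- tab$numerator[i]; marg$siteDen[s] <- tab$denominator[i]
    } else {
      if (!s %in% c("2", "3", "4"))
        .err("incompleteTable", paste0(what, ": invalid site '", s, "'"))
      if (!k %in% keys)
        .err("incompleteTable", paste0(what, ": invalid key '", k, "'"))
      num[s, k] <- tab$numerator[i]; den[s, k] <- tab$denominator[i]
    }
  }
  list(num = num, den = den, marg = marg)
}

#' Read rule tables from TSV count files
#'
#' Each file has columns \code{site} (2/3/4 or ALL for a margin), \code{key}
#' (a compressed group or mismatch class, or ALL), \code{numerator}
#' (polymorphic primer pairs) and \code{denominator} (tested pairs). Margin
#' rows are optional; when present they are preserved verbatim, otherwise
#' margins are cell sums. Classes may be spelled in either letter order.
#'
#' @param siteGroupPath TSV of site-by-compressed-group counts
#' @param siteClassPath TSV of site-by-mismatch-class counts
#' @return a \code{\link{RuleTable}}
#' @seealso \code{\link{defaultRuleTables}} for the packaged counts
#' @export
readRuleTables <- function(siteGroupPath, siteClassPath) {
  sg <- .readCountFile(siteGroupPath, COMPRESSED_GROUPS, "site-by-group table")
  sc4 <- utils::read.delim(siteClassPath, stringsAsFactors = FALSE,
                           colClasses = "character")
  sc4$key <- vapply(sc4$key, canonicalMismatchClass, character(1))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(sc4, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- .readCountFile(tmp, MISMATCH_CLASSES, "site-by-class table")
  m <- sg$marg
  ruleTable(sg$num, sg$den, sc$num, sc$den,
            siteMarginNum = if (is.null(m$siteNum)) NULL else
              m$siteNum[c("2", "3", "4")],
            siteMarginDen = if (is.null(m$siteDen)) NULL else
              m$siteDen[c("2", "3", "4")],
            groupMarginNum = if (is.null(m$keyNum)) NULL else
              m$keyNum[COMPRESSED_GROUPS],
            groupMarginDen = if (is.null(m$keyDen)) NULL else
              m$keyDen[COMPRESSED_GROUPS],
            grandNum = m$grandNum, grandDen = m$grandDen)
}

#' The packaged default rule tables
#'
#' Polymorphism counts of 1686 validated allele-specific primer pairs,
#' cross-classified by mismatch site and compressed SNP group and by
#' mismatch site and mismatch class, as published. Printed marginal counts
#' are preserved verbatim; note that in the published site-by-group table
#' the cell numerators do not sum exactly to the printed margins (see the
#' methods vignette).
#'
#' @param dir optional directory holding \code{table3_site_by_group.tsv} and
#'   \code{table4_site_by_class.tsv} in the same schema, for species-specific
#'   tables
#' @return a \code{\link{RuleTable}}
#' @examples
#' rt <- defaultRuleTables()
#' selectSite("AT_TA", rt)
#' @export
defaultRuleTables <- function(dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", package = "ASPrimer", mustWork = TRUE)
  readRuleTables(file.path(dir, "table3_site_by_group.tsv"),
                 file.path(dir, "table4_site_by_class.tsv"))
}

#' Derive rule tables from raw primer-validation outcomes
#'
#' Aggregates per-primer binary polymorphism results into the two count
#' tables that drive design. Margins are always computed by summation here
#' (raw data cannot disagree with itself).
#'
#' @param outcomes data.frame with columns \code{snp_type},
#'   \code{mismatch_site} (2/3/4), \code{mismatch_class} (either spelling)
#'   and \code{polymorphic} (logical or 0/1)
#' @return a \code{\link{RuleTable}}
#' @examples
#' out <- data.frame(snp_type = "T/A", mismatch_site = 3,
#'                   mismatch_class = "CA", polymorphic = 1)
#' deriveRuleTables(out)
#' @export
deriveRuleTables <- function(outcomes) {
  need <- c("snp_type", "mismatch_site", "mismatch_class", "polymorphic")
  if (!all(need %in% names(outcomes)))
    .err("incompleteTable",
         paste("outcomes must have columns", paste(need, collapse = ", ")))
  if (nrow(outcomes) == 0L)
    .err("incompleteTable", "no outcome records supplied")
  site <- as.character(outcomes$mismatch_site)
  if (!all(site %in% c("2", "3", "4")))
    .err("incompleteTable", "mismatch_site must be 2, 3 or 4")
  grp <- vapply(as.character(outcomes$snp_type), compressType, character(1))
  cls <- vapply(as.character(outcomes$mismatch_class),
                canonicalMismatchClass, character(1))
  poly <- as.logical(outcomes$polymorphic)
  if (anyNA(poly)) .err("incompleteTable", "polymorphic must be 0/1 or logical")

  tally <- function(key, keys) {
    den <- .emptyMat(keys)
    num <- .emptyMat(keys)
    t1 <- table(factor(site, c("2", "3", "4")), factor(key, keys))
    t2 <- table(factor(site[poly], c("2", "3", "4")), factor(key[poly], keys))
    den[] <- as.numeric(t1); num[] <- as.numeric(t2)
    list(num = num, den = den)
  }
  sg <- tally(grp, COMPRESSED_GROUPS)
  sc <- tally(cls, MISMATCH_CLASSES)
  ruleTable(sg$num, sg$den, sc$num, sc$den)
}

#' Site-by-group percentage matrix
#' @param table a \code{\link{RuleTable}}
#' @return 3 x 4 matrix of percentages at 1 decimal; NA for empty cells
#' @export
siteGroupPercent <- function(table) {
  stopifnot(is(table, "RuleTable"))
  p <- pctFmt(table@sgNum, table@sgDen)
  p[table@sgDen == 0] <- NA_real_
  p
}

#' Site-by-class percentage matrix
#' @param table a \code{\link{RuleTable}}
#' @return 3 x 8 matrix of percentages at 1 decimal; NA for empty cells
#' @export
siteClassPercent <- function(table) {
  stopifnot(is(table, "RuleTable"))
  p <- pctFmt(table@scNum, table@scDen)
  p[table@scDen == 0] <- NA_real_
  p
}

#' Marginal percentages of a RuleTable
#' @param table a \code{\link{RuleTable}}
#' @return list with \code{site}, \code{group} and \code{overall}
#'   percentages at 1 decimal
#' @export
ruleTableMargins <- function(table) {
  stopifnot(is(table, "RuleTable"))
  list(site = pctFmt(table@siteMarginNum, table@siteMarginDen),
       group = pctFmt(table@groupMarginNum, table@groupMarginDen),
       overall = pctFmt(table@grandNum, table@grandDen))
}
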