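## The core design algorithm: enumerate the nine candidate artificial
## mismatches in the 3' context, pick the mismatch site per compressed SNP
## group, pick the substituted base per site, and audit annotated primer
## tables for conformance with the rule.

.checkContext <- function(context) {
  .checkSeq(context, "3' context")
  if (nchar(context) != 4L)
    .err("contextTooShort",
         "primer 3' context must be exactly 4 bases (positions 4..1 from the 3' end, 5'->3')")
  invisible(context)
}

## base at position `site` counted from the 3' end of a 5'->3' string
.baseFrom3 <- function(seq, site) {
  n <- nchar(seq)
  substring(seq, n - site + 1L, n - site + 1L)
}

#' Enumerate the nine candidate artificial mismatches
#'
#' Given the last four bases of an allele-specific primer (5'->3'; the final
#' base is the allele-specific terminus, position 1), every substitution of
#' the bases at positions 2, 3 and 4 from the 3' end yields a candidate
#' mismatch against the template: 3 sites x 3 alternative bases = 9
#' candidates. The terminal base is never modified. Because the template
#' base is the complement of the original primer base, a substitution can
#' never recreate a Watson-Crick pair, so all nine candidates are true
#' mismatches.
#'
#' @param context the primer's last 4 bases, 5'->3'
#' @return data.frame with columns \code{site}, \code{original},
#'   \code{substituted}, \code{template} and \code{class} (9 rows)
#' @examples
#' enumerateCandidates("TCGA")
#' @export
enumerateCandidates <- function(context) {
  .checkContext(context)
  rows <- lapply(2:4, function(site) {
    orig <- .baseFrom3(context, site)
    tmpl <- complementBase(orig)
    subs <- setdiff(.BASES, orig)
    data.frame(site = site, original = orig, substituted = subs,
               template = tmpl,
               class = vapply(subs, function(s) mismatchClassFor(tmpl, s),
                              character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Select the mismatch site for a compressed SNP group
#'
#' Returns the site (2, 3 or 4 from the 3' end) whose empirical polymorphism
#' percentage is highest in the group's column of the rule table. Ties break
#' toward the smaller site index.
#'
#' @param group one of \code{\link{COMPRESSED_GROUPS}} (or an ordered SNP
#'   type, which is compressed first)
#' @param table a \code{\link{RuleTable}}; default the packaged counts
#' @return list with \code{site} (integer) and \code{percent}
#' @examples
#' selectSite("AT_TA")   # site 3, 45.9
#' selectSite("CG_GC")   # site 2, 43.3
#' @export
selectSite <- function(group, table = defaultRuleTables()) {
  if (group %in% SNP_TYPES) group <- compressType(group)
  if (!group %in% COMPRESSED_GROUPS)
    .err("invalidSNPType", paste0("unknown compressed group '", group, "'"))
  p <- siteGroupPercent(table)[, group]
  if (anyNA(p))
    .err("incompleteTable",
         paste0("rule table has empty site cells for group ", group))
  best <- which.max(p)  # first maximum = smaller site on ties
  list(site = as.integer(names(p)[best]), percent = unname(p[best]))
}

#' Select the substituted base at a given site
#'
#' For the primer's original base at the chosen site, three mismatch classes
#' are reachable (one per alternative base). The substitution whose class
#' has the highest empirical percentage in the site's row wins; ties break
#' by substituted base in the fixed order A < C < G < T.
#'
#' @param site mismatch site, 2, 3 or 4 from the 3' end
#' @param originalBase the primer/template-matching base currently at that
#'   site
#' @param table a \code{\link{RuleTable}}; default the packaged counts
#' @return list with \code{substituted}, \code{class} and \code{percent}
#' @examples
#' selectSubstitution(3, "G")  # substitute A, class CA, 46.8
#' @export
selectSubstitution <- function(site, originalBase,
                               table = defaultRuleTables()) {
  site <- as.integer(site)
  if (!site %in% 2:4) .err("invalidSite", "site must be 2, 3 or 4")
  .checkBase(originalBase, "original base")
  tmpl <- complementBase(originalBase)
  subs <- sort(setdiff(.BASES, originalBase))  # A < C < G < T
  cls <- vapply(subs, function(s) mismatchClassFor(tmpl, s), character(1))
  p <- siteClassPercent(table)[as.character(site), cls]
  if (anyNA(p))
    .err("incompleteTable",
         paste0("rule table has empty class cells at site ", site, ": ",
                paste(cls[is.na(p)], collapse = ", ")))
  best <- which.max(p)  # first maximum = alphabetically smallest substitution
  list(substituted = subs[best], class = unname(cls[best]),
       percent = unname(p[best]))
}

#' Apply the full design rule to one SNP
#'
#' Deterministically composes type compression, site selection and
#' substitution selection into the single best artificial mismatch for a
#' SNP, given the primer's 3' context.
#'
#' @param snpType one of the 12 ordered SNP types
#' @param context the primer's last 4 bases, 5'->3' (position 1 = the
#'   allele-specific terminal base)
#' @param table a \code{\link{RuleTable}}; default the packaged counts
#' @return a \code{\link{RuleDecision}}
#' @examples
#' designRule("T/A", "AGCA")  # site 3, G -> A, class CA
#' @export
designRule <- function(snpType, context, table = defaultRuleTables()) {
  .checkSnpType(snpType)
  .checkContext(context)
  grp <- compressType(snpType)
  siteSel <- selectSite(grp, table)
  orig <- .baseFrom3(context, siteSel$site)
  subSel <- selectSubstitution(siteSel$site, orig, table)
  new("RuleDecision", snpType = snpType, compressedType = grp,
      chosenSite = siteSel$site, originalBase = orig,
      substitutedBase = subSel$substituted, mismatchClass = subSel$class,
      sitePercent = siteSel$percent, classPercent = subSel$percent)
}

#' Audit an annotated primer table for conformance with the design rule
#'
#' For each annotated primer row, checks whether the annotated mismatch site
#' equals the site the rule selects for that SNP type, and -- when the
#' forward sequence is available -- whether the annotated mismatch class is
#' reachable (the primer base at the annotated site is one of the class's
#' two bases) and optimal (it equals the class the substitution rule selects
#' for the inferred original base at that site). Rows that cannot be parsed
#' are reported with an error message rather than aborting the audit.
#'
#' @param rows data.frame with columns \code{snp_type}, \code{mismatch_site}
#'   and \code{mismatch_class}; optional \code{primer_name} and
#'   \code{forward}
#' @param table a \code{\link{RuleTable}}; default the packaged counts
#' @return list with \code{rows} (per-row report) and \code{summary}
#'   (conformance counts)
#' @examples
#' audit <- auditPrimerTable(rapeseedPrimerTable())
#' audit$summary
#' @export
auditPrimerTable <- function(rows, table = defaultRuleTables()) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  rep <- data.frame(
    primer_name = if ("primer_name" %in% names(rows))
      as.character(rows$primer_name) else sprintf("row%02d", seq_len(n)),
    snp_type = as.character(rows$snp_type),
    annotated_site = NA_integer_, rule_site = NA_integer_,
    site_conformant = NA, class_reachable = NA, class_optimal = NA,
    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      ty <- as.character(rows$snp_type[i]); .checkSnpType(ty)
      site <- as.integer(rows$mismatch_site[i])
      if (!site %in% 2:4) .err("invalidSite", "annotated site must be 2-4")
      cls <- canonicalMismatchClass(as.character(rows$mismatch_class[i]))
      rule <- selectSite(compressType(ty), table)
      rep$annotated_site[i] <- site
      rep$rule_site[i] <- rule$site
      rep$site_conformant[i] <- site == rule$site
      if ("forward" %in% names(rows) && nzchar(rows$forward[i])) {
        fwd <- toupper(as.character(rows$forward[i]))
        .checkSeq(fwd, "forward primer")
        pb <- .baseFrom3(fwd, site)
        letters2 <- strsplit(cls, "", fixed = TRUE)[[1L]]
        rep$class_reachable[i] <- pb %in% letters2
        if (rep$class_reachable[i]) {
          tmpl <- setdiff(letters2, pb)
          tmpl <- if (length(tmpl)) tmpl else pb  # homo-pair class
          orig <- complementBase(tmpl[1L])
          rep$class_optimal[i] <-
            selectSubstitution(site, orig, table)$class == cls
        } else rep$class_optimal[i] <- FALSE
      }
      NULL
    }, ASPrimerError = function(e) conditionMessage(e))
    if (!is.null(res)) rep$error[i] <- res
  }
  ok <- !is.na(rep$site_conformant)
  list(rows = rep,
       summary = list(
         n = n,
         parsed = sum(ok),
         site_conformant = sum(rep$site_conformant, na.rm = TRUE),
         class_reachable = sum(rep$class_reachable, na.rm = TRUE),
         class_optimal = sum(rep$class_optimal, na.rm = TRUE),
         errors = sum(!is.na(rep$error))))
}

#' The packaged annotated rapeseed primer fixture
#'
#' Twenty allele-specific primer pairs designed with the rule tables for
#' SNPs between two rapeseed lines, with their annotated SNP type, mismatch
#' site and mismatch class -- the standard input for
#' \code{\link{auditPrimerTable}}.
#'
#' @return data.frame of 20 annotated primer pairs
#' @export
rapeseedPrimerTable <- function() {
  path <- system.file("extdata", "table5_rapeseed_primers.tsv",
                      package = "ASPrimer", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
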