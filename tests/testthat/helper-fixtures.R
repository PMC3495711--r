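## Shared fixture builders. Everything is generated in code; the only files
## used are the package's own extdata tables.

## expand a (site x key) count matrix pair into one outcome record per
## tested primer; the dimension not under test gets a fixed valid filler
expandSiteGroupCounts <- function(num, den) {
  rep1 <- c(TRANSITION = "A/G", AC_GT = "A/C", AT_TA = "A/T", CG_GC = "C/G")
  rows <- list()
  for (s in rownames(num)) for (g in colnames(num)) {
    n <- den[s, g]; k <- num[s, g]
    if (n == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_type = rep1[[g]], mismatch_site = as.integer(s),
      mismatch_class = "AA",
      polymorphic = rep(c(1L, 0L), c(k, n - k)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

expandSiteClassCounts <- function(num, den) {
  rows <- list()
  for (s in rownames(num)) for (cl in colnames(num)) {
    n <- den[s, cl]; k <- num[s, cl]
    if (n == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      snp_type = "A/G", mismatch_site = as.integer(s),
      mismatch_class = cl,
      polymorphic = rep(c(1L, 0L), c(k, n - k)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## published per-type genome SNP counts, as a named vector
publishedSnpCounts <- function() {
  tab <- read.delim(system.file("extdata", "table1_snp_counts.tsv",
                                package = "ASPrimer"))
  stats::setNames(tab$count, tab$snp_type)
}

## a small simulated locus + panel sized so every SNP has room for design
toyLocus <- function(seed = 101, len = 20000, nSnps = 12) {
  ref <- simulateReference(len, seed = seed)
  panel <- simulateSnpPanel(ref, nSnps = nSnps, minSpacing = 400,
                            buffer = 700, seed = seed + 1L)
  list(ref = ref, panel = panel)
}
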