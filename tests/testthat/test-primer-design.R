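rt <- defaultRuleTables()

test_that("forward primer has the one-vs-two mismatch geometry on a hand-built locus", {
  ## A/T SNP at position 40; wide Tm window so the minimum length is taken
  set.seed(5)
  left <- paste(sample(c("A", "C", "G", "T"), 39, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  refSeq <- paste0(left, "A", right)
  snp <- list(contig = "chr1", position = 40L, allele_line1 = "A",
              allele_line2 = "T")
  cfg <- designConfig(tmMin = 0, tmMax = 100, ampMin = 100, ampMax = 600)
  ctx <- paste0(substr(refSeq, 37, 39), "T")
  dec <- designRule("A/T", ctx, rt)
  fwd <- buildAsForward(snp, refSeq, dec, cfg, targetBase = "T")

  expect_equal(nchar(fwd$seq), cfg@primerLenMin)  # shortest satisfying length
  L <- nchar(fwd$seq)
  targetTemplate <- paste0(substr(refSeq, 40 - L + 1, 39), "T")
  nonTargetTemplate <- substr(refSeq, 40 - L + 1, 40)
  expect_identical(differencePositions(fwd$seq, targetTemplate),
                   dec@chosenSite)
  expect_identical(differencePositions(fwd$seq, nonTargetTemplate),
                   sort(c(1L, dec@chosenSite)))
  ## terminal base is the target allele; substituted base sits at the site
  expect_identical(substr(fwd$seq, L, L), "T")
  expect_identical(substr(fwd$seq, L - dec@chosenSite + 1L,
                          L - dec@chosenSite + 1L), dec@substitutedBase)
})

test_that("insufficient 5' flank is a structured error", {
  snp <- list(contig = "c", position = 5L, allele_line1 = "A",
              allele_line2 = "G")
  dec <- designRule("A/G", "AAAG", rt)
  expect_error(buildAsForward(snp, strrep("A", 100), dec, designConfig()),
               class = "insufficientFlank")
})

test_that("reverse primer scan respects amplicon window, Tm pairing and determinism", {
  loc <- toyLocus(seed = 31, len = 5000, nSnps = 3)
  refSeq <- as.character(loc$ref[[1]])
  snp <- loc$panel[1, ]
  p <- designPair(snp, loc$ref, table = rt)
  expect_identical(p@status, "designed")
  cfg <- designConfig()
  expect_true(p@ampliconLength >= cfg@ampMin && p@ampliconLength <= cfg@ampMax)
  expect_true(abs(p@forwardTm - p@reverseTm) <= cfg@tmDiffMax)
  expect_true(all(c(p@forwardTm, p@reverseTm) >= cfg@tmMin))
  expect_true(all(c(p@forwardTm, p@reverseTm) <= cfg@tmMax))
  ## reverse primer is the reverse complement of the amplicon's 3' window
  win <- substr(refSeq, p@ampliconEnd - nchar(p@reverseSeq) + 1L,
                p@ampliconEnd)
  expect_identical(p@reverseSeq, revComp(win))
  ## deterministic: identical input, byte-identical output
  p2 <- designPair(snp, loc$ref, table = rt)
  expect_identical(primerTable(p), primerTable(p2))

  ## no downstream room -> structured failure
  shortRef <- Biostrings::DNAStringSet(substr(refSeq, 1, snp$position + 50))
  names(shortRef) <- snp$contig
  pf <- designPair(snp, shortRef, table = rt)
  expect_identical(pf@status, "failed")
  expect_identical(pf@reason, "amplicon_unsatisfiable")
})

test_that("every designed pair in a batch satisfies the published primer geometry", {
  loc <- toyLocus(seed = 61, len = 30000, nSnps = 20)
  pairs <- designPrimers(loc$panel, loc$ref, table = rt)
  refSeq <- as.character(loc$ref[[1]])
  designed <- Filter(function(p) p@status == "designed", pairs)
  expect_gt(length(designed), 10)
  for (p in designed) {
    i <- match(p@position, loc$panel$position)
    L <- nchar(p@forwardSeq)
    tgt <- paste0(substr(refSeq, p@position - L + 1, p@position - 1),
                  loc$panel$allele_line2[i])
    non <- substr(refSeq, p@position - L + 1, p@position)
    expect_identical(differencePositions(p@forwardSeq, tgt),
                     p@decision@chosenSite)
    expect_identical(differencePositions(p@forwardSeq, non),
                     sort(c(1L, p@decision@chosenSite)))
    expect_true(p@decision@chosenSite %in% 2:4)
    ## the chosen site follows the rule table for the compressed group
    expect_equal(p@decision@chosenSite,
                 selectSite(compressType(p@snpType), rt)$site)
  }
})

test_that("batch design isolates per-SNP failures as rows", {
  loc <- toyLocus(seed = 91, len = 15000, nSnps = 8)
  panel <- loc$panel
  panel$position[3] <- 6L  # no flank
  panel$allele_line1[3] <- as.character(
    Biostrings::subseq(loc$ref[[1]], 6, 6))
  pairs <- designPrimers(panel, loc$ref, table = rt)
  tab <- primerTable(pairs)
  expect_equal(nrow(tab), 8L)
  expect_identical(tab$status[3], "failed")
  expect_identical(tab$reason[3], "flank")
  expect_true(all(tab$status[-3] == "designed"))
})

test_that("uniqueness screen counts 3' k-mer occurrences on both strands", {
  base <- simulateReference(3000, seed = 77)
  primer <- substr(as.character(base[[1]]), 1001, 1024)
  expect_true(screenUniqueness(primer, base)$pass)
  kmer <- substr(primer, nchar(primer) - 14L, nchar(primer))
  dup <- Biostrings::DNAStringSet(paste0(as.character(base[[1]]), "TTTT", kmer))
  sc <- screenUniqueness(primer, dup)
  expect_false(sc$pass)
  expect_equal(sc$count, 2L)
  ## reverse-complement occurrences count too
  dupRC <- Biostrings::DNAStringSet(
    paste0(as.character(base[[1]]), "TTTT", revComp(kmer)))
  expect_false(screenUniqueness(primer, dupRC)$pass)
  expect_error(screenUniqueness("ACGTACGT", base, designConfig()),
               class = "invalidConfig")
})

test_that("allele and strand modes mirror the design correctly", {
  loc <- toyLocus(seed = 121, len = 20000, nSnps = 6)
  snp <- loc$panel[2, ]
  ## targeting line 1 reverses the SNP type and the terminal base
  p1 <- designPair(snp, loc$ref, designConfig(targetAllele = "line1"),
                   rt)
  expect_identical(p1@snpType,
                   paste0(snp$allele_line2, "/", snp$allele_line1))
  if (p1@status == "designed")
    expect_identical(substr(p1@forwardSeq, nchar(p1@forwardSeq),
                            nchar(p1@forwardSeq)), snp$allele_line1)
  ## minus strand: design on the mirrored locus, coordinates mapped back
  pm <- designPair(snp, loc$ref, designConfig(strand = "minus"), rt)
  if (pm@status == "designed") {
    refLen <- nchar(as.character(loc$ref[[1]]))
    expect_true(pm@ampliconStart >= 0 && pm@ampliconEnd <= refLen)
    ## forward primer terminal base is the complement of the line-2 allele
    expect_identical(substr(pm@forwardSeq, nchar(pm@forwardSeq),
                            nchar(pm@forwardSeq)),
                     complementBase(snp$allele_line2))
  }
})
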