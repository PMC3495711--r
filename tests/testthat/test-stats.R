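test_that("snp spectrum conserves totals and classifies changes", {
  s <- snpSpectrum(c("A/G", "A/G", "T/A"))
  expect_equal(s$transitions, 2)
  expect_equal(s$transversions, 1)
  expect_equal(s$total, 3)

  one <- snpSpectrum("A/T")
  expect_equal(one$transversionPercent, 100.0)

  empty <- snpSpectrum(character(0))
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$transitionPercent))

  ## data.frame input with raw alleles
  df <- data.frame(allele_line1 = c("G", "C"), allele_line2 = c("A", "G"))
  s2 <- snpSpectrum(df)
  expect_equal(s2$perType$count[s2$perType$snp_type == "G/A"], 1)
  expect_equal(s2$perType$count[s2$perType$snp_type == "C/G"], 1)

  ## conservation under random input
  set.seed(13)
  types <- sample(SNP_TYPES, 500, TRUE)
  s3 <- snpSpectrum(types)
  expect_equal(s3$transitions + s3$transversions, 500)
})

test_that("candidate filtering applies biallelic, depth and uniqueness rules", {
  cands <- data.frame(
    contig = "c", position = 1:4,
    alleles_observed = c("A,C,T", "A,G", "A,G", "C,T"),
    read_depth = c(20, 7, 9, 8),
    maps_uniquely = c(TRUE, TRUE, TRUE, FALSE))
  f <- filterSnpCandidates(cands)
  expect_equal(f$tally[["retained"]], 1L)
  expect_equal(f$retained$position, 3L)
  expect_equal(f$tally[["not_biallelic"]], 1L)
  expect_equal(f$tally[["low_depth"]], 1L)
  expect_equal(f$tally[["non_unique"]], 1L)

  ## depth exactly at the threshold is retained
  atThreshold <- data.frame(contig = "c", position = 9,
                            alleles_observed = "A,G", read_depth = 8,
                            maps_uniquely = TRUE)
  expect_equal(filterSnpCandidates(atThreshold)$tally[["retained"]], 1L)
  expect_equal(filterSnpCandidates(atThreshold,
                                   minDepth = 9)$tally[["low_depth"]], 1L)
})

test_that("proportions round half-up and the Wilson interval matches the closed form", {
  expect_equal(proportionWithCI(37, 79)$percent, 46.8)
  expect_equal(proportionWithCI(0, 10)$percent, 0.0)
  expect_lte(proportionWithCI(0, 10)$ciLow, 1e-9)
  expect_error(proportionWithCI(1, 0), class = "invalidInput")
  expect_error(proportionWithCI(5, 4), class = "invalidInput")

  ## closed-form Wilson check, independent of prop.test
  wilson <- function(k, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2); p <- k / n
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    100 * c(ctr - hw, ctr + hw)
  }
  for (kn in list(c(37, 79), c(158, 193), c(1, 50), c(490, 1686))) {
    got <- proportionWithCI(kn[1], kn[2])
    expect_equal(c(got$ciLow, got$ciHigh), wilson(kn[1], kn[2]),
                 tolerance = 1e-9)
  }
  ## half-up rounding at the .x5 boundary
  expect_equal(roundHalfUp(26.45, 1), 26.5)
  expect_equal(roundHalfUp(26.35, 1), 26.4)
})

test_that("polymorphism summary is order-invariant and internally consistent", {
  set.seed(99)
  out <- data.frame(
    snp_type = sample(SNP_TYPES, 300, TRUE),
    mismatch_site = sample(2:4, 300, TRUE),
    mismatch_class = sample(MISMATCH_CLASSES, 300, TRUE),
    polymorphic = rbinom(300, 1, 0.3))
  s1 <- polymorphismSummary(out)
  s2 <- polymorphismSummary(out[sample(300), ])
  for (part in c("siteGroup", "siteClass", "siteMargins", "groupMargins",
                 "overall"))
    expect_equal(s1[[part]], s2[[part]])
  ## margins equal cell sums for derived tables
  rt <- s1$ruleTable
  expect_equal(unname(rt@siteMarginNum), unname(rowSums(rt@sgNum)))
  expect_equal(unname(rt@groupMarginDen), unname(colSums(rt@sgDen)))
  expect_equal(rt@grandDen, 300)
  expect_equal(rt@grandNum, sum(out$polymorphic))
})
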