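test_that("reference simulation is seed-reproducible with the requested GC", {
  r1 <- simulateReference(1000, 0.5, seed = 1)
  r2 <- simulateReference(1000, 0.5, seed = 1)
  expect_identical(as.character(r1), as.character(r2))
  expect_false(identical(as.character(simulateReference(1000, 0.5, seed = 2)),
                         as.character(r1)))

  big <- simulateReference(100000, 0.7, seed = 2)
  expect_equal(gcContent(as.character(big[[1]])), 0.7, tolerance = 0.02 / 0.7)

  expect_error(simulateReference(0, seed = 1), class = "invalidInput")
  expect_error(simulateReference(100, gc = 1, seed = 1),
               class = "invalidInput")
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulateReference(500, seed = 9))
  expect_identical(runif(1), before)
})

test_that("SNP panels anchor line-1 to the reference and respect spacing", {
  ref <- simulateReference(50000, seed = 5)
  refSeq <- as.character(ref[[1]])
  panel <- simulateSnpPanel(ref, nSnps = 100, minSpacing = 200, seed = 6)
  expect_equal(nrow(panel), 100L)
  expect_true(all(diff(panel$position) >= 200))
  expect_identical(panel$allele_line1,
                   substring(refSeq, panel$position, panel$position))
  expect_true(all(panel$allele_line1 != panel$allele_line2))
  expect_true(all(panel$snp_type %in% SNP_TYPES))
  ## same seed, same panel
  expect_identical(panel, simulateSnpPanel(ref, nSnps = 100,
                                           minSpacing = 200, seed = 6))
  expect_error(simulateSnpPanel(ref, nSnps = 100, minSpacing = 5000,
                                seed = 1),
               class = "invalidInput")
})

test_that("the default panel spectrum reproduces the genome transition share", {
  ref <- simulateReference(3000000, seed = 21)
  panel <- simulateSnpPanel(ref, nSnps = 10000, minSpacing = 100, seed = 22)
  s <- snpSpectrum(panel)
  expect_equal(s$transitionPercent, 56.7, tolerance = 2 / 56.7)
})

test_that("outcome simulation draws Bernoulli at the per-cell rates", {
  dec <- data.frame(snp_type = "T/A", mismatch_site = 3,
                    mismatch_class = "CA")
  dec <- dec[rep(1, 1000), ]
  out <- simulateOutcomes(dec, seed = 33)
  expect_equal(nrow(out), 1000L)
  expect_equal(mean(out$polymorphic), 0.468, tolerance = 0.04 / 0.468)
  expect_identical(out$polymorphic,
                   simulateOutcomes(dec, seed = 33)$polymorphic)

  rates <- defaultOutcomeRates()
  rates["3", "CA"] <- 1
  expect_true(all(simulateOutcomes(dec, rates, seed = 34)$polymorphic == 1))

  rates["3", "CA"] <- NA
  expect_error(simulateOutcomes(dec, rates, seed = 35),
               class = "incompleteTable")
})

test_that("panel VCF output round-trips through the VCF reader", {
  ref <- simulateReference(20000, seed = 41, name = "chrSim")
  panel <- simulateSnpPanel(ref, nSnps = 12, minSpacing = 300, seed = 42)
  vcf <- tempfile(fileext = ".vcf")
  writeSnpVcf(panel, vcf, ref)
  got <- readSnps(vcf, ref)
  expect_equal(sum(got$skipped), 0L)
  expect_equal(got$snps$position, panel$position)
  expect_identical(got$snps$allele_line1, panel$allele_line1)
  expect_identical(got$snps$allele_line2, panel$allele_line2)
  expect_identical(got$snps$snp_type, panel$snp_type)
})
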