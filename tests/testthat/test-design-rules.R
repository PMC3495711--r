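rt <- defaultRuleTables()

test_that("candidate enumeration yields 9 true mismatches at sites 2-4", {
  ## worked case: terminal A, site2 G, site3 C, site4 T (5'->3' "TCGA")
  cand <- enumerateCandidates("TCGA")
  expect_equal(nrow(cand), 9L)
  at3 <- cand[cand$site == 3, ]
  expect_identical(at3$original[1], "C")
  expect_identical(unique(at3$template), "G")
  expect_setequal(at3$class, c("GA", "GG", "TG"))
  ## original G at site 3 reaches exactly CC, CA, TC (= CT)
  at3g <- enumerateCandidates("AGTA")
  at3g <- at3g[at3g$site == 3, ]
  expect_setequal(at3g$class, c("CC", "CA", "TC"))
  expect_error(enumerateCandidates("ACG"), class = "contextTooShort")
})

test_that("enumeration is exhaustive: all 256 contexts give 9 distinct non-complementary candidates", {
  bases <- c("A", "C", "G", "T")
  for (ctx in apply(expand.grid(bases, bases, bases, bases), 1, paste,
                    collapse = "")) {
    cand <- enumerateCandidates(ctx)
    expect_equal(nrow(cand), 9L)
    expect_equal(sort(unique(cand$site)), 2:4)
    expect_false(any(duplicated(cand[, c("site", "substituted")])))
    expect_true(all(cand$substituted != cand$original))
    expect_true(all(cand$class %in% MISMATCH_CLASSES))
    ## three reachable classes per site are distinct
    for (s in 2:4)
      expect_equal(length(unique(cand$class[cand$site == s])), 3L)
  }
})

test_that("site selection takes the argmax of the group column", {
  expect_equal(selectSite("AT_TA", rt), list(site = 3L, percent = 45.9))
  expect_equal(selectSite("CG_GC", rt), list(site = 2L, percent = 43.3))
  expect_equal(selectSite("AC_GT", rt), list(site = 3L, percent = 37.4))
  expect_equal(selectSite("TRANSITION", rt), list(site = 3L, percent = 30.7))
  ## ordered types are compressed first
  expect_equal(selectSite("T/A", rt)$site, 3L)
  ## ties break toward the smaller site
  sg <- matrix(10, 3, 4, dimnames = list(c("2", "3", "4"), COMPRESSED_GROUPS))
  flat <- ruleTable(sg, sg * 2, matrix(1, 3, 8,
           dimnames = list(c("2", "3", "4"), MISMATCH_CLASSES)),
           matrix(2, 3, 8, dimnames = list(c("2", "3", "4"),
                                           MISMATCH_CLASSES)))
  expect_equal(selectSite("AT_TA", flat)$site, 2L)
})

test_that("substitution selection takes the class argmax among the 3 reachable", {
  expect_equal(selectSubstitution(3, "G", rt),
               list(substituted = "A", class = "CA", percent = 46.8))
  ## original T at site 3: reachable AA 30.6, CA 46.8, GA 28.3
  expect_equal(selectSubstitution(3, "T", rt),
               list(substituted = "C", class = "CA", percent = 46.8))
  ## original A at site 2: reachable TC 26.2, TG 26.4, TT 25.6
  expect_equal(selectSubstitution(2, "A", rt),
               list(substituted = "G", class = "TG", percent = 26.4))
  expect_error(selectSubstitution(5, "A", rt), class = "invalidSite")
})

test_that("the composed design rule is deterministic and records both percentages", {
  d <- designRule("T/A", "AGCA", rt)  # G at site 3
  expect_s4_class(d, "RuleDecision")
  expect_equal(d@chosenSite, 3L)
  expect_identical(d@originalBase, "G")
  expect_identical(d@substitutedBase, "A")
  expect_identical(d@mismatchClass, "CA")
  expect_equal(d@sitePercent, 45.9)
  expect_equal(d@classPercent, 46.8)

  ## C/G SNP with A at site 2 -> site 2, A>G, class TG
  d2 <- designRule("C/G", "TCAG", rt)
  expect_equal(d2@chosenSite, 2L)
  expect_identical(d2@substitutedBase, "G")
  expect_identical(d2@mismatchClass, "TG")

  ## A/G SNP with C at site 3 -> reachable GA 28.3, GG 30.4, TG 38.6
  d3 <- designRule("A/G", "GCTG", rt)
  expect_equal(d3@chosenSite, 3L)
  expect_identical(d3@mismatchClass, "TG")

  ## purity: identical calls give identical decisions
  expect_identical(designRule("T/A", "AGCA", rt), designRule("T/A", "AGCA", rt))
})

test_that("rule derivation from outcome records reproduces cell counts", {
  out <- data.frame(snp_type = c("T/A", "T/A", "C/G"),
                    mismatch_site = c(3, 3, 2),
                    mismatch_class = c("CA", "CA", "GT"),
                    polymorphic = c(1, 0, 1))
  d <- deriveRuleTables(out)
  expect_equal(d@sgNum["3", "AT_TA"], 1)
  expect_equal(d@sgDen["3", "AT_TA"], 2)
  expect_equal(d@scNum["2", "TG"], 1)  # GT normalized to TG
  expect_equal(d@grandNum, 2)
  expect_equal(d@grandDen, 3)
  ## single polymorphic record -> 100.0% cell
  one <- deriveRuleTables(data.frame(snp_type = "T/A", mismatch_site = 3,
                                     mismatch_class = "CA", polymorphic = 1))
  expect_equal(siteClassPercent(one)["3", "CA"], 100.0)
})

test_that("the packaged primer-table audit flags fabricated non-conformant rows", {
  aud <- auditPrimerTable(rapeseedPrimerTable(), rt)
  expect_equal(aud$summary$n, 20L)
  expect_equal(aud$summary$site_conformant, 20L)
  expect_equal(aud$summary$class_optimal, 20L)

  bad <- data.frame(snp_type = c("T/A", "X/Y"), mismatch_site = c(2, 3),
                    mismatch_class = c("CA", "CA"))
  audBad <- auditPrimerTable(bad, rt)
  expect_false(audBad$rows$site_conformant[1])  # T/A rule site is 3, not 2
  expect_equal(audBad$summary$errors, 1L)       # unparseable row reported
  expect_equal(audBad$summary$site_conformant, 0L)
})
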