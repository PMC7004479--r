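test_that("within-fraction proportions are MSI over total MSI", {
  df <- rbind(psmFrame(accession = "A", peptide = c("p1", "p2"),
                       intensity = c(60, 100), n = 2),
              psmFrame(accession = "B", peptide = "p3", intensity = 20))
  wft <- withinFractionAbundance(PsmTable(df))
  expect_equal(wft$msi[wft$accession == "A"], 80)
  expect_equal(wft$proportion[wft$accession == "A"], 0.8)
  expect_equal(wft$proportion[wft$accession == "B"], 0.2)

  solo <- withinFractionAbundance(PsmTable(psmFrame()))
  expect_equal(solo$proportion, 1)

  zero <- PsmTable(psmFrame(n = 2, peptide = c("a", "b"), intensity = 0))
  expect_error(withinFractionAbundance(zero), class = "dcx_empty_fraction")
})

test_that("duplicate accession entries pool their peptides when merging", {
  df <- rbind(psmFrame(accession = "P18965", protein_name = "entry one",
                       peptide = c("p1", "p2"), intensity = c(10, 20),
                       n = 2),
              psmFrame(accession = "P18965", protein_name = "entry two",
                       peptide = "p3", intensity = 60),
              psmFrame(accession = "B", peptide = "p4", intensity = 30))
  merged <- withinFractionAbundance(PsmTable(df), mergeDuplicates = TRUE)
  expect_identical(nrow(merged), 2L)
  expect_equal(merged$msi[merged$accession == "P18965"], 30)  # mean(10,20,60)

  kept <- withinFractionAbundance(PsmTable(df), mergeDuplicates = FALSE)
  expect_identical(nrow(kept), 3L)
})

test_that("simulator fractions reproduce hand-computed mean/total ratios", {
  tr <- venomTruth(seed = 17)
  psms <- simulatePsms(tr)
  filt <- suppressWarnings(filterPsms(psms))
  wft <- withinFractionAbundance(filt$psms)
  p <- psmData(filt$psms)
  f1 <- p[p$fraction_id == "F1", ]
  oracle <- tapply(f1$intensity, f1$accession, mean)
  oracle <- oracle / sum(oracle)
  got <- wft[wft$fraction_id == "F1", ]
  expect_equal(got$proportion[match(names(oracle), got$accession)],
               as.numeric(oracle), tolerance = 1e-12)
})

test_that("whole-venom abundance is share times within-fraction proportion", {
  shareTable <- FractionShareTable(c(F4 = 0.0983, F9 = 0.9017))
  wft <- data.frame(
    fraction_id = c("F4", "F4", "F4", "F9"),
    accession = c("A8Y7N4", "A8Y7N9", "A8Y7P6", "B3RFI7"),
    protein_name = c("KSPI C1", "KSPI C6", "KSPI B6", "Basic PLA2"),
    species = "D. siamensis", n_psms = 1L, msi = 1,
    proportion = c(0.74975, 0.05493, 0.19532, 1),
    stringsAsFactors = FALSE)
  ab <- wholeVenomAbundance(shareTable, wft, venomId = "demo")
  p <- proteinAbundance(ab)
  f4 <- p$abundance[p$fraction_id == "F4"]
  expect_equal(round(f4, 2), c(7.37, 0.54, 1.92))
  expect_equal(sum(p$abundance) + unidentifiedShare(ab), 100,
               tolerance = 1e-9)
})

test_that("unidentified fractions contribute their full share to the bucket", {
  shareTable <- FractionShareTable(c(F6 = 0.0747, F7 = 0.9253))
  wft <- data.frame(fraction_id = "F7", accession = "X",
                    protein_name = "x", species = "s", n_psms = 1L,
                    msi = 1, proportion = 1, stringsAsFactors = FALSE)
  ab <- wholeVenomAbundance(shareTable, wft, unidentified = "F6")
  expect_equal(unidentifiedShare(ab), 7.47)

  # a silent fraction (share, no PSMs, not declared) is warned into the bucket
  expect_warning(
    ab2 <- wholeVenomAbundance(shareTable, wft),
    class = "dcx_unassigned_fraction")
  expect_equal(unidentifiedShare(ab2), 7.47)

  # a fraction with PSMs but no share is an error
  orphan <- rbind(wft, within(wft, fraction_id <- "F9"))
  expect_error(wholeVenomAbundance(shareTable, orphan),
               class = "dcx_missing_share")
})

test_that("computed abundances conserve mass and ignore intensity scaling", {
  tr <- venomTruth(seed = 23)
  psms <- simulatePsms(tr)
  filt <- suppressWarnings(filterPsms(psms))
  sim <- simulateChromatogram(tr)
  st <- integrateFractions(correctBaseline(sim$chromatogram),
                           sim$boundaries)
  ab <- wholeVenomAbundance(st, withinFractionAbundance(filt$psms))
  expect_equal(sum(proteinAbundance(ab)$abundance) +
                 unidentifiedShare(ab), 100, tolerance = 1e-6)

  # multiply all intensities in one fraction by a constant
  p <- psmData(filt$psms)
  p$intensity[p$fraction_id == "F2"] <- 1000 * p$intensity[p$fraction_id == "F2"]
  ab2 <- wholeVenomAbundance(st, withinFractionAbundance(PsmTable(p)))
  expect_equal(proteinAbundance(ab2)$abundance,
               proteinAbundance(ab)$abundance, tolerance = 1e-12)
})

test_that("family aggregation reproduces the reference family totals", {
  ref <- referenceProteomes()
  th <- aggregateFamilies(ref$thailand)
  expect_equal(th$abundance[th$family == "KSPI"], 22.38, tolerance = 1e-9)
  indo <- aggregateFamilies(ref$indonesia)
  expect_equal(indo$abundance[indo$family == "snaclec"], 1.03,
               tolerance = 1e-9)

  # families absent from the venom aggregate to zero
  both <- aggregateFamilies(ref$thailand, all = TRUE)
  expect_equal(both$abundance[both$family == "LAAO"], 0)
  expect_equal(both$abundance[both$family == "DIS"], 0)

  # sorted by descending abundance
  expect_true(all(diff(th$abundance) <= 0))

  # totals equal the sum of member rows exactly (no double counting)
  p <- proteinAbundance(ref$thailand)
  expect_equal(sum(th$abundance), sum(p$abundance), tolerance = 1e-12)
})

test_that("non-redundant counts match the reference proteomes", {
  ref <- referenceProteomes()
  th <- countNonredundant(ref$thailand)
  expect_identical(th$proteins, 47L)
  expect_identical(th$families, 9L)
  expect_identical(
    th$perFamily$n_proteins[th$perFamily$family == "PLA2"], 6L)
  expect_identical(
    th$perFamily$n_proteins[th$perFamily$family == "SVSP"], 10L)

  indo <- countNonredundant(ref$indonesia)
  expect_identical(indo$proteins, 25L)
  expect_identical(indo$families, 9L)

  none <- countNonredundant(
    new("AbundanceTable",
        proteins = proteinAbundance(ref$thailand)[0, ],
        unidentifiedShare = 0, venomId = "empty"))
  expect_identical(none$proteins, 0L)
  expect_identical(none$families, 0L)
})

test_that("venom comparison flags unique families exactly", {
  ref <- referenceProteomes()
  cmp <- compareVenoms(ref$thailand, ref$indonesia)
  f <- comparisonTable(cmp)
  expect_setequal(f$family[f$status == "unique_to_a"],
                  c("KSPI", "svVEGF"))
  expect_setequal(f$family[f$status == "unique_to_b"], c("LAAO", "DIS"))

  self <- compareVenoms(ref$thailand, ref$thailand)
  sf <- comparisonTable(self)
  expect_true(all(sf$status == "shared"))
  expect_true(all(sf$delta == 0))

  # synthetic pair differing in exactly one family
  a <- AbundanceTable(data.frame(
    accession = c("P1", "P2"), protein_name = c("x", "y"),
    family = c("PLA2", "SVSP"), fraction_id = NA_character_,
    abundance = c(60, 40), stringsAsFactors = FALSE))
  b <- AbundanceTable(data.frame(
    accession = "P1", protein_name = "x", family = "PLA2",
    fraction_id = NA_character_, abundance = 100,
    stringsAsFactors = FALSE))
  d <- comparisonTable(compareVenoms(a, b))
  expect_identical(sum(d$status != "shared"), 1L)
  expect_identical(d$status[d$family == "SVSP"], "unique_to_a")
})
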