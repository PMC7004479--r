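test_that("one seed fully determines every simulated stage", {
  a <- venomTruth(seed = 4)
  b <- venomTruth(seed = 4)
  expect_identical(a@proteins, b@proteins)
  expect_identical(a@fractions, b@fractions)

  ca <- simulateChromatogram(a)
  cb <- simulateChromatogram(b)
  expect_identical(absorbance(ca$chromatogram), absorbance(cb$chromatogram))
  expect_identical(psmData(simulatePsms(a)), psmData(simulatePsms(b)))
  expect_identical(wells(simulateElisa(a)), wells(simulateElisa(b)))

  # a different seed changes the data
  expect_false(identical(absorbance(ca$chromatogram),
                         absorbance(simulateChromatogram(
                           venomTruth(seed = 5))$chromatogram)))
})

test_that("generated datasets satisfy every reader invariant", {
  dir <- tempfile()
  for (seed in 1:25) {
    tr <- venomTruth(seed = seed,
                     nUnidentified = seed %% 3L,
                     preset = "random")
    paths <- writeSyntheticExperiment(tr, dir)
    expect_s4_class(readChromatogram(paths[["trace"]]), "Chromatogram")
    expect_s4_class(readBoundaries(paths[["boundaries"]]),
                    "FractionBoundarySet")
    psms <- readPsmTable(paths[["psms"]])
    expect_s4_class(psms, "PsmTable")
    expect_gt(decoyCount(psms), 0L)
    expect_s4_class(readFamilyMap(paths[["family_map"]]), "FamilyMap")
    expect_s4_class(readElisaPlate(paths[["elisa"]]), "ElisaPlate")
  }
})

test_that("noiseless simulation recovers the truth exactly", {
  tr <- venomTruth(seed = 8, intensitySigma = 0,
                   scores = list(decoy_fraction = 0),
                   noise = list(chrom_sd = 0, drift_slope = 0,
                                drift_intercept = 0))
  # within-fraction proportions recovered exactly from intensities
  # (quantified directly: with no decoys the table is already clean)
  wft <- withinFractionAbundance(simulatePsms(tr))
  truth <- tr@proteins
  m <- merge(wft, truth, by = "accession")
  expect_equal(m$proportion, m$within_fraction, tolerance = 1e-12)

  # fraction shares recovered from the noiseless trace within 1%
  sim <- simulateChromatogram(tr)
  s <- shares(integrateFractions(sim$chromatogram, sim$boundaries))
  truth_s <- setNames(tr@fractions$share, tr@fractions$fraction_id)
  expect_equal(s[names(truth_s)], truth_s, tolerance = 0.01)
})

test_that("two noiseless peaks with 60/40 shares integrate back to 60/40", {
  tr <- venomTruth(seed = 12, nFractions = 2L, proteinsPerFamily = 1,
                   familyProportions = c(PLA2 = 0.6, SVSP = 0.4),
                   noise = list(chrom_sd = 0, drift_slope = 0,
                                drift_intercept = 0))
  sim <- simulateChromatogram(tr)
  s <- shares(integrateFractions(sim$chromatogram, sim$boundaries))
  expect_setequal(round(unname(s), 2), c(0.6, 0.4))
})

test_that("a zero decoy fraction yields an all-zero FDR curve", {
  tr <- venomTruth(seed = 14, scores = list(decoy_fraction = 0))
  psms <- simulatePsms(tr)
  expect_identical(decoyCount(psms), 0L)
  expect_warning(curve <- estimateFdrCurve(psms), class = "dcx_no_decoys")
  expect_true(all(curve$fdr == 0))
})

test_that("presets fix the family composition and fraction layout", {
  thai <- venomTruth(preset = "thai-like", seed = 1)
  expect_identical(nrow(thai@fractions), 13L)
  expect_true(all(thai@fractions$identified))
  comp <- truthComposition(thai)
  expect_equal(unname(comp["PLA2"]), 100 * 37.92 / 99.99, tolerance = 1e-6)

  indo <- venomTruth(preset = "indo-like", seed = 1)
  expect_identical(sum(!indo@fractions$identified), 2L)
  unid <- attr(truthComposition(indo), "unidentified_pct")
  expect_gt(unid, 8)
  expect_lt(unid, 18)
  # identified composition keeps the preset's proportions
  comp_i <- truthComposition(indo)
  expect_equal(unname(comp_i["PLA2"] / comp_i["SVSP"]), 48.37 / 22.41,
               tolerance = 1e-6)
})

test_that("the packaged reference transcription matches its source values", {
  ref <- referenceProteomes()
  th <- proteinAbundance(ref$thailand)
  expect_equal(th$abundance[th$accession == "P31100"], 21.27)
  indo <- proteinAbundance(ref$indonesia)
  expect_equal(indo$abundance[indo$accession == "Q7ZZM2"], 6.21)
  # one row per detected (accession, venom) pair: 47 + 25
  expect_identical(nrow(th) + nrow(indo), 47L + 25L)
  # every fixture accession is mapped
  expect_true(all(c(th$accession, indo$accession) %in%
                    names(familyAssignments(ref$familyMap))))
})

test_that("end-to-end family recovery stays within 2 percentage points", {
  maes <- vapply(1:5, familyRecoveryMae, numeric(1))
  expect_lt(mean(maes), 2)
})
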