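test_that("chromatogram reader enforces the trace invariants", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time_min,absorbance_mau", "0,0", "1,5", "2,0"), f)
  ch <- readChromatogram(f)
  expect_s4_class(ch, "Chromatogram")
  expect_length(ch, 3L)

  writeLines(c("time_min,absorbance_mau", "0,0", "1,5", "1,4"), f)
  expect_error(readChromatogram(f), class = "dcx_malformed_trace")

  writeLines(c("time_min,absorbance_mau", "0,0"), f)
  expect_error(readChromatogram(f), class = "dcx_malformed_trace")

  writeLines(c("wrong,cols", "0,0", "1,1"), f)
  expect_error(readChromatogram(f), class = "dcx_schema_error")
})

test_that("a simulated trace round-trips through write/read bit-identically", {
  tr <- venomTruth(seed = 3)
  ch <- simulateChromatogram(tr)$chromatogram
  f <- tempfile(fileext = ".csv")
  writeChromatogram(ch, f)
  back <- readChromatogram(f)
  expect_identical(elutionTime(back), elutionTime(ch))
  expect_identical(absorbance(back), absorbance(ch))
})

test_that("PSM reader validates records and reports offending rows", {
  f <- tempfile(fileext = ".tsv")
  writePsmTable(PsmTable(psmFrame(spi = 71, intensity = 100)), f)
  p <- readPsmTable(f)
  expect_length(p, 1L)
  expect_identical(psmData(p)$spi, 71)

  bad <- psmFrame(n = 2, peptide = c("A", "B"))
  bad$spi <- c(80, 150)
  err <- tryCatch(PsmTable(bad), error = identity)
  expect_s3_class(err, "dcx_malformed_record")
  expect_identical(err$rows, 2L)

  writeLines(c("fraction_id\taccession", "F1\tP1"), f)
  expect_error(readPsmTable(f), class = "dcx_schema_error")
})

test_that("simulator PSM tables survive the disk round trip", {
  tr <- venomTruth(seed = 5)
  psms <- simulatePsms(tr, targetPsms = 5000)
  f <- tempfile(fileext = ".tsv")
  writePsmTable(psms, f)
  back <- readPsmTable(f)
  expect_identical(length(back), length(psms))
  expect_identical(decoyCount(back), decoyCount(psms))
  expect_equal(psmData(back)$intensity, psmData(psms)$intensity)
})

test_that("decoy prefix convention is accepted as an alternative flag", {
  df <- rbind(psmFrame(accession = "P00001"),
              psmFrame(accession = "DECOY_P00001", peptide = "PEP2"))
  f <- tempfile(fileext = ".tsv")
  writePsmTable(PsmTable(df), f)
  # strip the explicit flag from the file
  lines <- readLines(f)
  lines <- sub("\t[01]$", "\t0", lines)
  lines[1] <- sub("is_decoy", "is_decoy", lines[1])
  writeLines(lines, f)
  p <- readPsmTable(f, decoyPrefix = "DECOY_")
  expect_identical(decoyCount(p), 1L)
})

test_that("family map reader enforces the controlled vocabulary", {
  ref <- referenceProteomes()
  expect_identical(unname(familyAssignments(ref$familyMap)["P31100"]),
                   "PLA2")
  f <- tempfile(fileext = ".tsv")
  writeFamilyMap(ref$familyMap, f)
  back <- readFamilyMap(f)
  expect_identical(familyAssignments(back),
                   familyAssignments(ref$familyMap))

  writeLines(c("accession\tfamily", "P1\tNOT_A_FAMILY"), f)
  expect_error(readFamilyMap(f), class = "dcx_vocabulary_error")

  expect_warning(fam <- lookupFamily(ref$familyMap, "UNKNOWN1"),
                 class = "dcx_unmapped_accession")
  expect_identical(fam, "OTHER")
})

test_that("ELISA reader rejects empty and blankless files", {
  f <- tempfile(fileext = ".csv")
  writeLines("fraction_id,antivenom,replicate,a492,is_blank,is_control", f)
  expect_error(readElisaPlate(f), class = "dcx_schema_error")

  writeLines(c("fraction_id,antivenom,replicate,a492,is_blank,is_control",
               "F1,AV,1,0.5,0,0"), f)
  expect_error(readElisaPlate(f), class = "dcx_no_blank")

  tr <- venomTruth(seed = 2)
  plate <- simulateElisa(tr)
  writeElisaPlate(plate, f)
  back <- readElisaPlate(f)
  expect_identical(length(back), length(plate))
  expect_equal(wells(back)$a492, wells(plate)$a492)
})

test_that("reference abundance tables round-trip losslessly", {
  ref <- referenceProteomes()
  f <- tempfile(fileext = ".tsv")
  writeAbundanceTable(ref$indonesia, f)
  back <- readAbundanceTable(f)
  expect_identical(venomId(back), venomId(ref$indonesia))
  expect_equal(unidentifiedShare(back),
               unidentifiedShare(ref$indonesia))
  expect_equal(proteinAbundance(back), proteinAbundance(ref$indonesia))
})

test_that("boundary tables round-trip and enforce ordering", {
  fb <- FractionBoundarySet(c("F2", "F1"), start = c(10, 0),
                            end = c(20, 10), collected = c(TRUE, FALSE))
  b <- boundaries(fb)
  expect_identical(b$fraction_id, c("F1", "F2"))  # sorted by start
  f <- tempfile(fileext = ".tsv")
  writeBoundaries(fb, f)
  expect_identical(boundaries(readBoundaries(f)), b)
  expect_error(FractionBoundarySet("F1", start = 5, end = 5),
               "end > start")
  expect_error(FractionBoundarySet(c("F1", "F2"), start = c(0, 5),
                                   end = c(10, 15)),
               "overlap")
})
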