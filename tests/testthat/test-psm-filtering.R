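test_that("the score cascade applies strict inequalities at every gate", {
  at_boundary <- PsmTable(rbind(
    psmFrame(accession = "A", protein_score = 20.01, peptide_score = 10.5,
             spi = 71),
    psmFrame(accession = "B", protein_score = 20, peptide_score = 30,
             spi = 90, peptide = "PEP2"),
    psmFrame(accession = "C", protein_score = 40, peptide_score = 10,
             spi = 90, peptide = "PEP3"),
    psmFrame(accession = "D", protein_score = 40, peptide_score = 30,
             spi = 70, peptide = "PEP4")))
  kept <- applyScoreFilters(at_boundary)
  expect_identical(psmData(kept)$accession, "A")

  empty <- applyScoreFilters(PsmTable(psmFrame()[0, ]))
  expect_length(empty, 0L)
})

test_that("the cascade is a subset operation, idempotent and order-independent", {
  set.seed(7)
  df <- psmFrame(n = 200, accession = sprintf("P%03d", 1:200))
  df$protein_score <- runif(200, 0, 60)
  df$peptide_score <- runif(200, 0, 40)
  df$spi <- runif(200, 0, 100)
  p <- PsmTable(df)
  once <- applyScoreFilters(p)
  twice <- applyScoreFilters(once)
  expect_identical(psmData(once), psmData(twice))
  expect_true(all(psmData(once)$accession %in% df$accession))

  shuffled <- PsmTable(df[sample.int(200), ])
  a <- psmData(applyScoreFilters(shuffled))
  expect_setequal(a$accession, psmData(once)$accession)
})

test_that("the FDR curve equals exhaustive brute-force enumeration", {
  set.seed(13)
  df <- psmFrame(n = 300, accession = sprintf("P%03d", 1:300))
  df$peptide_score <- c(rnorm(260, 30, 8), rnorm(40, 18, 6))
  df$is_decoy <- c(rep(FALSE, 260), rep(TRUE, 40))
  curve <- estimateFdrCurve(PsmTable(df))

  # independent oracle: explicit loops over all cutoffs, no vectorised
  # counting, running minimum computed by re-scanning lower cutoffs
  cutoffs <- sort(unique(df$peptide_score))
  raw <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    nd <- 0L; nt <- 0L
    for (j in seq_len(nrow(df))) {
      if (df$peptide_score[j] >= cutoffs[i]) {
        if (df$is_decoy[j]) nd <- nd + 1L else nt <- nt + 1L
      }
    }
    raw[i] <- nd / max(1L, nt)
  }
  smooth <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) smooth[i] <- min(raw[seq_len(i)])

  expect_equal(curve$cutoff, cutoffs)
  expect_equal(curve$fdr_raw, raw)
  expect_equal(curve$fdr, smooth)
  expect_true(all(diff(curve$fdr) <= 0))  # monotone non-increasing
})

test_that("degenerate decoy configurations are flagged", {
  no_decoys <- PsmTable(psmFrame(n = 5, peptide_score = 20 + 1:5,
                                 accession = sprintf("P%d", 1:5)))
  expect_warning(curve <- estimateFdrCurve(no_decoys),
                 class = "dcx_no_decoys")
  expect_true(all(curve$fdr == 0))
  expect_true(isTRUE(attr(curve, "no_decoys")))

  all_decoys <- PsmTable(psmFrame(n = 4, peptide_score = c(10, 20, 30, 40),
                                  accession = sprintf("D%d", 1:4),
                                  is_decoy = TRUE))
  curve2 <- estimateFdrCurve(all_decoys)
  expect_true(isTRUE(attr(curve2, "all_decoys")))
  # with no targets the ratio divides by max(1, 0): fdr = #decoys >= c
  expect_equal(curve2$fdr_raw, c(4, 3, 2, 1))
  expect_error(filterAtFdr(all_decoys), class = "dcx_fdr_unattainable")
})

test_that("filterAtFdr picks the lowest passing cutoff and drops decoys", {
  df <- rbind(psmFrame(n = 99, accession = sprintf("T%02d", 1:99),
                       peptide_score = 50),
              psmFrame(accession = "D1", peptide_score = 40,
                       is_decoy = TRUE, peptide = "PEPD"))
  res <- filterAtFdr(PsmTable(df))
  # 1 decoy / 99 targets at cutoff 40 is 1.01% > 1%; cutoff moves to 50
  expect_equal(res$cutoff, 50)
  expect_equal(res$achievedFdr, 0)
  expect_length(res$psms, 99L)
  expect_identical(decoyCount(res$psms), 0L)

  no_decoys <- PsmTable(psmFrame(n = 5, peptide_score = 20 + 1:5,
                                 accession = sprintf("P%d", 1:5)))
  expect_warning(res2 <- filterAtFdr(no_decoys), class = "dcx_no_decoys")
  expect_equal(res2$cutoff, 21)  # minimum observed score: everything passes
  expect_length(res2$psms, 5L)
})

test_that("realized FDP stays within twice the nominal bound on labelled simulations", {
  fdp <- vapply(1:5, realizedFdp, numeric(1))
  expect_true(all(fdp <= 0.02))
})

test_that("stage order cascade/FDR is configurable and reported", {
  tr <- venomTruth(seed = 21)
  psms <- simulatePsms(tr, targetPsms = 1000)
  a <- filterPsms(psms, order = "cascade_then_fdr")
  b <- filterPsms(psms, order = "fdr_then_cascade")
  expect_identical(a$report$stage, c("score_cascade", "fdr_control"))
  expect_identical(b$report$stage, c("fdr_control", "score_cascade"))
  expect_true(all(psmData(a$psms)$peptide_score >= a$cutoff))
  expect_identical(decoyCount(a$psms), 0L)
  expect_identical(decoyCount(b$psms), 0L)
})
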