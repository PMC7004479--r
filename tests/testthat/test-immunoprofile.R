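elisaWells <- function(values, fraction_id = "F1", antivenom = "AV",
                       blank = 0, is_control = FALSE) {
  rbind(
    data.frame(fraction_id = fraction_id, antivenom = antivenom,
               replicate = seq_along(values), a492 = values,
               is_blank = FALSE, is_control = is_control,
               stringsAsFactors = FALSE),
    data.frame(fraction_id = "blank", antivenom = antivenom,
               replicate = 1L, a492 = blank, is_blank = TRUE,
               is_control = FALSE, stringsAsFactors = FALSE))
}

test_that("plate summary blank-corrects and reports mean with SEM", {
  s <- summarizePlate(ElisaPlate(elisaWells(c(0.5, 0.6, 0.7))))
  cell <- s[s$fraction_id == "F1", ]
  expect_equal(cell$mean, 0.6)
  expect_equal(cell$sem, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_identical(cell$n, 3L)

  # replicates equal to the blank collapse to zero
  s2 <- summarizePlate(ElisaPlate(elisaWells(c(0.2, 0.2), blank = 0.2)))
  expect_equal(s2$mean[s2$fraction_id == "F1"], 0)

  expect_warning(
    s3 <- summarizePlate(ElisaPlate(elisaWells(0.5))),
    class = "dcx_single_replicate")
  expect_true(is.na(s3$sem[s3$fraction_id == "F1"]))
})

test_that("reactivity classification follows the two observed regimes", {
  expect_identical(classifyReactivity(c(0.05, 0.15, 0.6)),
                   c("low", "indeterminate", "reactive"))
  expect_identical(classifyReactivity(c(0.1, 0.2)),
                   c("indeterminate", "reactive"))
  expect_error(classifyReactivity(-0.01), class = "dcx_contract_violation")
})

test_that("relative immunoreactivity is comparator over reference percent", {
  mkProfile <- function(means) {
    data.frame(fraction_id = sprintf("F%d", seq_along(means)),
               antivenom = "AV", is_control = FALSE,
               n = 3L, mean = means, sem = 0.01,
               stringsAsFactors = FALSE)
  }
  same <- relativeImmunoreactivity(mkProfile(c(0.4, 0.8)),
                                   mkProfile(c(0.4, 0.8)))
  expect_true(all(same$relative_pct == 100))

  half <- relativeImmunoreactivity(mkProfile(0.5), mkProfile(0.25))
  expect_equal(half$relative_pct, 50)

  floored <- relativeImmunoreactivity(mkProfile(c(0.5, 0.005)),
                                      mkProfile(c(0.25, 0.9)))
  expect_true(floored$undefined[floored$fraction_id == "F2"])
  expect_true(is.na(floored$relative_pct[floored$fraction_id == "F2"]))
  expect_false(any(is.infinite(floored$relative_pct), na.rm = TRUE))

  expect_error(
    relativeImmunoreactivity(mkProfile(c(0.4, 0.8)), mkProfile(0.4)),
    class = "dcx_alignment_error")
})

test_that("control checks report pass/fail without gating", {
  ctrl <- function(values, id) {
    w <- elisaWells(values, fraction_id = id, is_control = TRUE)
    summarizePlate(ElisaPlate(w))
  }
  ok <- controlCheck(ctrl(c(0.03, 0.04, 0.05), "neg"), negative = "neg")
  expect_true(ok$pass)
  bad <- controlCheck(ctrl(c(0.7, 0.8, 0.9), "neg"), negative = "neg")
  expect_false(bad$pass)
  pos <- controlCheck(ctrl(c(0.7, 0.8, 0.9), "pos"), positive = "pos")
  expect_true(pos$pass)

  # simulator plate with an injected control failure is detected
  tr <- venomTruth(seed = 31)
  tr@elisa$antivenoms$DsMAV$control_affinity <- 0.9  # should be negative
  s <- summarizePlate(simulateElisa(tr))
  res <- controlCheck(s, negative = "control_venom")
  expect_false(res$pass[res$antivenom == "DsMAV"])
})

test_that("raising any replicate never demotes a cell's class", {
  rank <- c(low = 1L, indeterminate = 2L, reactive = 3L)
  set.seed(99)
  for (i in 1:20) {
    vals <- runif(3, 0, 0.4)
    blank <- runif(1, 0, 0.05)
    base <- summarizePlate(ElisaPlate(elisaWells(vals, blank = blank)))
    up <- vals
    j <- sample.int(3, 1)
    up[j] <- up[j] + runif(1, 0, 0.5)
    bumped <- summarizePlate(ElisaPlate(elisaWells(up, blank = blank)))
    c0 <- classifyReactivity(base$mean[base$fraction_id == "F1"])
    c1 <- classifyReactivity(bumped$mean[bumped$fraction_id == "F1"])
    expect_gte(rank[[c1]], rank[[c0]])
  }
})

test_that("SEM shrinks as one over the square root of replicate count", {
  # same empirical spread, different replicate counts
  v3 <- c(0.5, 0.6, 0.7)
  v12 <- rep(v3, 4)
  s3 <- summarizePlate(ElisaPlate(elisaWells(v3)))
  s12 <- summarizePlate(ElisaPlate(elisaWells(v12)))
  expect_equal(s12$sem[s12$fraction_id == "F1"] /
                 s3$sem[s3$fraction_id == "F1"],
               sd(v12) / sd(v3) * sqrt(3 / 12), tolerance = 1e-9)
})

test_that("simulated plates recover the true response means", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    tr <- venomTruth(seed = seed)
    el <- tr@elisa
    s <- summarizePlate(simulateElisa(tr))
    s <- s[!s$is_control, ]
    for (av in names(el$antivenoms)) {
      aff <- el$antivenoms[[av]]$affinity
      truth <- el$amax * aff / (aff + el$k)
      cells <- s[s$antivenom == av, ]
      truth <- truth[cells$fraction_id]
      # tolerance: cell SEM plus the shared blank-mean uncertainty
      tol <- 3 * sqrt(cells$sem^2 + el$sd^2 / el$reps)
      hits <- hits + sum(abs(cells$mean - truth) <= pmax(tol, 0.02))
      total <- total + nrow(cells)
    }
  }
  expect_gte(hits / total, 0.95)
})
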