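# Shared builders for in-code fixtures.

# One-liner PSM frame with sensible defaults; override any field.
psmFrame <- function(n = 1L, fraction_id = "F1", accession = "P00001",
                     protein_name = "protein", species = "D. siamensis",
                     peptide = sprintf("PEP%d", seq_len(n)),
                     protein_score = 50, peptide_score = 30, spi = 80,
                     intensity = 100, is_decoy = FALSE) {
  data.frame(fraction_id = fraction_id, accession = accession,
             protein_name = protein_name, species = species,
             peptide = peptide, protein_score = protein_score,
             peptide_score = peptide_score, spi = spi,
             intensity = intensity, is_decoy = is_decoy,
             stringsAsFactors = FALSE)
}

# Sum-of-Gaussians trace sampled at dt minutes.
gaussTrace <- function(centers, sds, areas, tmax = 60, dt = 0.1,
                       baseline = 0) {
  t <- seq(0, tmax, by = dt)
  a <- rep(baseline, length(t))
  for (i in seq_along(centers))
    a <- a + areas[i] * dnorm(t, centers[i], sds[i])
  Chromatogram(time = t, absorbance = a)
}

# Closed-form Gaussian mass inside a window (the integration oracle).
gaussWindowArea <- function(center, sd, area, lo, hi) {
  area * (pnorm(hi, center, sd) - pnorm(lo, center, sd))
}

# End-to-end family estimate vs truth for one simulated venom; returns the
# mean absolute error in percentage points over the union of families.
familyRecoveryMae <- function(seed) {
  tr <- venomTruth(seed = seed)
  sim <- simulateChromatogram(tr)
  st <- integrateFractions(correctBaseline(sim$chromatogram),
                           sim$boundaries)
  # the cascade can remove every decoy in small simulations, which the
  # FDR estimator legitimately warns about
  filt <- suppressWarnings(filterPsms(simulatePsms(tr)))
  ab <- wholeVenomAbundance(st, withinFractionAbundance(filt$psms),
                            venomId = "sim")
  est <- suppressWarnings(
    aggregateFamilies(ab, fmap = truthFamilyMap(tr), all = TRUE))
  truth <- truthComposition(tr)
  m <- merge(est[, c("family", "abundance")],
             data.frame(family = names(truth), true = as.numeric(truth),
                        stringsAsFactors = FALSE),
             all = TRUE)
  m$abundance[is.na(m$abundance)] <- 0
  m$true[is.na(m$true)] <- 0
  m <- m[m$true > 0 | m$abundance > 0, , drop = FALSE]
  mean(abs(m$abundance - m$true))
}

# Realized false-discovery proportion of the full validation on one
# labelled simulation.
realizedFdp <- function(seed, nPsms = 2000) {
  tr <- venomTruth(seed = seed)
  filt <- filterPsms(simulatePsms(tr, targetPsms = nPsms))
  kept <- psmData(filt$psms)
  sum(!kept$true_match) / max(1L, nrow(kept))
}
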