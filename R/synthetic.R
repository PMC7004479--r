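## Synthetic decomplexing-venomics experiments with known ground truth.
## One seed in the truth object controls every stage: the truth itself is
## drawn at seed, the chromatogram at seed + 101, the PSM tables at
## seed + 202 and the ELISA plate at seed + 303, in a fixed documented
## order of draws, so identical truths always yield identical data.

#' VenomTruth class
#'
#' Complete ground truth for a synthetic decomplexing experiment: the true
#' whole-venom family composition, the synthetic proteins with their
#' fraction assignments and within-fraction proportions, the
#' chromatographic layout (peak centres, widths, area shares), and the
#' generative models for peptides, search scores and ELISA affinities.
#'
#' @slot venomId Character label.
#' @slot families data.frame \code{family}, \code{proportion} (proportions
#'   of total venom protein, summing to 1 together with the unidentified
#'   fraction shares).
#' @slot proteins data.frame \code{accession}, \code{protein_name},
#'   \code{family}, \code{fraction_id}, \code{venom_proportion},
#'   \code{within_fraction}.
#' @slot fractions data.frame \code{fraction_id}, \code{center_min},
#'   \code{width_min}, \code{share}, \code{identified}.
#' @slot peptides List: \code{lambda} (mean peptides per protein),
#'   \code{sigma} (lognormal intensity sdlog), \code{fraction_total}
#'   (total spectral intensity per fraction, the equal-mass digestion
#'   convention).
#' @slot scores List of score-model parameters (target/decoy peptide-score
#'   normals, decoy fraction, SPI uniform range, protein-score model).
#' @slot elisa List: per-antivenom affinities, control affinity, response
#'   parameters.
#' @slot noise List: chromatogram noise/drift and sampling step.
#' @slot seed Integer master seed.
#'
#' @aliases VenomTruth-class
#' @exportClass VenomTruth
setClass("VenomTruth",
  representation(venomId = "character", families = "data.frame",
                 proteins = "data.frame", fractions = "data.frame",
                 peptides = "list", scores = "list", elisa = "list",
                 noise = "list", seed = "integer"))

setValidity("VenomTruth", function(object) {
  msgs <- character()
  total <- sum(object@proteins$venom_proportion) +
    sum(object@fractions$share[!object@fractions$identified])
  if (abs(total - 1) > 1e-8)
    msgs <- c(msgs, "protein proportions + unidentified shares must sum to 1")
  if (any(object@fractions$share < 0))
    msgs <- c(msgs, "fraction shares must be non-negative")
  if (object@peptides$sigma < 0 || object@peptides$lambda <= 0)
    msgs <- c(msgs, "peptide model parameters must be positive")
  if (length(msgs)) msgs else TRUE
})

.dirichlet <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

.rtruncnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.elisaAffinity <- function(preset, fractionIds) {
  n <- length(fractionIds)
  nEarly <- ceiling(0.3 * n)
  switch(preset,
    "dsmav-like" = list(
      affinity = stats::setNames(
        c(stats::runif(nEarly, 0.001, 0.01),
          stats::runif(n - nEarly, 0.4, 0.9)), fractionIds),
      high_affinity = fractionIds[seq.int(nEarly + 1L, length.out = n - nEarly)],
      control_affinity = 0.001),
    "sabu-like" = list(
      affinity = stats::setNames(stats::runif(n, 0.0003, 0.0015),
                                 fractionIds),
      high_affinity = character(),
      control_affinity = 0.8),
    stop("unknown ELISA preset: ", preset))
}

.presetFamilies <- list(
  "thai-like" = c(PLA2 = 37.92, KSPI = 22.38, SVSP = 18.07,
                  snaclec = 10.63, svVEGF = 5.42, SVMP = 3.04,
                  `5NUC` = 1.85, svNGF = 0.52, PDE = 0.16),
  "indo-like" = c(PLA2 = 48.37, SVSP = 22.41, DIS = 6.21, SVMP = 2.15,
                  LAAO = 1.47, snaclec = 1.03, PDE = 0.89, svNGF = 0.85,
                  `5NUC` = 0.18))

#' Construct a synthetic venom ground truth
#'
#' Draws (or fixes) a whole-venom toxin-family composition, populates the
#' families with synthetic proteins, lays the proteins out over
#' chromatographic fractions and attaches the generative models for every
#' downstream stage. Presets reproduce the study conditions emulated by
#' the package: \code{"thai-like"} (13 fractions, 9 families, all
#' identified) and \code{"indo-like"} (9 identified + 2 unidentified
#' fractions, 9 families) fix the family composition to the reference
#' proteomes; \code{"random"} draws a Dirichlet composition.
#'
#' @param venomId Label for the venom.
#' @param preset \code{"random"}, \code{"thai-like"} or \code{"indo-like"}.
#' @param nFractions Number of identified chromatographic fractions
#'   (default 12 for the random preset).
#' @param nUnidentified Number of additional collected fractions with no
#'   MS identifications (each drawing a 4-9\% area share).
#' @param familyProportions Optional named numeric of family proportions
#'   (overrides the preset; normalised to the identified share).
#' @param proteinsPerFamily Mean number of proteins per family
#'   (1 + Poisson(mean - 1), so at least one).
#' @param peptideLambda Mean peptides per protein per fraction (default 6).
#' @param intensitySigma Lognormal sdlog of peptide spectral intensities
#'   (default 0.4).
#' @param scores Score-model parameters; defaults: target peptide score
#'   N(35, 5), decoy N(15, 5), decoy fraction 5\%, SPI Uniform(60, 100),
#'   protein score N(80, 25) truncated at 25 for true proteins.
#' @param elisaPresets Named character vector antivenom -> ELISA preset
#'   (\code{"dsmav-like"} or \code{"sabu-like"}).
#' @param noise Chromatogram noise model: \code{chrom_sd} (mAU white
#'   noise), \code{drift_slope}/\code{drift_intercept} (linear baseline),
#'   \code{dt} (sampling step, min), \code{total_area} (mAU*min),
#'   \code{elisa_sd}, \code{elisa_blank}, \code{elisa_amax},
#'   \code{elisa_k}, \code{elisa_reps}.
#' @param seed Integer master seed controlling all stages.
#' @return A \linkS4class{VenomTruth}.
#' @export
#' @examples
#' tr <- venomTruth(seed = 7)
#' head(truthComposition(tr))
venomTruth <- function(venomId = "synthetic-venom",
                       preset = c("random", "thai-like", "indo-like"),
                       nFractions = NULL,
                       nUnidentified = NULL,
                       familyProportions = NULL,
                       proteinsPerFamily = 3,
                       peptideLambda = 6,
                       intensitySigma = 0.4,
                       scores = list(),
                       elisaPresets = c(DsMAV = "dsmav-like",
                                        SABU = "sabu-like"),
                       noise = list(),
                       seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(familyProportions) && preset != "random")
    familyProportions <- .presetFamilies[[preset]]
  if (is.null(nFractions))
    nFractions <- switch(preset, "thai-like" = 13L, "indo-like" = 9L, 12L)
  if (is.null(nUnidentified))
    nUnidentified <- if (preset == "indo-like") 2L else 0L

  scoreDefaults <- list(target_mean = 35, target_sd = 5, decoy_mean = 15,
                        decoy_sd = 5, decoy_fraction = 0.05, spi_min = 60,
                        spi_max = 100, protein_mean = 80, protein_sd = 25,
                        protein_min = 25)
  scores <- utils::modifyList(scoreDefaults, scores)
  noiseDefaults <- list(chrom_sd = 0.5, drift_slope = 0.02,
                        drift_intercept = 2, dt = 0.1, total_area = 6000,
                        elisa_sd = 0.03, elisa_blank = 0.02,
                        elisa_amax = 1.5, elisa_k = 0.15, elisa_reps = 3L)
  noise <- utils::modifyList(noiseDefaults, noise)

  set.seed(as.integer(seed))

  ## 1. family composition
  if (is.null(familyProportions)) {
    nFam <- 9L
    fams <- setdiff(toxinFamilies(), "OTHER")[seq_len(nFam)]
    w <- .dirichlet(nFam, 3)
  } else {
    fams <- names(familyProportions)
    stopifnot(all(fams %in% toxinFamilies()))
    w <- familyProportions / sum(familyProportions)
  }

  ## 2. proteins per family and their split of the family proportion
  nProt <- 1L + stats::rpois(length(fams), max(proteinsPerFamily - 1, 0))
  while (sum(nProt) < nFractions) {
    i <- sample.int(length(fams), 1L)
    nProt[i] <- nProt[i] + 1L
  }
  proteins <- do.call(rbind, lapply(seq_along(fams), function(i) {
    split_i <- .dirichlet(nProt[i], 1.5)
    data.frame(
      accession = sprintf("SYN_%s_%02d", fams[i], seq_len(nProt[i])),
      protein_name = sprintf("Synthetic %s protein %d", fams[i],
                             seq_len(nProt[i])),
      family = fams[i],
      venom_proportion = w[i] * split_i,
      stringsAsFactors = FALSE)
  }))

  ## 3. fraction layout; unidentified fractions draw their area share first
  nTotal <- nFractions + nUnidentified
  fractionIds <- sprintf("F%d", seq_len(nTotal))
  unidPos <- if (nUnidentified > 0L)
    sort(sample.int(nTotal, nUnidentified)) else integer()
  unidShare <- if (nUnidentified > 0L)
    stats::runif(nUnidentified, 0.04, 0.09) else numeric()
  identifiedIds <- fractionIds[setdiff(seq_len(nTotal), unidPos)]

  ## scale protein proportions onto the identified part of the venom
  proteins$venom_proportion <-
    proteins$venom_proportion * (1 - sum(unidShare))

  ## 4. assign proteins to identified fractions; every fraction non-empty
  assign_idx <- sample.int(nFractions, nrow(proteins), replace = TRUE)
  for (f in seq_len(nFractions)) {
    if (!any(assign_idx == f)) {
      donor <- which.max(tabulate(assign_idx, nFractions))
      assign_idx[which(assign_idx == donor)[1L]] <- f
    }
  }
  proteins$fraction_id <- identifiedIds[assign_idx]

  ## 5. floor tiny fraction shares (~>=1% of total area: smaller peaks
  ## would not have been collectable) by moving proteins from the richest
  ## fractions; this redistributes elution, never the venom composition
  fracShares <- function() vapply(identifiedIds, function(f)
    sum(proteins$venom_proportion[proteins$fraction_id == f]), numeric(1))
  fshare <- fracShares()
  iter <- 0L
  while (any(fshare < 0.012) && iter < 200L) {
    needy <- identifiedIds[which.min(fshare)]
    donors <- identifiedIds[order(-fshare)]
    donors <- donors[vapply(donors, function(f)
      sum(proteins$fraction_id == f) >= 2L, logical(1))]
    if (!length(donors)) break
    cand <- which(proteins$fraction_id == donors[1L])
    mover <- cand[which.min(proteins$venom_proportion[cand])]
    proteins$fraction_id[mover] <- needy
    fshare <- fracShares()
    iter <- iter + 1L
  }
  proteins$within_fraction <-
    proteins$venom_proportion / fshare[proteins$fraction_id]

  shareAll <- numeric(nTotal)
  names(shareAll) <- fractionIds
  shareAll[identifiedIds] <- fshare
  if (nUnidentified > 0L) shareAll[fractionIds[unidPos]] <- unidShare

  ## 6. retention layout: evenly spread centres with jitter
  centers <- seq(20, 175, length.out = nTotal) +
    stats::runif(nTotal, -2, 2)
  widths <- stats::runif(nTotal, 1.5, 2.5)
  fractions <- data.frame(fraction_id = fractionIds,
                          center_min = centers, width_min = widths,
                          share = unname(shareAll),
                          identified = !(seq_len(nTotal) %in% unidPos),
                          stringsAsFactors = FALSE)

  ## 7. final family composition (derived from the realised proteins)
  famProp <- vapply(split(proteins$venom_proportion, proteins$family),
                    sum, numeric(1))
  families <- data.frame(family = names(famProp),
                         proportion = unname(famProp),
                         stringsAsFactors = FALSE)
  families <- families[order(-families$proportion), , drop = FALSE]
  rownames(families) <- NULL

  ## 8. ELISA affinities per antivenom
  elisa <- list(
    antivenoms = lapply(stats::setNames(elisaPresets, names(elisaPresets)),
                        .elisaAffinity, fractionIds = fractionIds),
    amax = noise$elisa_amax, k = noise$elisa_k, sd = noise$elisa_sd,
    blank = noise$elisa_blank, reps = noise$elisa_reps)

  rownames(proteins) <- NULL
  new("VenomTruth", venomId = venomId, families = families,
      proteins = proteins[, c("accession", "protein_name", "family",
                              "fraction_id", "venom_proportion",
                              "within_fraction")],
      fractions = fractions,
      peptides = list(lambda = peptideLambda, sigma = intensitySigma,
                      fraction_total = 1e6),
      scores = scores, elisa = elisa, noise = noise,
      seed = as.integer(seed))
}

setMethod("show", "VenomTruth", function(object) {
  cat(sprintf(
    "VenomTruth '%s': %d proteins / %d families over %d fractions (%d unidentified), seed %d\n",
    object@venomId, nrow(object@proteins), nrow(object@families),
    nrow(object@fractions), sum(!object@fractions$identified),
    object@seed))
})

#' True whole-venom family composition of a synthetic truth
#'
#' @param object A \linkS4class{VenomTruth}.
#' @return Named numeric vector of family percentages of total venom
#'   protein (identified families; the remainder is the unidentified
#'   share, in the attribute \code{unidentified_pct}).
#' @export
setGeneric("truthComposition",
           function(object) standardGeneric("truthComposition"))

#' @rdname truthComposition
#' @export
setMethod("truthComposition", "VenomTruth", function(object) {
  out <- stats::setNames(100 * object@families$proportion,
                         object@families$family)
  attr(out, "unidentified_pct") <-
    100 * sum(object@fractions$share[!object@fractions$identified])
  out
})

#' Simulate the RP-HPLC chromatogram of a synthetic venom
#'
#' Sum of Gaussian peaks (areas proportional to the true fraction shares)
#' on a linear baseline drift with white noise, sampled on a regular grid
#' over 0-190 min, plus the true collection windows (peak centre +/- 5
#' widths, clipped at the midpoints between neighbouring peaks).
#'
#' @param truth A \linkS4class{VenomTruth}.
#' @return List with elements \code{chromatogram}
#'   (\linkS4class{Chromatogram}) and \code{boundaries}
#'   (\linkS4class{FractionBoundarySet}).
#' @export
simulateChromatogram <- function(truth) {
  stopifnot(is(truth, "VenomTruth"))
  set.seed(truth@seed + 101L)
  nz <- truth@noise
  fr <- truth@fractions
  t <- seq(0, 190, by = nz$dt)
  signal <- rep(0, length(t))
  for (i in seq_len(nrow(fr))) {
    area <- fr$share[i] * nz$total_area
    signal <- signal + area * stats::dnorm(t, fr$center_min[i],
                                           fr$width_min[i])
  }
  drift <- nz$drift_intercept + nz$drift_slope * t
  eps <- if (nz$chrom_sd > 0)
    stats::rnorm(length(t), 0, nz$chrom_sd) else 0
  chrom <- Chromatogram(time = t, absorbance = pmax(signal + drift + eps, 0),
                        meta = list(
                          flow_rate_ml_min = 1,
                          gradient = list(c("0-10 min", "0-5% B"),
                                          c("10-30 min", "5-15% B"),
                                          c("30-150 min", "15-45% B"),
                                          c("150-170 min", "45-70% B"))))
  n <- nrow(fr)
  start <- pmax(fr$center_min - 5 * fr$width_min, 0)
  end <- pmin(fr$center_min + 5 * fr$width_min, max(t))
  if (n > 1L) {
    mid <- (fr$center_min[-n] + fr$center_min[-1L]) / 2
    start[-1L] <- pmax(start[-1L], mid)
    end[-n] <- pmin(end[-n], mid)
  }
  list(chromatogram = chrom,
       boundaries = FractionBoundarySet(fr$fraction_id, start, end))
}

#' Simulate per-fraction PSM tables for a synthetic venom
#'
#' For every protein in every identified fraction, draws a Poisson number
#' of peptides whose spectral intensities are lognormal with a
#' protein-level scale proportional to the protein's within-fraction
#' proportion; intensities are then rescaled so every fraction carries the
#' same total intensity (the equal-mass digestion convention). Spurious
#' target matches and decoy matches (each at the configured decoy
#' fraction) are appended with decoy-model scores; the extra logical
#' column \code{true_match} carries the ground-truth label and is not part
#' of the on-disk PSM schema.
#'
#' @param truth A \linkS4class{VenomTruth}.
#' @param targetPsms Optional approximate total number of PSM rows; when
#'   given, the per-protein peptide mean is adjusted accordingly.
#' @return A \linkS4class{PsmTable} whose underlying data.frame carries
#'   the additional \code{true_match} column.
#' @export
simulatePsms <- function(truth, targetPsms = NULL) {
  stopifnot(is(truth, "VenomTruth"))
  set.seed(truth@seed + 202L)
  sc <- truth@scores
  pep <- truth@peptides
  prot <- truth@proteins
  lambda <- pep$lambda
  if (!is.null(targetPsms)) {
    nTrueTotal <- targetPsms / (1 + 2 * sc$decoy_fraction)
    lambda <- max(1, nTrueTotal / nrow(prot))
  }
  pepCounter <- 0L
  junkCounter <- 0L
  decoyCounter <- 0L
  rows <- list()
  for (f in truth@fractions$fraction_id[truth@fractions$identified]) {
    members <- prot[prot$fraction_id == f, , drop = FALSE]
    fracRows <- lapply(seq_len(nrow(members)), function(j) {
      n <- max(1L, stats::rpois(1L, lambda))
      intens <- members$within_fraction[j] * (if (pep$sigma > 0)
        stats::rlnorm(n, -pep$sigma^2 / 2, pep$sigma) else rep(1, n))
      pscore <- .rtruncnorm_min(1L, sc$protein_mean, sc$protein_sd,
                                sc$protein_min)
      data.frame(
        fraction_id = f,
        accession = members$accession[j],
        protein_name = members$protein_name[j],
        species = "Daboia siamensis (synthetic)",
        peptide = sprintf("PEPTIDE%06d", pepCounter + seq_len(n)),
        protein_score = pscore,
        peptide_score = stats::rnorm(n, sc$target_mean, sc$target_sd),
        spi = stats::runif(n, sc$spi_min, sc$spi_max),
        intensity = intens,
        is_decoy = FALSE,
        true_match = TRUE,
        stringsAsFactors = FALSE)
    })
    ## assign peptide ids sequentially across proteins
    for (j in seq_along(fracRows)) {
      n <- nrow(fracRows[[j]])
      fracRows[[j]]$peptide <- sprintf("PEPTIDE%06d",
                                       pepCounter + seq_len(n))
      pepCounter <- pepCounter + n
    }
    df <- do.call(rbind, fracRows)
    nTrue <- nrow(df)
    nBad <- round(sc$decoy_fraction * nTrue)
    medInt <- stats::median(df$intensity)
    mkBad <- function(nbad, accession, name, decoy) {
      if (nbad == 0L) return(NULL)
      data.frame(
        fraction_id = f,
        accession = accession,
        protein_name = name,
        species = "synthetic database",
        peptide = sprintf("PEPTIDE%06d", pepCounter + seq_len(nbad)),
        protein_score = stats::rnorm(nbad, sc$decoy_mean, sc$decoy_sd),
        peptide_score = stats::rnorm(nbad, sc$decoy_mean, sc$decoy_sd),
        spi = stats::runif(nbad, sc$spi_min, sc$spi_max),
        intensity = medInt * 0.2 * stats::rlnorm(nbad, 0, 0.5),
        is_decoy = decoy,
        true_match = FALSE,
        stringsAsFactors = FALSE)
    }
    junk <- mkBad(nBad, sprintf("XJUNK%05d", junkCounter + seq_len(nBad)),
                  "Spurious match (synthetic)", FALSE)
    if (!is.null(junk)) {
      pepCounter <- pepCounter + nBad
      junkCounter <- junkCounter + nBad
    }
    dec <- mkBad(nBad, sprintf("DECOY_SYN%05d",
                               decoyCounter + seq_len(nBad)),
                 "Reversed-database match (synthetic)", TRUE)
    if (!is.null(dec)) {
      pepCounter <- pepCounter + nBad
      decoyCounter <- decoyCounter + nBad
    }
    df <- rbind(df, junk, dec)
    ## equal total spectral intensity per fraction
    df$intensity <- df$intensity * pep$fraction_total / sum(df$intensity)
    rows[[f]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new("PsmTable", psms = out)
}

#' Simulate an ELISA immunoprofiling plate for a synthetic venom
#'
#' Per antivenom: triplicate wells for every collected fraction with
#' \code{a492 = blank + Amax * aff / (aff + K) + noise} (truncated at 0),
#' one control-antigen cell (a heterologous whole venom whose recognition
#' depends on the antivenom's immunisation mixture) and blank wells.
#'
#' @param truth A \linkS4class{VenomTruth}.
#' @return An \linkS4class{ElisaPlate}.
#' @export
simulateElisa <- function(truth) {
  stopifnot(is(truth, "VenomTruth"))
  set.seed(truth@seed + 303L)
  el <- truth@elisa
  fr <- truth@fractions$fraction_id
  rows <- list()
  for (av in names(el$antivenoms)) {
    aff <- el$antivenoms[[av]]$affinity
    signal <- el$amax * aff / (aff + el$k)
    for (i in seq_along(fr)) {
      a <- el$blank + signal[i] + stats::rnorm(el$reps, 0, el$sd)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction_id = fr[i], antivenom = av,
        replicate = seq_len(el$reps), a492 = pmax(a, 0),
        is_blank = FALSE, is_control = FALSE, stringsAsFactors = FALSE)
    }
    ctrlAff <- el$antivenoms[[av]]$control_affinity
    ctrlSig <- el$amax * ctrlAff / (ctrlAff + el$k)
    a <- el$blank + ctrlSig + stats::rnorm(el$reps, 0, el$sd)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction_id = "control_venom", antivenom = av,
      replicate = seq_len(el$reps), a492 = pmax(a, 0),
      is_blank = FALSE, is_control = TRUE, stringsAsFactors = FALSE)
    a <- el$blank + stats::rnorm(el$reps, 0, el$sd)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction_id = "blank", antivenom = av,
      replicate = seq_len(el$reps), a492 = pmax(a, 0),
      is_blank = TRUE, is_control = FALSE, stringsAsFactors = FALSE)
  }
  ElisaPlate(do.call(rbind, rows))
}

#' @rdname truthComposition
#' @export
setGeneric("truthFractions",
           function(object) standardGeneric("truthFractions"))

#' @rdname truthComposition
#' @export
setMethod("truthFractions", "VenomTruth", function(object) object@fractions)

#' @rdname truthComposition
#' @export
setGeneric("truthProteins",
           function(object) standardGeneric("truthProteins"))

#' @rdname truthComposition
#' @export
setMethod("truthProteins", "VenomTruth", function(object) object@proteins)

#' Family map of a synthetic truth
#'
#' @param truth A \linkS4class{VenomTruth}.
#' @return A \linkS4class{FamilyMap} covering the truth's accessions.
#' @export
truthFamilyMap <- function(truth) {
  stopifnot(is(truth, "VenomTruth"))
  FamilyMap(stats::setNames(truth@proteins$family,
                            truth@proteins$accession))
}

#' Write a complete synthetic experiment to disk
#'
#' Emits every input file the pipeline consumes: chromatogram trace
#' (\code{trace.csv}), collection windows (\code{boundaries.tsv}), PSM
#' table (\code{psms.tsv}, standard schema without ground-truth labels),
#' family map (\code{family_map.tsv}), ELISA plate (\code{elisa.csv}) and
#' a JSON summary of the ground truth (\code{truth.json}).
#'
#' @param truth A \linkS4class{VenomTruth}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
writeSyntheticExperiment <- function(truth, dir) {
  stopifnot(is(truth, "VenomTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateChromatogram(truth)
  psms <- simulatePsms(truth)
  plate <- simulateElisa(truth)
  paths <- c(trace = file.path(dir, "trace.csv"),
             boundaries = file.path(dir, "boundaries.tsv"),
             psms = file.path(dir, "psms.tsv"),
             family_map = file.path(dir, "family_map.tsv"),
             elisa = file.path(dir, "elisa.csv"),
             truth = file.path(dir, "truth.json"))
  writeChromatogram(sim$chromatogram, paths[["trace"]])
  writeBoundaries(sim$boundaries, paths[["boundaries"]])
  writePsmTable(psms, paths[["psms"]])
  writeFamilyMap(truthFamilyMap(truth), paths[["family_map"]])
  writeElisaPlate(plate, paths[["elisa"]])
  comp <- truthComposition(truth)
  jsonlite::write_json(
    list(venom_id = truth@venomId, seed = truth@seed,
         family_pct = as.list(comp),
         unidentified_pct = attr(comp, "unidentified_pct"),
         unidentified_fractions =
           truth@fractions$fraction_id[!truth@fractions$identified]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
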