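#' @import methods
NULL

#' Controlled vocabulary of toxin-family labels
#'
#' Family labels used throughout the package for aggregating venom proteins:
#' Kunitz-type serine protease inhibitor (KSPI), phospholipase A2 (PLA2),
#' snake venom C-type lectin/lectin-like protein (snaclec), snake venom
#' serine protease (SVSP), snake venom metalloproteinase (SVMP), L-amino
#' acid oxidase (LAAO), snake venom vascular endothelial growth factor
#' (svVEGF), snake venom nerve growth factor (svNGF), 5'-nucleotidase
#' (5NUC), phosphodiesterase (PDE), disintegrin (DIS), plus the catch-all
#' OTHER.
#'
#' @return Character vector of valid family labels.
#' @export
#' @examples
#' toxinFamilies()
toxinFamilies <- function() {
  c("KSPI", "PLA2", "snaclec", "SVSP", "SVMP", "LAAO",
    "svVEGF", "svNGF", "5NUC", "PDE", "DIS", "OTHER")
}

## ---------------------------------------------------------------------------
## Chromatogram
## ---------------------------------------------------------------------------

#' Chromatogram class
#'
#' A timed absorbance trace from reverse-phase HPLC, typically recorded at
#' 215 nm in milli-absorbance units (mAU). Time must be strictly increasing
#' with at least two points and all absorbances finite. The \code{meta} list
#' can carry acquisition metadata such as flow rate (mL/min) and the mobile
#' phase gradient program.
#'
#' @slot time Numeric, retention time in minutes, strictly increasing.
#' @slot absorbance Numeric, absorbance at each time point (mAU).
#' @slot meta List of acquisition metadata.
#'
#' @aliases Chromatogram-class
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(time = "numeric", absorbance = "numeric", meta = "list"),
  prototype(time = c(0, 1), absorbance = c(0, 0), meta = list())
)

setValidity("Chromatogram", function(object) {
  msgs <- character()
  if (length(object@time) < 2L)
    msgs <- c(msgs, "a chromatogram needs at least 2 points")
  if (length(object@time) != length(object@absorbance))
    msgs <- c(msgs, "time and absorbance must have equal length")
  if (anyNA(object@time) || any(!is.finite(object@time)))
    msgs <- c(msgs, "time values must be finite")
  if (anyNA(object@absorbance) || any(!is.finite(object@absorbance)))
    msgs <- c(msgs, "absorbance values must be finite")
  if (length(object@time) >= 2L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Chromatogram
#'
#' @param time Numeric vector of retention times (minutes), strictly
#'   increasing.
#' @param absorbance Numeric vector of absorbances (mAU), same length.
#' @param meta Optional list of metadata (e.g. \code{flow_rate_ml_min},
#'   \code{gradient} as a list of (window, \%B) segments).
#' @return A \linkS4class{Chromatogram}.
#' @export
#' @examples
#' Chromatogram(time = 0:10, absorbance = dnorm(0:10, 5, 1) * 100)
Chromatogram <- function(time, absorbance, meta = list()) {
  new("Chromatogram", time = as.numeric(time),
      absorbance = as.numeric(absorbance), meta = meta)
}

#' @describeIn Chromatogram-class retention times (minutes).
#' @param object,x A \code{Chromatogram}.
#' @export
setGeneric("elutionTime", function(object) standardGeneric("elutionTime"))

#' @rdname Chromatogram-class
#' @export
setMethod("elutionTime", "Chromatogram", function(object) object@time)

#' @rdname Chromatogram-class
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname Chromatogram-class
#' @export
setMethod("absorbance", "Chromatogram", function(object) object@absorbance)

#' @rdname Chromatogram-class
#' @export
setMethod("length", "Chromatogram", function(x) length(x@time))

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram:", length(object@time), "points,",
      sprintf("%.2f-%.2f min,", min(object@time), max(object@time)),
      sprintf("max %.2f mAU\n", max(object@absorbance)))
})

## ---------------------------------------------------------------------------
## FractionBoundarySet
## ---------------------------------------------------------------------------

#' FractionBoundarySet class
#'
#' Manually (or automatically) collected fraction windows on a chromatogram.
#' Intervals are half-open \code{[start, end)} in minutes, sorted and
#' non-overlapping; \code{collected} marks windows that were actually
#' collected and hence enter the normalising denominator when shares are
#' integrated.
#'
#' @slot boundaries data.frame with columns \code{fraction_id},
#'   \code{start}, \code{end}, \code{collected}.
#'
#' @aliases FractionBoundarySet-class
#' @exportClass FractionBoundarySet
setClass("FractionBoundarySet",
  representation(boundaries = "data.frame"),
  prototype(boundaries = data.frame(
    fraction_id = character(), start = numeric(), end = numeric(),
    collected = logical()))
)

setValidity("FractionBoundarySet", function(object) {
  b <- object@boundaries
  msgs <- character()
  need <- c("fraction_id", "start", "end", "collected")
  if (!all(need %in% names(b)))
    return(paste("boundaries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(b$fraction_id))
    msgs <- c(msgs, "fraction ids must be unique")
  if (any(b$end <= b$start))
    msgs <- c(msgs, "each boundary needs end > start")
  if (nrow(b) > 1L) {
    if (is.unsorted(b$start, strictly = TRUE))
      msgs <- c(msgs, "boundaries must be sorted by start time")
    else if (any(b$start[-1L] < b$end[-nrow(b)]))
      msgs <- c(msgs, "boundaries must not overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FractionBoundarySet
#'
#' @param fraction_id Character labels, unique.
#' @param start,end Numeric window edges in minutes; intervals are half-open
#'   \code{[start, end)}.
#' @param collected Logical, whether each window was collected
#'   (default all \code{TRUE}).
#' @return A \linkS4class{FractionBoundarySet} sorted by start time.
#' @export
#' @examples
#' FractionBoundarySet(c("F1", "F2"), start = c(0, 10), end = c(10, 20))
FractionBoundarySet <- function(fraction_id, start, end,
                                collected = rep(TRUE, length(fraction_id))) {
  b <- data.frame(fraction_id = as.character(fraction_id),
                  start = as.numeric(start), end = as.numeric(end),
                  collected = as.logical(collected),
                  stringsAsFactors = FALSE)
  b <- b[order(b$start), , drop = FALSE]
  rownames(b) <- NULL
  new("FractionBoundarySet", boundaries = b)
}

#' @rdname FractionBoundarySet-class
#' @param object,x A \code{FractionBoundarySet}.
#' @export
setGeneric("boundaries", function(object) standardGeneric("boundaries"))

#' @rdname FractionBoundarySet-class
#' @export
setMethod("boundaries", "FractionBoundarySet",
          function(object) object@boundaries)

#' @rdname FractionBoundarySet-class
#' @export
setMethod("length", "FractionBoundarySet",
          function(x) nrow(x@boundaries))

setMethod("show", "FractionBoundarySet", function(object) {
  b <- object@boundaries
  cat("FractionBoundarySet:", nrow(b), "fractions,",
      sum(b$collected), "collected\n")
  if (nrow(b)) print(utils::head(b, 8L))
})

## ---------------------------------------------------------------------------
## FractionShareTable
## ---------------------------------------------------------------------------

#' FractionShareTable class
#'
#' The proportion of total integrated chromatographic area attributed to
#' each collected fraction. Shares are dimensionless proportions in [0, 1]
#' and sum to 1 over collected fractions (tolerance 1e-9).
#'
#' @slot shares Named numeric vector (names = fraction ids).
#'
#' @aliases FractionShareTable-class
#' @exportClass FractionShareTable
setClass("FractionShareTable",
  representation(shares = "numeric"),
  prototype(shares = c(F1 = 1))
)

setValidity("FractionShareTable", function(object) {
  s <- object@shares
  msgs <- character()
  if (is.null(names(s)) || any(!nzchar(names(s))))
    msgs <- c(msgs, "shares must be named by fraction id")
  if (any(s < 0)) msgs <- c(msgs, "shares must be non-negative")
  if (length(s) && abs(sum(s) - 1) > 1e-9)
    msgs <- c(msgs, sprintf("shares must sum to 1 (got %.12f)", sum(s)))
  if (length(msgs)) msgs else TRUE
})

#' Construct a FractionShareTable
#'
#' @param shares Named numeric vector of per-fraction area proportions;
#'   must sum to 1 within 1e-9.
#' @return A \linkS4class{FractionShareTable}.
#' @export
#' @examples
#' FractionShareTable(c(F1 = 0.75, F2 = 0.25))
FractionShareTable <- function(shares) {
  new("FractionShareTable", shares = shares)
}

#' @rdname FractionShareTable-class
#' @param object,x A \code{FractionShareTable}.
#' @export
setGeneric("shares", function(object) standardGeneric("shares"))

#' @rdname FractionShareTable-class
#' @export
setMethod("shares", "FractionShareTable", function(object) object@shares)

#' @rdname FractionShareTable-class
#' @export
setMethod("length", "FractionShareTable", function(x) length(x@shares))

setMethod("show", "FractionShareTable", function(object) {
  cat("FractionShareTable:", length(object@shares), "fractions\n")
  print(round(object@shares, 4))
})

## ---------------------------------------------------------------------------
## PsmTable
## ---------------------------------------------------------------------------

.psmColumns <- c("fraction_id", "accession", "protein_name", "species",
                 "peptide", "protein_score", "peptide_score", "spi",
                 "intensity", "is_decoy")

#' PsmTable class
#'
#' A table of peptide-spectrum matches (PSMs), one row per match, with the
#' search-engine scores used by the validation cascade: \code{protein_score}
#' and \code{peptide_score} (dimensionless), \code{spi} (scored peak
#' intensity, percent of spectral peak intensity explained, in [0, 100]),
#' \code{intensity} (spectral intensity, arbitrary units, non-negative) and
#' a decoy flag for target-decoy FDR estimation.
#'
#' @slot psms data.frame with columns \code{fraction_id}, \code{accession},
#'   \code{protein_name}, \code{species}, \code{peptide},
#'   \code{protein_score}, \code{peptide_score}, \code{spi},
#'   \code{intensity}, \code{is_decoy} (logical).
#'
#' @aliases PsmTable-class
#' @exportClass PsmTable
setClass("PsmTable",
  representation(psms = "data.frame"),
  prototype(psms = stats::setNames(
    data.frame(character(), character(), character(), character(),
               character(), numeric(), numeric(), numeric(), numeric(),
               logical(), stringsAsFactors = FALSE),
    .psmColumns))
)

.validatePsmFrame <- function(p) {
  missing_cols <- setdiff(.psmColumns, names(p))
  if (length(missing_cols))
    return(list(schema = paste("missing column(s):",
                               paste(missing_cols, collapse = ", "))))
  bad <- list()
  rows_bad_spi <- which(is.na(p$spi) | p$spi < 0 | p$spi > 100)
  if (length(rows_bad_spi)) bad$spi <- rows_bad_spi
  rows_bad_int <- which(is.na(p$intensity) | p$intensity < 0)
  if (length(rows_bad_int)) bad$intensity <- rows_bad_int
  rows_bad_acc <- which(is.na(p$accession) | !nzchar(p$accession))
  if (length(rows_bad_acc)) bad$accession <- rows_bad_acc
  bad
}

setValidity("PsmTable", function(object) {
  bad <- .validatePsmFrame(object@psms)
  if (!length(bad)) return(TRUE)
  if (!is.null(bad$schema)) return(bad$schema)
  msgs <- character()
  if (!is.null(bad$spi))
    msgs <- c(msgs, paste("spi outside [0,100] at row(s)",
                          paste(utils::head(bad$spi, 5L), collapse = ", ")))
  if (!is.null(bad$intensity))
    msgs <- c(msgs, paste("negative/missing intensity at row(s)",
                          paste(utils::head(bad$intensity, 5L), collapse = ", ")))
  if (!is.null(bad$accession))
    msgs <- c(msgs, paste("empty accession at row(s)",
                          paste(utils::head(bad$accession, 5L), collapse = ", ")))
  msgs
})

#' Construct a PsmTable
#'
#' @param psms data.frame holding one PSM per row (see
#'   \linkS4class{PsmTable} for the column contract). \code{is_decoy} may
#'   be 0/1 and is coerced to logical.
#' @return A validated \linkS4class{PsmTable}.
#' @export
PsmTable <- function(psms) {
  if (!is.data.frame(psms))
    dcxError("dcx_schema_error", "psms must be a data.frame")
  bad <- .validatePsmFrame(psms)
  if (!is.null(bad$schema))
    dcxError("dcx_schema_error", paste("PSM table:", bad$schema))
  if (length(bad)) {
    field <- names(bad)[1L]
    dcxError("dcx_malformed_record",
             sprintf("PSM table: invalid %s at row(s) %s", field,
                     paste(utils::head(bad[[field]], 10L), collapse = ", ")),
             rows = bad[[field]])
  }
  psms$is_decoy <- as.logical(psms$is_decoy)
  for (col in c("fraction_id", "accession", "protein_name", "species",
                "peptide"))
    psms[[col]] <- as.character(psms[[col]])
  for (col in c("protein_score", "peptide_score", "spi", "intensity"))
    psms[[col]] <- as.numeric(psms[[col]])
  rownames(psms) <- NULL
  new("PsmTable", psms = psms)
}

#' @rdname PsmTable-class
#' @param object,x A \code{PsmTable}.
#' @export
setGeneric("psmData", function(object) standardGeneric("psmData"))

#' @rdname PsmTable-class
#' @export
setMethod("psmData", "PsmTable", function(object) object@psms)

#' @rdname PsmTable-class
#' @export
setGeneric("decoyCount", function(object) standardGeneric("decoyCount"))

#' @rdname PsmTable-class
#' @export
setMethod("decoyCount", "PsmTable", function(object) sum(object@psms$is_decoy))

#' @rdname PsmTable-class
#' @export
setMethod("length", "PsmTable", function(x) nrow(x@psms))

setMethod("show", "PsmTable", function(object) {
  p <- object@psms
  cat("PsmTable:", nrow(p), "PSMs (", sum(p$is_decoy), "decoys ) in",
      length(unique(p$fraction_id)), "fraction(s)\n")
})

## ---------------------------------------------------------------------------
## FilterThresholds
## ---------------------------------------------------------------------------

#' FilterThresholds class
#'
#' Validation thresholds for the PSM filter cascade. Score and SPI filters
#' are strict (\code{>}); the FDR bound is applied as \code{fdr < maxFdr}
#' on the smoothed target-decoy curve.
#'
#' @slot minProteinScore Minimum protein score, strict (default 20).
#' @slot minPeptideScore Minimum peptide score, strict (default 10).
#' @slot minSpi Minimum scored peak intensity in percent, strict
#'   (default 70).
#' @slot maxFdr PSM-level FDR bound in (0, 1) (default 0.01).
#'
#' @aliases FilterThresholds-class
#' @exportClass FilterThresholds
setClass("FilterThresholds",
  representation(minProteinScore = "numeric", minPeptideScore = "numeric",
                 minSpi = "numeric", maxFdr = "numeric"),
  prototype(minProteinScore = 20, minPeptideScore = 10, minSpi = 70,
            maxFdr = 0.01)
)

setValidity("FilterThresholds", function(object) {
  vals <- c(object@minProteinScore, object@minPeptideScore, object@minSpi,
            object@maxFdr)
  if (length(vals) != 4L || anyNA(vals) || any(!is.finite(vals)))
    return("all thresholds must be single finite numbers")
  if (object@maxFdr <= 0 || object@maxFdr >= 1)
    return("maxFdr must lie in (0, 1)")
  TRUE
})

#' Construct FilterThresholds
#'
#' @param minProteinScore,minPeptideScore,minSpi Strict lower bounds for
#'   protein score, peptide score and SPI (\%).
#' @param maxFdr PSM-level FDR bound in (0, 1).
#' @return A \linkS4class{FilterThresholds}.
#' @export
#' @examples
#' FilterThresholds()  # protein > 20, peptide > 10, SPI > 70, FDR < 1%
FilterThresholds <- function(minProteinScore = 20, minPeptideScore = 10,
                             minSpi = 70, maxFdr = 0.01) {
  new("FilterThresholds", minProteinScore = minProteinScore,
      minPeptideScore = minPeptideScore, minSpi = minSpi, maxFdr = maxFdr)
}

setMethod("show", "FilterThresholds", function(object) {
  cat(sprintf(
    "FilterThresholds: protein score > %g, peptide score > %g, SPI > %g%%, FDR < %g\n",
    object@minProteinScore, object@minPeptideScore, object@minSpi,
    object@maxFdr))
})

## ---------------------------------------------------------------------------
## FamilyMap
## ---------------------------------------------------------------------------

#' FamilyMap class
#'
#' Assignment of protein accessions to toxin families, restricted to the
#' controlled vocabulary of \code{\link{toxinFamilies}}. Accessions are
#' compared case-sensitively.
#'
#' @slot map Named character vector, accession -> family label.
#'
#' @aliases FamilyMap-class
#' @exportClass FamilyMap
setClass("FamilyMap",
  representation(map = "character"),
  prototype(map = c(X = "OTHER"))
)

setValidity("FamilyMap", function(object) {
  m <- object@map
  msgs <- character()
  if (length(m) && (is.null(names(m)) || any(!nzchar(names(m)))))
    msgs <- c(msgs, "map must be named by accession")
  if (anyDuplicated(names(m)))
    msgs <- c(msgs, "duplicate accessions in family map")
  unknown <- setdiff(unique(m), toxinFamilies())
  if (length(unknown))
    msgs <- c(msgs, paste("unknown family label(s):",
                          paste(unknown, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a FamilyMap
#'
#' @param map Named character vector mapping accession to a family label
#'   from \code{\link{toxinFamilies}}.
#' @return A \linkS4class{FamilyMap}.
#' @export
#' @examples
#' FamilyMap(c(P31100 = "PLA2", Q7ZZM2 = "DIS"))
FamilyMap <- function(map) {
  new("FamilyMap", map = map)
}

#' @rdname FamilyMap-class
#' @param object,x A \code{FamilyMap}.
#' @export
setGeneric("familyAssignments",
           function(object) standardGeneric("familyAssignments"))

#' @rdname FamilyMap-class
#' @export
setMethod("familyAssignments", "FamilyMap", function(object) object@map)

#' Look up toxin families for accessions
#'
#' Unmapped accessions are assigned \code{"OTHER"} with a warning.
#'
#' @param fmap A \linkS4class{FamilyMap}.
#' @param accession Character vector of accessions.
#' @return Character vector of family labels, same length as
#'   \code{accession}.
#' @export
lookupFamily <- function(fmap, accession) {
  stopifnot(is(fmap, "FamilyMap"))
  fam <- unname(fmap@map[accession])
  if (anyNA(fam)) {
    miss <- unique(accession[is.na(fam)])
    dcxWarn("dcx_unmapped_accession",
            paste("unmapped accession(s) assigned to OTHER:",
                  paste(utils::head(miss, 10L), collapse = ", ")))
    fam[is.na(fam)] <- "OTHER"
  }
  fam
}

#' @rdname FamilyMap-class
#' @export
setMethod("length", "FamilyMap", function(x) length(x@map))

setMethod("show", "FamilyMap", function(object) {
  cat("FamilyMap:", length(object@map), "accessions over",
      length(unique(object@map)), "families\n")
})

## ---------------------------------------------------------------------------
## AbundanceTable
## ---------------------------------------------------------------------------

#' AbundanceTable class
#'
#' Whole-venom relative abundances: one row per (protein, source fraction),
#' in percent of total venom protein, plus a bucket for collected fractions
#' whose proteins could not be identified by MS. Per-protein percentages
#' and the unidentified share together sum to 100 (tolerance 0.5 to absorb
#' the 2-dp rounding of transcribed tables; pipeline-computed tables agree
#' to 1e-6).
#'
#' @slot proteins data.frame with columns \code{accession},
#'   \code{protein_name}, \code{family} (may be NA before family
#'   assignment), \code{fraction_id} (NA when provenance is unknown) and
#'   \code{abundance} (percent).
#' @slot unidentifiedShare Numeric scalar, percent.
#' @slot venomId Character label for the venom.
#'
#' @aliases AbundanceTable-class
#' @exportClass AbundanceTable
setClass("AbundanceTable",
  representation(proteins = "data.frame", unidentifiedShare = "numeric",
                 venomId = "character"),
  prototype(proteins = data.frame(
    accession = "X", protein_name = "x", family = NA_character_,
    fraction_id = NA_character_, abundance = 100,
    stringsAsFactors = FALSE),
    unidentifiedShare = 0, venomId = "venom")
)

setValidity("AbundanceTable", function(object) {
  p <- object@proteins
  need <- c("accession", "protein_name", "family", "fraction_id",
            "abundance")
  if (!all(need %in% names(p)))
    return(paste("proteins must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(p$abundance < 0)) msgs <- c(msgs, "abundances must be >= 0")
  if (object@unidentifiedShare < 0)
    msgs <- c(msgs, "unidentified share must be >= 0")
  total <- sum(p$abundance) + object@unidentifiedShare
  if (nrow(p) && abs(total - 100) > 0.5)
    msgs <- c(msgs, sprintf(
      "abundances + unidentified share must total 100 (got %.4f)", total))
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbundanceTable
#'
#' @param proteins data.frame of per-protein rows (see
#'   \linkS4class{AbundanceTable}); \code{family} and \code{fraction_id}
#'   default to NA when absent.
#' @param unidentifiedShare Percent of total venom protein in collected but
#'   MS-unidentified fractions.
#' @param venomId Label for the venom.
#' @return An \linkS4class{AbundanceTable}.
#' @export
AbundanceTable <- function(proteins, unidentifiedShare = 0,
                           venomId = "venom") {
  if (!"family" %in% names(proteins)) proteins$family <- NA_character_
  if (!"fraction_id" %in% names(proteins))
    proteins$fraction_id <- NA_character_
  proteins <- proteins[, c("accession", "protein_name", "family",
                           "fraction_id", "abundance")]
  rownames(proteins) <- NULL
  new("AbundanceTable", proteins = proteins,
      unidentifiedShare = unidentifiedShare, venomId = venomId)
}

#' @rdname AbundanceTable-class
#' @param object,x An \code{AbundanceTable}.
#' @export
setGeneric("proteinAbundance",
           function(object) standardGeneric("proteinAbundance"))

#' @rdname AbundanceTable-class
#' @export
setMethod("proteinAbundance", "AbundanceTable",
          function(object) object@proteins)

#' @rdname AbundanceTable-class
#' @export
setGeneric("unidentifiedShare",
           function(object) standardGeneric("unidentifiedShare"))

#' @rdname AbundanceTable-class
#' @export
setMethod("unidentifiedShare", "AbundanceTable",
          function(object) object@unidentifiedShare)

#' @rdname AbundanceTable-class
#' @export
setGeneric("venomId", function(object) standardGeneric("venomId"))

#' @rdname AbundanceTable-class
#' @export
setMethod("venomId", "AbundanceTable", function(object) object@venomId)

#' @rdname AbundanceTable-class
#' @export
setMethod("length", "AbundanceTable", function(x) nrow(x@proteins))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf(
    "AbundanceTable '%s': %d protein rows (%d distinct accessions), %.2f%% unidentified\n",
    object@venomId, nrow(object@proteins),
    length(unique(object@proteins$accession)), object@unidentifiedShare))
})

## ---------------------------------------------------------------------------
## ElisaPlate
## ---------------------------------------------------------------------------

#' ElisaPlate class
#'
#' Raw A492 readings from an indirect ELISA in which wells precoated with
#' HPLC venom fractions (default 10 ng) are probed with an antivenom
#' (default dilution 1:2700). Replicate wells per (fraction, antivenom)
#' cell, at least one blank well per plate, and optional control-antigen
#' wells flagged by \code{is_control}.
#'
#' @slot wells data.frame with columns \code{fraction_id},
#'   \code{antivenom}, \code{replicate}, \code{a492}, \code{is_blank},
#'   \code{is_control}.
#' @slot meta List, e.g. \code{dilution}, \code{coat_ng}.
#'
#' @aliases ElisaPlate-class
#' @exportClass ElisaPlate
setClass("ElisaPlate",
  representation(wells = "data.frame", meta = "list"),
  prototype(wells = data.frame(
    fraction_id = c("F1", "blank"), antivenom = c("AV", "AV"),
    replicate = c(1L, 1L), a492 = c(0.5, 0.02),
    is_blank = c(FALSE, TRUE), is_control = c(FALSE, FALSE),
    stringsAsFactors = FALSE),
    meta = list(dilution = "1:2700", coat_ng = 10))
)

setValidity("ElisaPlate", function(object) {
  w <- object@wells
  need <- c("fraction_id", "antivenom", "replicate", "a492", "is_blank",
            "is_control")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(is.na(w$a492) | w$a492 < 0))
    msgs <- c(msgs, "a492 readings must be non-negative")
  if (nrow(w) && !any(w$is_blank))
    msgs <- c(msgs, "plate must contain at least one blank well")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ElisaPlate
#'
#' @param wells data.frame of well readings (see \linkS4class{ElisaPlate}).
#' @param meta List of plate metadata; defaults record a 1:2700 antivenom
#'   dilution and 10 ng coat mass per well.
#' @return An \linkS4class{ElisaPlate}.
#' @export
ElisaPlate <- function(wells, meta = list(dilution = "1:2700",
                                          coat_ng = 10)) {
  wells$is_blank <- as.logical(wells$is_blank)
  wells$is_control <- as.logical(wells$is_control)
  rownames(wells) <- NULL
  new("ElisaPlate", wells = wells, meta = meta)
}

#' @rdname ElisaPlate-class
#' @param object,x An \code{ElisaPlate}.
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname ElisaPlate-class
#' @export
setMethod("wells", "ElisaPlate", function(object) object@wells)

#' @rdname ElisaPlate-class
#' @export
setMethod("length", "ElisaPlate", function(x) nrow(x@wells))

setMethod("show", "ElisaPlate", function(object) {
  w <- object@wells
  cat("ElisaPlate:", nrow(w), "wells,",
      length(unique(w$fraction_id[!w$is_blank])), "antigens x",
      length(unique(w$antivenom[!w$is_blank])), "antivenom(s),",
      sum(w$is_blank), "blank(s)\n")
})

## ---------------------------------------------------------------------------
## VenomComparison
## ---------------------------------------------------------------------------

#' VenomComparison class
#'
#' Family-level comparison of two venoms: per-family abundances in both,
#' their difference, and a status flag. \code{unique_to_a} means the family
#' was detected only in venom A (abundance in B exactly 0), and vice versa;
#' families present in both are \code{shared}.
#'
#' @slot venoms Character vector of the two venom ids (A, B).
#' @slot families data.frame with columns \code{family},
#'   \code{abundance_a}, \code{abundance_b}, \code{delta}, \code{status}.
#' @slot counts data.frame with per-venom non-redundant \code{proteins} and
#'   \code{families} counts.
#'
#' @aliases VenomComparison-class
#' @exportClass VenomComparison
setClass("VenomComparison",
  representation(venoms = "character", families = "data.frame",
                 counts = "data.frame"),
  prototype(venoms = c("A", "B"),
            families = data.frame(
              family = character(), abundance_a = numeric(),
              abundance_b = numeric(), delta = numeric(),
              status = character(), stringsAsFactors = FALSE),
            counts = data.frame(venom = character(), proteins = integer(),
                                families = integer(),
                                stringsAsFactors = FALSE))
)

setValidity("VenomComparison", function(object) {
  f <- object@families
  if (length(object@venoms) != 2L)
    return("exactly two venoms are compared")
  bad_a <- f$status == "unique_to_a" & !(f$abundance_b == 0 & f$abundance_a > 0)
  bad_b <- f$status == "unique_to_b" & !(f$abundance_a == 0 & f$abundance_b > 0)
  if (any(bad_a) || any(bad_b))
    return("unique_to_* status requires zero abundance in the other venom")
  TRUE
})

#' @rdname VenomComparison-class
#' @param object An \code{VenomComparison}.
#' @export
setGeneric("comparisonTable",
           function(object) standardGeneric("comparisonTable"))

#' @rdname VenomComparison-class
#' @export
setMethod("comparisonTable", "VenomComparison",
          function(object) object@families)

#' @rdname VenomComparison-class
#' @export
setGeneric("comparisonCounts",
           function(object) standardGeneric("comparisonCounts"))

#' @rdname VenomComparison-class
#' @export
setMethod("comparisonCounts", "VenomComparison",
          function(object) object@counts)

setMethod("show", "VenomComparison", function(object) {
  f <- object@families
  cat(sprintf("VenomComparison %s vs %s: %d families (%d shared, %d/%d unique)\n",
              object@venoms[1L], object@venoms[2L], nrow(f),
              sum(f$status == "shared"), sum(f$status == "unique_to_a"),
              sum(f$status == "unique_to_b")))
  if (nrow(f)) print(f, row.names = FALSE)
})
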