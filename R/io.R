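## Readers and writers for the pipeline's plain-text formats. All files are
## UTF-8; decimals use the point dialect. Numeric output is written with
## enough digits ("%.17g") that a write -> read cycle reproduces doubles
## bit-identically.

.fmtNum <- function(x) sprintf("%.17g", x)

.readTable <- function(path, sep, what) {
  if (!file.exists(path))
    dcxError("dcx_schema_error", sprintf("%s file not found: %s", what, path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) dcxError(
      "dcx_schema_error",
      sprintf("%s file %s could not be parsed: %s", what, path,
              conditionMessage(e))))
  df
}

.requireColumns <- function(df, cols, what, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    dcxError("dcx_schema_error",
             sprintf("%s file %s: missing column(s) %s", what, path,
                     paste(missing_cols, collapse = ", ")))
  invisible(df)
}

## ---------------------------------------------------------------------------
## Chromatogram
## ---------------------------------------------------------------------------

#' Read / write a chromatogram trace
#'
#' The trace format is a two-column CSV with header
#' \code{time_min,absorbance_mau}: retention time in minutes (strictly
#' increasing) and absorbance at 215 nm in mAU.
#'
#' @param path File path.
#' @return \code{readChromatogram} returns a \linkS4class{Chromatogram};
#'   \code{writeChromatogram} returns \code{path} invisibly.
#' @export
readChromatogram <- function(path) {
  df <- .readTable(path, sep = ",", what = "chromatogram")
  .requireColumns(df, c("time_min", "absorbance_mau"), "chromatogram", path)
  if (nrow(df) < 2L)
    dcxError("dcx_malformed_trace",
             sprintf("chromatogram %s has fewer than 2 points", path))
  t <- as.numeric(df$time_min)
  a <- as.numeric(df$absorbance_mau)
  if (anyNA(t) || anyNA(a) || any(!is.finite(t)) || any(!is.finite(a)))
    dcxError("dcx_malformed_trace",
             sprintf("chromatogram %s contains non-finite values", path),
             rows = which(!is.finite(t) | !is.finite(a)))
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0) + 1L
    dcxError("dcx_malformed_trace",
             sprintf("chromatogram %s: time not strictly increasing at row(s) %s",
                     path, paste(utils::head(bad, 5L), collapse = ", ")),
             rows = bad)
  }
  Chromatogram(time = t, absorbance = a)
}

#' @rdname readChromatogram
#' @param chrom A \linkS4class{Chromatogram}.
#' @export
writeChromatogram <- function(chrom, path) {
  stopifnot(is(chrom, "Chromatogram"))
  lines <- c("time_min,absorbance_mau",
             paste(.fmtNum(chrom@time), .fmtNum(chrom@absorbance), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Fraction boundaries
## ---------------------------------------------------------------------------

#' Read / write fraction boundary tables
#'
#' TSV with columns \code{fraction_id}, \code{start_min}, \code{end_min},
#' \code{collected} (0/1). Intervals are half-open \code{[start, end)}.
#'
#' @param path File path.
#' @return \code{readBoundaries} returns a
#'   \linkS4class{FractionBoundarySet}.
#' @export
readBoundaries <- function(path) {
  df <- .readTable(path, sep = "\t", what = "boundaries")
  .requireColumns(df, c("fraction_id", "start_min", "end_min", "collected"),
                  "boundaries", path)
  FractionBoundarySet(df$fraction_id, df$start_min, df$end_min,
                      as.logical(as.integer(df$collected)))
}

#' @rdname readBoundaries
#' @param bounds A \linkS4class{FractionBoundarySet}.
#' @export
writeBoundaries <- function(bounds, path) {
  stopifnot(is(bounds, "FractionBoundarySet"))
  b <- bounds@boundaries
  lines <- c("fraction_id\tstart_min\tend_min\tcollected",
             paste(b$fraction_id, .fmtNum(b$start), .fmtNum(b$end),
                   as.integer(b$collected), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## PSM tables
## ---------------------------------------------------------------------------

#' Read / write PSM tables
#'
#' TSV with the columns of \linkS4class{PsmTable}: \code{fraction_id},
#' \code{accession}, \code{protein_name}, \code{species}, \code{peptide},
#' \code{protein_score}, \code{peptide_score}, \code{spi},
#' \code{intensity}, \code{is_decoy} (0/1). Records violating the type
#' invariants (SPI outside [0, 100], negative intensity, empty accession)
#' are rejected with the offending row numbers.
#'
#' @param path File path.
#' @param decoyPrefix Optional accession prefix (commonly \code{"DECOY_"})
#'   marking decoy PSMs. When supplied, accessions with this prefix are
#'   flagged as decoys in addition to (or, if the \code{is_decoy} column is
#'   absent, instead of) the explicit flag.
#' @return \code{readPsmTable} returns a \linkS4class{PsmTable}.
#' @export
readPsmTable <- function(path, decoyPrefix = NULL) {
  df <- .readTable(path, sep = "\t", what = "PSM")
  need <- setdiff(.psmColumns, "is_decoy")
  .requireColumns(df, need, "PSM", path)
  if (!"is_decoy" %in% names(df)) {
    if (is.null(decoyPrefix))
      dcxError("dcx_schema_error",
               sprintf("PSM file %s: missing column(s) is_decoy", path))
    df$is_decoy <- FALSE
  } else {
    df$is_decoy <- as.logical(as.integer(df$is_decoy))
  }
  if (!is.null(decoyPrefix))
    df$is_decoy <- df$is_decoy | startsWith(as.character(df$accession),
                                            decoyPrefix)
  PsmTable(df)
}

#' @rdname readPsmTable
#' @param psms A \linkS4class{PsmTable}.
#' @export
writePsmTable <- function(psms, path) {
  stopifnot(is(psms, "PsmTable"))
  p <- psms@psms
  lines <- c(paste(.psmColumns, collapse = "\t"),
             paste(p$fraction_id, p$accession, p$protein_name, p$species,
                   p$peptide, .fmtNum(p$protein_score),
                   .fmtNum(p$peptide_score), .fmtNum(p$spi),
                   .fmtNum(p$intensity), as.integer(p$is_decoy),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Family map
## ---------------------------------------------------------------------------

#' Read / write a family map
#'
#' TSV with columns \code{accession}, \code{family}; the family must come
#' from \code{\link{toxinFamilies}}.
#'
#' @param path File path.
#' @return \code{readFamilyMap} returns a \linkS4class{FamilyMap}.
#' @export
readFamilyMap <- function(path) {
  df <- .readTable(path, sep = "\t", what = "family map")
  .requireColumns(df, c("accession", "family"), "family map", path)
  unknown <- which(!(df$family %in% toxinFamilies()))
  if (length(unknown))
    dcxError("dcx_vocabulary_error",
             sprintf("family map %s: unknown family label(s) %s at row(s) %s",
                     path,
                     paste(unique(df$family[unknown]), collapse = ", "),
                     paste(utils::head(unknown, 5L), collapse = ", ")),
             rows = unknown)
  FamilyMap(stats::setNames(as.character(df$family),
                            as.character(df$accession)))
}

#' @rdname readFamilyMap
#' @param fmap A \linkS4class{FamilyMap}.
#' @export
writeFamilyMap <- function(fmap, path) {
  stopifnot(is(fmap, "FamilyMap"))
  lines <- c("accession\tfamily",
             paste(names(fmap@map), unname(fmap@map), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## ELISA plates
## ---------------------------------------------------------------------------

#' Read / write ELISA plate data
#'
#' Long-format CSV with columns \code{fraction_id}, \code{antivenom},
#' \code{replicate}, \code{a492}, \code{is_blank} (0/1), \code{is_control}
#' (0/1).
#'
#' @param path File path.
#' @return \code{readElisaPlate} returns an \linkS4class{ElisaPlate}.
#' @export
readElisaPlate <- function(path) {
  df <- .readTable(path, sep = ",", what = "ELISA")
  .requireColumns(df, c("fraction_id", "antivenom", "replicate", "a492",
                        "is_blank", "is_control"), "ELISA", path)
  if (nrow(df) == 0L)
    dcxError("dcx_schema_error", sprintf("ELISA file %s is empty", path))
  bad <- which(is.na(df$a492) | df$a492 < 0)
  if (length(bad))
    dcxError("dcx_malformed_record",
             sprintf("ELISA file %s: negative/missing a492 at row(s) %s",
                     path, paste(utils::head(bad, 5L), collapse = ", ")),
             rows = bad)
  df$is_blank <- as.logical(as.integer(df$is_blank))
  df$is_control <- as.logical(as.integer(df$is_control))
  if (!any(df$is_blank))
    dcxError("dcx_no_blank",
             sprintf("ELISA file %s contains no blank well", path))
  ElisaPlate(df[, c("fraction_id", "antivenom", "replicate", "a492",
                    "is_blank", "is_control")])
}

#' @rdname readElisaPlate
#' @param plate An \linkS4class{ElisaPlate}.
#' @export
writeElisaPlate <- function(plate, path) {
  stopifnot(is(plate, "ElisaPlate"))
  w <- plate@wells
  lines <- c("fraction_id,antivenom,replicate,a492,is_blank,is_control",
             paste(w$fraction_id, w$antivenom, w$replicate, .fmtNum(w$a492),
                   as.integer(w$is_blank), as.integer(w$is_control),
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Abundance tables and comparisons
## ---------------------------------------------------------------------------

#' Read / write whole-venom abundance tables
#'
#' TSV with columns \code{venom_id}, \code{accession}, \code{protein_name},
#' \code{family}, \code{fraction_id}, \code{abundance_pct}. The
#' unidentified bucket is carried as a final row with accession
#' \code{"(unidentified)"}. \code{writeAbundanceTable} optionally also
#' writes the per-family aggregate sheet.
#'
#' @param path File path for the per-protein sheet.
#' @param familyPath Optional path for a per-family TSV
#'   (\code{family}, \code{abundance_pct}, \code{n_proteins}).
#' @param fmap Optional \linkS4class{FamilyMap} used for the family sheet
#'   when the table rows carry no family assignment.
#' @return \code{readAbundanceTable} returns an
#'   \linkS4class{AbundanceTable}.
#' @export
writeAbundanceTable <- function(x, path, familyPath = NULL, fmap = NULL) {
  stopifnot(is(x, "AbundanceTable"))
  p <- x@proteins
  na2empty <- function(v) ifelse(is.na(v), "", v)
  lines <- c(
    "venom_id\taccession\tprotein_name\tfamily\tfraction_id\tabundance_pct",
    paste(x@venomId, p$accession, p$protein_name, na2empty(p$family),
          na2empty(p$fraction_id), .fmtNum(p$abundance), sep = "\t"),
    paste(x@venomId, "(unidentified)", "Unidentified proteins", "", "",
          .fmtNum(x@unidentifiedShare), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(familyPath)) {
    fam <- aggregateFamilies(x, fmap = fmap)
    flines <- c("family\tabundance_pct\tn_proteins",
                paste(fam$family, .fmtNum(fam$abundance), fam$n_proteins,
                      sep = "\t"))
    writeLines(flines, familyPath, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname writeAbundanceTable
#' @param x An \linkS4class{AbundanceTable}.
#' @export
readAbundanceTable <- function(path) {
  df <- .readTable(path, sep = "\t", what = "abundance")
  .requireColumns(df, c("venom_id", "accession", "protein_name", "family",
                        "fraction_id", "abundance_pct"), "abundance", path)
  unid <- df$accession == "(unidentified)"
  unidShare <- if (any(unid)) sum(df$abundance_pct[unid]) else 0
  p <- df[!unid, , drop = FALSE]
  empty2na <- function(v) {
    v <- as.character(v)
    v[!nzchar(v) | is.na(v)] <- NA_character_
    v
  }
  AbundanceTable(
    data.frame(accession = as.character(p$accession),
               protein_name = as.character(p$protein_name),
               family = empty2na(p$family),
               fraction_id = empty2na(p$fraction_id),
               abundance = as.numeric(p$abundance_pct),
               stringsAsFactors = FALSE),
    unidentifiedShare = unidShare,
    venomId = as.character(df$venom_id[1L]))
}

#' Write a venom comparison as JSON
#'
#' @param cmp A \linkS4class{VenomComparison}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeComparison <- function(cmp, path) {
  stopifnot(is(cmp, "VenomComparison"))
  out <- list(
    venom_a = cmp@venoms[1L],
    venom_b = cmp@venoms[2L],
    families = cmp@families,
    counts = cmp@counts,
    unique_to_a = cmp@families$family[cmp@families$status == "unique_to_a"],
    unique_to_b = cmp@families$family[cmp@families$status == "unique_to_b"])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Render abundances as percent strings with two decimals
#'
#' @param x Numeric vector of percentages.
#' @return Character vector formatted to 2 decimal places.
#' @export
formatAbundance <- function(x) sprintf("%.2f", x)
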