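## Curated reference dataset: per-protein whole-venom abundances of two
## Daboia siamensis venom proteomes (a Thailand and an Indonesia
## population), transcribed from a published comparative decomplexing
## venomics study, together with the per-fraction area percentages of both
## RP-HPLC runs. Values are percent of total venom protein as printed
## (2 dp); the Indonesian proteome carries an unidentified bucket from two
## fractions whose proteins defied MS identification.

.referenceCsv <- function(name) {
  path <- system.file("extdata", name, package = "decomplexR",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, quote = "\"",
                  check.names = FALSE)
}

#' Reference D. siamensis venom proteomes (Thailand vs Indonesia)
#'
#' Returns the packaged per-protein transcription of a published
#' comparative venomics dataset for two geographically distant
#' \emph{Daboia siamensis} populations: 47 non-redundant proteins in nine
#' toxin families (Thailand) and 25 proteins in nine families plus a
#' 16.44\% unidentified bucket (Indonesia). Useful for exercising family
#' aggregation, non-redundant counting and venom comparison on real
#' numbers without any MS data.
#'
#' @return List with elements \code{thailand} and \code{indonesia}
#'   (\linkS4class{AbundanceTable}s) and \code{familyMap}
#'   (\linkS4class{FamilyMap} covering every accession).
#' @export
#' @examples
#' ref <- referenceProteomes()
#' aggregateFamilies(ref$thailand)[1:3, ]
referenceProteomes <- function() {
  df <- .referenceCsv("ds_venom_reference_proteins.csv")
  unid <- df$accession == "(unidentified)"
  unidIndo <- sum(df$indonesia_pct[unid], na.rm = TRUE)
  p <- df[!unid, , drop = FALSE]
  fmap <- FamilyMap(stats::setNames(p$family, p$accession))
  mk <- function(col, venom, unidShare) {
    keep <- !is.na(p[[col]])
    AbundanceTable(
      data.frame(accession = p$accession[keep],
                 protein_name = p$protein_name[keep],
                 family = p$family[keep],
                 fraction_id = NA_character_,
                 abundance = p[[col]][keep],
                 stringsAsFactors = FALSE),
      unidentifiedShare = unidShare, venomId = venom)
  }
  list(thailand = mk("thailand_pct", "Ds-Thailand", 0),
       indonesia = mk("indonesia_pct", "Ds-Indonesia", unidIndo),
       familyMap = fmap)
}

#' Reference per-fraction area percentages
#'
#' Per-fraction percentages of both reference RP-HPLC runs as printed in
#' the source tables (Thailand F4-F16; Indonesia F4-F12 with fractions F6
#' and F11 collected but MS-unidentified). These are transcribed values:
#' the Thailand run sums to 100.00 but the Indonesian fraction headers
#' carry a transcription inconsistency and do not (so they are returned as
#' a plain data.frame, not a \linkS4class{FractionShareTable}).
#'
#' @return data.frame with columns \code{venom}, \code{fraction_id},
#'   \code{share_pct}, \code{identified}.
#' @export
referenceFractionShares <- function() {
  df <- .referenceCsv("ds_venom_reference_fractions.csv")
  df$identified <- as.logical(df$identified)
  df
}
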