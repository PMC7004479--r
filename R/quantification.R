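## MSI-based quantification. Within each chromatographic fraction a
## protein's abundance is its mean spectral intensity (MSI, the mean of its
## peptide PSM intensities) relative to the total MSI of all proteins in
## that fraction. Whole-venom abundance is hierarchical: the fraction's
## chromatographic area share times the protein's within-fraction MSI
## proportion. This reading is forced by the equal-mass digestion of every
## fraction (the same protein amount enters MS regardless of how large the
## fraction is), which makes within-fraction proportions the only
## MS-observable signal; a literal global-MSI normalisation is available
## for comparison via globalMsiAbundance().

#' Within-fraction MSI proportions
#'
#' For each fraction, computes every protein's MSI (mean of its peptide
#' spectral intensities) and its proportion of the fraction's total MSI.
#' Duplicate entries of one accession within a fraction are merged by
#' pooling their peptides when \code{mergeDuplicates} is on (default);
#' otherwise rows are grouped by (accession, protein name).
#'
#' @param psms A validated (filtered, decoy-free) \linkS4class{PsmTable};
#'   any remaining decoy rows are dropped.
#' @param mergeDuplicates Pool duplicate accession entries (default TRUE).
#' @return data.frame with columns \code{fraction_id}, \code{accession},
#'   \code{protein_name}, \code{species}, \code{n_psms}, \code{msi},
#'   \code{proportion}; proportions sum to 1 within each fraction.
#' @export
withinFractionAbundance <- function(psms, mergeDuplicates = TRUE) {
  stopifnot(is(psms, "PsmTable"))
  p <- psms@psms
  p <- p[!p$is_decoy, , drop = FALSE]
  if (nrow(p) == 0L)
    dcxError("dcx_empty_fraction", "no target PSMs to quantify")
  key <- if (mergeDuplicates) p$accession else
    paste(p$accession, p$protein_name, sep = "\r")
  res <- lapply(split(seq_len(nrow(p)), p$fraction_id), function(idx) {
    q <- p[idx, , drop = FALSE]
    k <- key[idx]
    groups <- split(seq_len(nrow(q)), k)
    msi <- vapply(groups, function(g) mean(q$intensity[g]), numeric(1))
    first <- vapply(groups, function(g) g[1L], integer(1))
    total <- sum(msi)
    if (total <= 0)
      dcxError("dcx_empty_fraction",
               sprintf("fraction %s has zero total MSI", q$fraction_id[1L]))
    data.frame(fraction_id = q$fraction_id[1L],
               accession = q$accession[first],
               protein_name = q$protein_name[first],
               species = q$species[first],
               n_psms = vapply(groups, length, integer(1)),
               msi = msi,
               proportion = msi / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Whole-venom abundance from fraction shares and MSI proportions
#'
#' The hierarchical estimator: a protein's whole-venom abundance (percent
#' of total venom protein) is \code{100 * f_i * p_ij}, the fraction's
#' chromatographic area share times the protein's within-fraction MSI
#' proportion. Collected fractions with no identified proteins contribute
#' their full share to the unidentified bucket, so all abundances plus the
#' bucket sum to 100.
#'
#' @param shareTable A \linkS4class{FractionShareTable}.
#' @param wft Within-fraction table from
#'   \code{\link{withinFractionAbundance}}.
#' @param unidentified Character vector of collected-but-unidentified
#'   fraction ids.
#' @param venomId Label for the resulting table.
#' @return An \linkS4class{AbundanceTable}.
#' @export
wholeVenomAbundance <- function(shareTable, wft,
                                unidentified = character(),
                                venomId = "venom") {
  stopifnot(is(shareTable, "FractionShareTable"), is.data.frame(wft))
  s <- shareTable@shares
  fr_wft <- unique(wft$fraction_id)
  missing_share <- setdiff(fr_wft, names(s))
  if (length(missing_share))
    dcxError("dcx_missing_share",
             paste("fraction(s) with PSMs but no chromatographic share:",
                   paste(missing_share, collapse = ", ")))
  silent <- setdiff(names(s), c(fr_wft, unidentified))
  if (length(silent)) {
    dcxWarn("dcx_unassigned_fraction",
            paste("collected fraction(s) with a share but no PSMs treated",
                  "as unidentified:", paste(silent, collapse = ", ")))
    unidentified <- c(unidentified, silent)
  }
  bad_unid <- intersect(unidentified, fr_wft)
  if (length(bad_unid))
    dcxError("dcx_config_error",
             paste("fraction(s) declared unidentified but carrying PSMs:",
                   paste(bad_unid, collapse = ", ")))
  proteins <- data.frame(
    accession = wft$accession,
    protein_name = wft$protein_name,
    family = NA_character_,
    fraction_id = wft$fraction_id,
    abundance = 100 * unname(s[wft$fraction_id]) * wft$proportion,
    stringsAsFactors = FALSE)
  AbundanceTable(proteins,
                 unidentifiedShare = 100 * sum(s[intersect(unidentified,
                                                           names(s))]),
                 venomId = venomId)
}

#' Whole-venom abundance by global MSI normalisation
#'
#' The non-hierarchical alternative: each protein's pooled MSI is
#' normalised by the total MSI over all fractions, ignoring
#' chromatographic shares. Provided for comparison with
#' \code{\link{wholeVenomAbundance}}; it cannot attribute abundance to
#' MS-unidentified fractions.
#'
#' @param wft Within-fraction table from
#'   \code{\link{withinFractionAbundance}}.
#' @param venomId Label for the resulting table.
#' @return An \linkS4class{AbundanceTable} with zero unidentified share.
#' @export
globalMsiAbundance <- function(wft, venomId = "venom") {
  stopifnot(is.data.frame(wft))
  total <- sum(wft$msi)
  if (total <= 0)
    dcxError("dcx_empty_fraction", "zero total MSI")
  proteins <- data.frame(
    accession = wft$accession,
    protein_name = wft$protein_name,
    family = NA_character_,
    fraction_id = wft$fraction_id,
    abundance = 100 * wft$msi / total,
    stringsAsFactors = FALSE)
  AbundanceTable(proteins, unidentifiedShare = 0, venomId = venomId)
}

.familyTotals <- function(table, fmap = NULL) {
  p <- table@proteins
  fam <- p$family
  if (!is.null(fmap)) fam <- lookupFamily(fmap, p$accession)
  if (anyNA(fam))
    dcxError("dcx_vocabulary_error",
             "table rows carry no family assignment and no family map given")
  fam
}

#' Aggregate whole-venom abundances by toxin family
#'
#' Family abundance is the sum of the member proteins' whole-venom
#' percentages across all fractions. Output is sorted by descending
#' abundance (ties broken by family label).
#'
#' @param table An \linkS4class{AbundanceTable}.
#' @param fmap Optional \linkS4class{FamilyMap}; when omitted the table's
#'   own family column is used. Unmapped accessions go to OTHER with a
#'   warning.
#' @param all Include vocabulary families with no member rows (as zero)?
#'   Default FALSE.
#' @return data.frame with columns \code{family}, \code{abundance}
#'   (percent) and \code{n_proteins} (distinct accessions with positive
#'   abundance).
#' @export
aggregateFamilies <- function(table, fmap = NULL, all = FALSE) {
  stopifnot(is(table, "AbundanceTable"))
  fam <- .familyTotals(table, fmap)
  p <- table@proteins
  ab <- vapply(split(p$abundance, fam), sum, numeric(1))
  np <- vapply(split(seq_len(nrow(p)), fam), function(idx)
    length(unique(p$accession[idx][p$abundance[idx] > 0])), integer(1))
  out <- data.frame(family = names(ab), abundance = unname(ab),
                    n_proteins = unname(np), stringsAsFactors = FALSE)
  if (all) {
    absent <- setdiff(toxinFamilies(), out$family)
    if (length(absent))
      out <- rbind(out, data.frame(family = absent, abundance = 0,
                                   n_proteins = 0L,
                                   stringsAsFactors = FALSE))
  }
  out <- out[order(-out$abundance, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Non-redundant protein and family counts
#'
#' Counts distinct accessions with positive whole-venom abundance, the
#' number of detected families, and the per-family breakdown.
#'
#' @param table An \linkS4class{AbundanceTable}.
#' @param fmap Optional \linkS4class{FamilyMap} (see
#'   \code{\link{aggregateFamilies}}).
#' @return List with \code{proteins} (integer), \code{families} (integer)
#'   and \code{perFamily} (data.frame \code{family}, \code{n_proteins}).
#' @export
countNonredundant <- function(table, fmap = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  p <- table@proteins
  detected <- p$abundance > 0
  fam <- aggregateFamilies(table, fmap = fmap)
  fam <- fam[fam$abundance > 0, , drop = FALSE]
  list(proteins = length(unique(p$accession[detected])),
       families = nrow(fam),
       perFamily = data.frame(family = fam$family,
                              n_proteins = fam$n_proteins,
                              stringsAsFactors = FALSE))
}

#' Compare the family composition of two venoms
#'
#' Families detected in only one venom are flagged \code{unique_to_a} /
#' \code{unique_to_b} (abundance exactly zero in the other); families with
#' positive abundance in both are \code{shared}. Also reports per-venom
#' non-redundant protein and family counts.
#'
#' @param a,b \linkS4class{AbundanceTable}s for the two venoms (same
#'   family map / vocabulary).
#' @param fmap Optional \linkS4class{FamilyMap} applied to both tables.
#' @return A \linkS4class{VenomComparison}.
#' @export
compareVenoms <- function(a, b, fmap = NULL) {
  stopifnot(is(a, "AbundanceTable"), is(b, "AbundanceTable"))
  fa <- aggregateFamilies(a, fmap = fmap, all = TRUE)
  fb <- aggregateFamilies(b, fmap = fmap, all = TRUE)
  m <- merge(fa[, c("family", "abundance")],
             fb[, c("family", "abundance")],
             by = "family", suffixes = c("_a", "_b"))
  m <- m[m$abundance_a > 0 | m$abundance_b > 0, , drop = FALSE]
  m$delta <- m$abundance_a - m$abundance_b
  m$status <- ifelse(m$abundance_a > 0 & m$abundance_b == 0, "unique_to_a",
              ifelse(m$abundance_b > 0 & m$abundance_a == 0, "unique_to_b",
                     "shared"))
  m <- m[order(-pmax(m$abundance_a, m$abundance_b), m$family), ,
         drop = FALSE]
  rownames(m) <- NULL
  ca <- countNonredundant(a, fmap = fmap)
  cb <- countNonredundant(b, fmap = fmap)
  new("VenomComparison",
      venoms = c(a@venomId, b@venomId),
      families = m,
      counts = data.frame(venom = c(a@venomId, b@venomId),
                          proteins = c(ca$proteins, cb$proteins),
                          families = c(ca$families, cb$families),
                          stringsAsFactors = FALSE))
}
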