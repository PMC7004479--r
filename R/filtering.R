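## PSM validation: the fixed score/SPI filter cascade and target-decoy FDR
## control on the peptide score. The cascade uses strict inequalities
## (protein score > 20, peptide score > 10, SPI > 70% by default); FDR is
## controlled at PSM level with the decoy/target ratio estimator and a
## q-value (running-minimum) smoothing of the curve.

#' Apply the score/SPI validation cascade
#'
#' Retains PSMs with \code{protein_score > minProteinScore},
#' \code{peptide_score > minPeptideScore} and \code{spi > minSpi}, all
#' strict. Decoy PSMs are subject to the same cascade and kept for
#' downstream FDR estimation.
#'
#' @param psms A \linkS4class{PsmTable}.
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @return A filtered \linkS4class{PsmTable} (subset of the input).
#' @export
#' @examples
#' p <- PsmTable(data.frame(
#'   fraction_id = "F1", accession = "P1", protein_name = "x",
#'   species = "s", peptide = "PEP", protein_score = 20.01,
#'   peptide_score = 10.5, spi = 71, intensity = 100, is_decoy = FALSE))
#' length(applyScoreFilters(p))  # 1: all three strict filters passed
applyScoreFilters <- function(psms, thresholds = FilterThresholds()) {
  stopifnot(is(psms, "PsmTable"), is(thresholds, "FilterThresholds"))
  p <- psms@psms
  keep <- p$protein_score > thresholds@minProteinScore &
    p$peptide_score > thresholds@minPeptideScore &
    p$spi > thresholds@minSpi
  new("PsmTable", psms = {
    q <- p[keep, , drop = FALSE]
    rownames(q) <- NULL
    q
  })
}

#' Estimate the target-decoy FDR curve
#'
#' For every candidate cutoff c (the sorted unique peptide scores), the raw
#' estimate is \code{fdr(c) = #decoys with score >= c / max(1, #targets
#' with score >= c)}. The smoothed column applies the q-value convention
#' \code{fdr_smoothed(c) = min over c' <= c of fdr(c')}, which is monotone
#' non-increasing in the cutoff and guarantees a well-defined lowest
#' passing cutoff.
#'
#' @param psms A \linkS4class{PsmTable} with decoy flags.
#' @return data.frame with columns \code{cutoff}, \code{n_target},
#'   \code{n_decoy}, \code{fdr_raw}, \code{fdr}. When the table contains no
#'   decoys a warning is raised, the curve is all zero and the attribute
#'   \code{no_decoys} is set; a pure-decoy table sets \code{all_decoys}.
#' @export
estimateFdrCurve <- function(psms) {
  stopifnot(is(psms, "PsmTable"))
  p <- psms@psms
  if (nrow(p) == 0L)
    dcxError("dcx_schema_error", "cannot estimate FDR from an empty table")
  cutoffs <- sort(unique(p$peptide_score))
  scores_t <- sort(p$peptide_score[!p$is_decoy])
  scores_d <- sort(p$peptide_score[p$is_decoy])
  ## count of scores >= c, exactly (left-open intervals count scores < c)
  nt <- length(scores_t) - findInterval(cutoffs, scores_t, left.open = TRUE)
  nd <- length(scores_d) - findInterval(cutoffs, scores_d, left.open = TRUE)
  if (length(scores_d) == 0L) {
    dcxWarn("dcx_no_decoys",
            "no decoy PSMs present; FDR reported as 0 at every cutoff")
    curve <- data.frame(cutoff = cutoffs, n_target = nt, n_decoy = 0L,
                        fdr_raw = 0, fdr = 0)
    attr(curve, "no_decoys") <- TRUE
    return(curve)
  }
  raw <- nd / pmax(1L, nt)
  curve <- data.frame(cutoff = cutoffs, n_target = nt, n_decoy = nd,
                      fdr_raw = raw, fdr = cummin(raw))
  if (length(scores_t) == 0L) attr(curve, "all_decoys") <- TRUE
  curve
}

#' Filter PSMs at a target FDR
#'
#' Chooses the lowest peptide-score cutoff whose smoothed FDR estimate is
#' strictly below \code{maxFdr}, retains all PSMs with
#' \code{peptide_score >= cutoff} (ties at the cutoff are retained), and
#' removes decoys from the output.
#'
#' @param psms A \linkS4class{PsmTable}, typically already passed through
#'   \code{\link{applyScoreFilters}}.
#' @param maxFdr FDR bound (default 0.01).
#' @return List with elements \code{psms} (target PSMs passing the cutoff),
#'   \code{cutoff} (chosen peptide-score cutoff), \code{achievedFdr} (raw
#'   decoy/target ratio at the cutoff) and \code{curve}.
#' @export
filterAtFdr <- function(psms, maxFdr = 0.01) {
  stopifnot(is(psms, "PsmTable"))
  curve <- estimateFdrCurve(psms)
  pass <- which(curve$fdr < maxFdr)
  if (!length(pass))
    dcxError("dcx_fdr_unattainable",
             sprintf("no peptide-score cutoff achieves FDR < %g", maxFdr))
  cutoff <- curve$cutoff[pass[1L]]
  p <- psms@psms
  keep <- !p$is_decoy & p$peptide_score >= cutoff
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(psms = new("PsmTable", psms = out),
       cutoff = cutoff,
       achievedFdr = curve$fdr_raw[pass[1L]],
       curve = curve)
}

#' Run the full PSM validation (cascade plus FDR control)
#'
#' By default the fixed score/SPI cascade runs first and FDR is then
#' controlled on the surviving PSMs; \code{order = "fdr_then_cascade"}
#' flips the two stages.
#'
#' @param psms A \linkS4class{PsmTable}.
#' @param thresholds A \linkS4class{FilterThresholds} (its \code{maxFdr}
#'   slot sets the FDR bound).
#' @param order Stage order.
#' @return List with \code{psms} (validated target PSMs), \code{cutoff},
#'   \code{achievedFdr}, \code{curve} and a \code{report} data.frame of
#'   per-stage input/output counts.
#' @export
filterPsms <- function(psms, thresholds = FilterThresholds(),
                       order = c("cascade_then_fdr", "fdr_then_cascade")) {
  stopifnot(is(psms, "PsmTable"))
  order <- match.arg(order)
  n0 <- length(psms)
  if (order == "cascade_then_fdr") {
    cascaded <- applyScoreFilters(psms, thresholds)
    n1 <- length(cascaded)
    fdr <- filterAtFdr(cascaded, maxFdr = thresholds@maxFdr)
    n2 <- length(fdr$psms)
    stages <- c("score_cascade", "fdr_control")
    ins <- c(n0, n1); outs <- c(n1, n2)
  } else {
    fdr <- filterAtFdr(psms, maxFdr = thresholds@maxFdr)
    n1 <- length(fdr$psms)
    cascaded <- applyScoreFilters(fdr$psms, thresholds)
    n2 <- length(cascaded)
    stages <- c("fdr_control", "score_cascade")
    ins <- c(n0, n1); outs <- c(n1, n2)
    fdr$psms <- cascaded
  }
  list(psms = fdr$psms, cutoff = fdr$cutoff, achievedFdr = fdr$achievedFdr,
       curve = fdr$curve,
       report = data.frame(stage = stages, n_in = ins, n_out = outs,
                           stringsAsFactors = FALSE))
}
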