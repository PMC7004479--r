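## Immunoprofiling: indirect ELISA readings (A492) of antivenoms against
## HPLC venom fractions. Blank-corrected triplicate means with SEM,
## two-regime reactivity classification, and relative immunoreactivity
## between two antivenoms.

#' Summarise an ELISA plate
#'
#' Subtracts the plate-wide blank mean from every reading (negatives
#' clipped to 0) and reports mean, SEM (sd divided by the square root of
#' n) and replicate count per (fraction, antivenom) cell. Control-antigen
#' cells are carried through with their flag.
#'
#' @param plate An \linkS4class{ElisaPlate}.
#' @return data.frame with columns \code{fraction_id}, \code{antivenom},
#'   \code{is_control}, \code{n}, \code{mean}, \code{sem} (NA with a
#'   warning for single-replicate cells).
#' @export
#' @examples
#' p <- ElisaPlate(data.frame(
#'   fraction_id = c(rep("F1", 3), "blank"), antivenom = "AV",
#'   replicate = c(1:3, 1), a492 = c(0.5, 0.6, 0.7, 0),
#'   is_blank = c(FALSE, FALSE, FALSE, TRUE), is_control = FALSE))
#' summarizePlate(p)  # mean 0.6, sem 0.0577
summarizePlate <- function(plate) {
  stopifnot(is(plate, "ElisaPlate"))
  w <- plate@wells
  if (!any(w$is_blank))
    dcxError("dcx_no_blank", "plate contains no blank well")
  blank <- mean(w$a492[w$is_blank])
  cells <- w[!w$is_blank, , drop = FALSE]
  cells$corrected <- pmax(cells$a492 - blank, 0)
  key <- paste(cells$fraction_id, cells$antivenom, sep = "\r")
  groups <- split(seq_len(nrow(cells)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    g <- cells[idx, , drop = FALSE]
    n <- nrow(g)
    data.frame(fraction_id = g$fraction_id[1L],
               antivenom = g$antivenom[1L],
               is_control = g$is_control[1L],
               n = n,
               mean = mean(g$corrected),
               sem = if (n >= 2L) stats::sd(g$corrected) / sqrt(n)
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n < 2L))
    dcxWarn("dcx_single_replicate",
            paste("single-replicate cell(s), SEM undefined:",
                  paste(out$fraction_id[out$n < 2L], collapse = ", ")))
  out <- out[order(out$antivenom, out$is_control, out$fraction_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify blank-corrected reactivity
#'
#' Two observed regimes: absorbance below 0.1 is \code{"low"}, 0.2 and
#' above (typically up to ~1.5) is \code{"reactive"}; the gap [0.1, 0.2)
#' is labelled \code{"indeterminate"} rather than forced onto a single
#' sharp threshold.
#'
#' @param mean_a492 Numeric vector of blank-corrected mean absorbances;
#'   must be non-negative.
#' @return Character vector in \{low, indeterminate, reactive\}.
#' @export
#' @examples
#' classifyReactivity(c(0.05, 0.15, 0.6))
classifyReactivity <- function(mean_a492) {
  if (any(is.na(mean_a492) | mean_a492 < 0))
    dcxError("dcx_contract_violation",
             "blank-corrected means must be non-negative and non-missing")
  ifelse(mean_a492 < 0.1, "low",
         ifelse(mean_a492 >= 0.2, "reactive", "indeterminate"))
}

#' Relative immunoreactivity between two antivenoms
#'
#' Expresses the comparator antivenom's blank-corrected mean as a
#' percentage of the reference antivenom's, fraction by fraction. When the
#' reference mean is below \code{floor} the ratio is undefined and flagged
#' rather than reported as a blow-up.
#'
#' @param reference,comparator data.frames as returned by
#'   \code{\link{summarizePlate}} (one antivenom each; control rows are
#'   ignored). Fraction sets must match.
#' @param floor Reference absorbance below which the ratio is undefined
#'   (default 0.02, the instrument noise scale).
#' @return data.frame with columns \code{fraction_id},
#'   \code{reference_mean}, \code{comparator_mean}, \code{relative_pct}
#'   (NA when undefined), \code{undefined}.
#' @export
relativeImmunoreactivity <- function(reference, comparator, floor = 0.02) {
  ref <- reference[!reference$is_control, , drop = FALSE]
  cmp <- comparator[!comparator$is_control, , drop = FALSE]
  if (!setequal(ref$fraction_id, cmp$fraction_id))
    dcxError("dcx_alignment_error",
             "reference and comparator profiles cover different fractions")
  m <- merge(ref[, c("fraction_id", "mean")],
             cmp[, c("fraction_id", "mean")],
             by = "fraction_id", suffixes = c("_ref", "_cmp"))
  undef <- m$mean_ref < floor
  out <- data.frame(fraction_id = m$fraction_id,
                    reference_mean = m$mean_ref,
                    comparator_mean = m$mean_cmp,
                    relative_pct = ifelse(undef, NA_real_,
                                          100 * m$mean_cmp / m$mean_ref),
                    undefined = undef,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Check control antigens on a summarised plate
#'
#' Negative-control antigens must classify \code{low}; positive controls
#' must classify \code{reactive}. This is a report, not a gate: failures
#' are flagged, no error is raised.
#'
#' @param summary data.frame from \code{\link{summarizePlate}}.
#' @param negative,positive Character vectors of control antigen
#'   \code{fraction_id}s expected to be non-reactive / reactive.
#' @return data.frame with columns \code{fraction_id}, \code{antivenom},
#'   \code{mean}, \code{class}, \code{expected}, \code{pass}; one row per
#'   control cell.
#' @export
controlCheck <- function(summary, negative = character(),
                         positive = character()) {
  ctrl <- summary[summary$is_control |
                    summary$fraction_id %in% c(negative, positive), ,
                  drop = FALSE]
  if (nrow(ctrl) == 0L)
    return(data.frame(fraction_id = character(), antivenom = character(),
                      mean = numeric(), class = character(),
                      expected = character(), pass = logical(),
                      stringsAsFactors = FALSE))
  cls <- classifyReactivity(ctrl$mean)
  expected <- ifelse(ctrl$fraction_id %in% negative, "low",
              ifelse(ctrl$fraction_id %in% positive, "reactive",
                     NA_character_))
  out <- data.frame(fraction_id = ctrl$fraction_id,
                    antivenom = ctrl$antivenom,
                    mean = ctrl$mean,
                    class = cls,
                    expected = expected,
                    pass = !is.na(expected) & cls == expected,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
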