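## Chromatogram processing: baseline correction, trapezoidal integration of
## manually collected fraction windows into area shares, and an optional
## prominence-based peak detector for automatic windowing.

#' Baseline-correct a chromatogram
#'
#' \code{linear_endpoints} subtracts the straight line through the first
#' and last sampled points; \code{rolling_min} subtracts a centred rolling
#' minimum of the trace (window in minutes). Corrected absorbances are
#' clipped at zero.
#'
#' @param chrom A \linkS4class{Chromatogram}.
#' @param method Baseline model; default \code{"linear_endpoints"}.
#' @param window Rolling-minimum window in minutes (only for
#'   \code{"rolling_min"}).
#' @return A baseline-corrected \linkS4class{Chromatogram}.
#' @export
#' @examples
#' ch <- Chromatogram(0:10, rep(5, 11))
#' absorbance(correctBaseline(ch))  # all zero
correctBaseline <- function(chrom,
                            method = c("linear_endpoints", "rolling_min"),
                            window = 15) {
  stopifnot(is(chrom, "Chromatogram"))
  method <- match.arg(method)
  t <- chrom@time
  a <- chrom@absorbance
  n <- length(t)
  baseline <- switch(method,
    linear_endpoints = {
      a[1L] + (a[n] - a[1L]) * (t - t[1L]) / (t[n] - t[1L])
    },
    rolling_min = {
      dt <- stats::median(diff(t))
      half <- max(1L, as.integer(round(window / dt / 2)))
      vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half)
        hi <- min(n, i + half)
        min(a[lo:hi])
      }, numeric(1))
    })
  Chromatogram(time = t, absorbance = pmax(a - baseline, 0),
               meta = chrom@meta)
}

.windowArea <- function(t, a, start, end) {
  ## trapezoidal area over [start, end], with linearly interpolated
  ## boundary ordinates so the result does not depend on whether a sample
  ## falls exactly on a window edge
  inside <- t > start & t < end
  tt <- c(start, t[inside], end)
  aa <- c(stats::approx(t, a, xout = start)$y, a[inside],
          stats::approx(t, a, xout = end)$y)
  pracma::trapz(tt, aa)
}

#' Integrate fraction windows into area shares
#'
#' Each collected fraction's trapezoidal area over its half-open window
#' \code{[start, end)} is divided by the total area over all collected
#' fractions, giving the proportion of venom protein eluting in that
#' fraction. Uncollected windows are excluded from the denominator.
#'
#' @param chrom A (typically baseline-corrected) \linkS4class{Chromatogram}.
#' @param bounds A \linkS4class{FractionBoundarySet} within the trace's
#'   time range.
#' @return A \linkS4class{FractionShareTable} over the collected fractions.
#' @export
#' @examples
#' t <- seq(0, 60, 0.1)
#' ch <- Chromatogram(t, 3 * dnorm(t, 20, 2) + dnorm(t, 40, 2))
#' fb <- FractionBoundarySet(c("F1", "F2"), c(5, 30), c(30, 55))
#' shares(integrateFractions(ch, fb))  # ~0.75 / 0.25
integrateFractions <- function(chrom, bounds) {
  stopifnot(is(chrom, "Chromatogram"), is(bounds, "FractionBoundarySet"))
  b <- bounds@boundaries
  if (nrow(b) == 0L)
    dcxError("dcx_bounds_error", "no fraction boundaries supplied")
  t <- chrom@time
  lo <- min(t); hi <- max(t)
  out <- which(b$start < lo - 1e-9 | b$end > hi + 1e-9)
  if (length(out))
    dcxError("dcx_bounds_error",
             sprintf("boundary window(s) outside trace range [%g, %g]: %s",
                     lo, hi, paste(b$fraction_id[out], collapse = ", ")),
             rows = out)
  areas <- mapply(.windowArea, start = b$start, end = b$end,
                  MoreArgs = list(t = t, a = chrom@absorbance))
  areas <- pmax(areas, 0)
  coll <- b$collected
  total <- sum(areas[coll])
  if (!any(coll) || total <= 0)
    dcxError("dcx_no_signal",
             "total integrated area over collected fractions is zero")
  FractionShareTable(stats::setNames(areas[coll] / total,
                                     b$fraction_id[coll]))
}

.peakProminence <- function(a, peaks) {
  n <- length(a)
  vapply(peaks, function(i) {
    h <- a[i]
    ## walk left/right to the nearest higher point (or edge); prominence is
    ## the height above the higher of the two intervening minima
    lmin <- h
    j <- i - 1L
    while (j >= 1L && a[j] <= h) {
      lmin <- min(lmin, a[j])
      j <- j - 1L
    }
    if (j < 1L) lmin <- min(a[1:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && a[j] <= h) {
      rmin <- min(rmin, a[j])
      j <- j + 1L
    }
    if (j > n) rmin <- min(a[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect peaks and derive fraction windows
#'
#' Local maxima with topographic prominence of at least
#' \code{minProminence} become fractions; window edges are placed at the
#' absorbance minima between consecutive retained peaks (and at the
#' flanking minima of the first/last peak). Intended as an automatic
#' alternative to manually recorded collection windows.
#'
#' @param chrom A baseline-corrected \linkS4class{Chromatogram}.
#' @param minProminence Minimum peak prominence in mAU (default 5).
#' @return A \linkS4class{FractionBoundarySet}; empty when no peak exceeds
#'   the prominence threshold.
#' @export
detectPeaks <- function(chrom, minProminence = 5) {
  stopifnot(is(chrom, "Chromatogram"))
  t <- chrom@time
  a <- chrom@absorbance
  n <- length(a)
  emptySet <- FractionBoundarySet(character(), numeric(), numeric(),
                                  logical())
  if (n < 3L) return(emptySet)
  d <- diff(a)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(emptySet)
  prom <- .peakProminence(a, cand)
  peaks <- cand[prom >= minProminence]
  if (!length(peaks)) return(emptySet)
  k <- length(peaks)
  edges <- integer(k + 1L)
  edges[1L] <- which.min(a[1:peaks[1L]])
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      seg <- peaks[j]:peaks[j + 1L]
      edges[j + 1L] <- seg[which.min(a[seg])]
    }
  }
  edges[k + 1L] <- (peaks[k]:n)[which.min(a[peaks[k]:n])]
  FractionBoundarySet(sprintf("F%d", seq_len(k)),
                      start = t[edges[seq_len(k)]],
                      end = t[edges[seq_len(k) + 1L]])
}
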