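#' @include AllClasses.R
NULL

#' Construct a Spectrum from vectors
#'
#' @param mzValues Numeric m/z values (Da); sorted on construction.
#' @param intensities Numeric non-negative intensities.
#' @param label Label; defaults to "".
#' @param sourcePath Provenance path; "" for in-memory spectra.
#' @return A \linkS4class{Spectrum}.
#' @export
newSpectrum <- function(mzValues, intensities, label = "", sourcePath = "") {
  ord <- order(mzValues)
  new("Spectrum", mz = as.numeric(mzValues[ord]),
      intensity = as.numeric(intensities[ord]),
      label = label, sourcePath = sourcePath)
}

#' Read a two-column ASCII mass spectrum
#'
#' Accepts the plain-text export format of most MALDI-TOF vendors: one
#' (m/z, intensity) pair per line, whitespace- or comma-separated, with
#' \code{#}-prefixed comment lines and blank lines ignored. Rows are sorted
#' by m/z.
#'
#' @param path Path to the ASCII file.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A \linkS4class{Spectrum}.
#' @export
readAsciiSpectrum <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data lines in spectrum file: ", path)
  fields <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  n <- lengths(fields)
  bad <- which(n != 2L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected two numeric columns",
                 keep[bad[1]], path))
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(2)))
  if (any(!is.finite(vals[1, ])) || any(is.na(vals[2, ]))) {
    bad <- which(!is.finite(vals[1, ]) | is.na(vals[2, ]))[1]
    stop(sprintf("malformed line %d in %s: non-numeric value", keep[bad], path))
  }
  newSpectrum(vals[1, ], vals[2, ], label = label, sourcePath = path)
}

#' Integrated peak area in a fixed window
#'
#' Trapezoidal integral of the intensity over
#' [center - halfWidth, center + halfWidth], with linear interpolation of
#' the signal at the window edges. The default half-width of 0.3 Da matches
#' the conventional "theoretical mass +/- 0.3 Da" quantification window for
#' 1 Da-spaced isotopic peaks.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param center Window center (Da).
#' @param halfWidth Window half-width (Da), > 0; default 0.3.
#' @return Non-negative area; 0 (with a warning) when the window lies
#'   outside the recorded m/z range.
#' @export
peakArea <- function(spectrum, center, halfWidth = 0.3) {
  stopifnot(halfWidth > 0)
  lo <- center - halfWidth
  hi <- center + halfWidth
  x <- spectrum@mz; y <- spectrum@intensity
  if (hi <= x[1] || lo >= x[length(x)]) {
    warning(sprintf("window [%.3f, %.3f] outside spectrum range; area = 0",
                    lo, hi))
    return(0)
  }
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  inside <- which(x > lo & x < hi)
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}

#' Quantify all theoretical isotopic peaks of a fragment
#'
#' Integrates the spectrum in a +/- halfWidth window around every peak
#' center of the fragment's basis-envelope grid, yielding the observation
#' vector for the mixture fit.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param fragment The \linkS4class{PeptideFragment} being quantified.
#' @param basis Basis envelopes from \code{\link{basisEnvelopes}} (all on a
#'   common grid).
#' @param halfWidth Integration half-width (Da), default 0.3. Widths >= 0.5
#'   make neighboring 1 Da windows overlap; a warning is issued and the
#'   integration proceeds.
#' @return A \linkS4class{PeakVector}.
#' @export
extractPeakVector <- function(spectrum, fragment, basis, halfWidth = 0.3) {
  stopifnot(length(basis) >= 1L)
  centers <- basis[[1]]@mz
  if (halfWidth >= min(diff(centers)) / 2)
    warning("integration windows overlap at this half-width; proceeding")
  areas <- vapply(centers, function(cc)
    suppressWarnings(peakArea(spectrum, cc, halfWidth)), numeric(1))
  areas[areas < 0] <- 0
  new("PeakVector", fragment = fragment, centers = centers, areas = areas,
      halfWidth = halfWidth)
}

#' Intensity-weighted average mass in a window
#'
#' The centroid (first moment) of the signal between two m/z bounds, as used
#' for linear-mode peptides whose isotopic peaks are not resolved.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param windowLo,windowHi Window bounds (Da), windowLo < windowHi.
#' @return Centroid m/z (Da).
#' @export
averageMass <- function(spectrum, windowLo, windowHi) {
  stopifnot(windowLo < windowHi)
  sel <- spectrum@mz >= windowLo & spectrum@mz <= windowHi
  tot <- sum(spectrum@intensity[sel])
  if (!any(sel) || tot <= 0)
    stop("no intensity inside the averaging window")
  sum(spectrum@mz[sel] * spectrum@intensity[sel]) / tot
}
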