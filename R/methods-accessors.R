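#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("mz", "Spectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("mz", "IsotopicEnvelope", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("abundance", "IsotopicEnvelope", function(object) object@abundance)

#' @rdname accessors
#' @export
setMethod("fragmentSequence", "PeptideFragment", function(object) object@sequence)

#' @rdname accessors
#' @export
setMethod("fractions", "CompositionProfile", function(object) {
  stats::setNames(object@fractions, paste0("f", seq_along(object@fractions) - 1L))
})

#' @rdname accessors
#' @export
setMethod("fractions", "HDXResult", function(object) fractions(object@profile))

#' @rdname accessors
#' @export
setMethod("nAmide", "CompositionProfile", function(object) object@nAmide)

#' @rdname accessors
#' @export
setMethod("nAmide", "PeptideFragment", function(object) {
  countExchangeSites(object)[["n_amide"]]
})

#' @rdname accessors
#' @export
setMethod("nAmide", "HDXResult", function(object) object@profile@nAmide)

#' @rdname accessors
#' @export
setMethod("peakCenters", "PeakVector", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("peakAreas", "PeakVector", function(object) object@areas)

setMethod("show", "PeptideFragment", function(object) {
  rng <- if (is.na(object@rangeStart)) "unmapped" else
    sprintf("%d-%d", object@rangeStart, object@rangeEnd)
  cat(sprintf("PeptideFragment '%s' (%s): %s  [%d aa, charge +1]\n",
              object@name, rng, object@sequence, nchar(object@sequence)))
})

setMethod("show", "IsotopicEnvelope", function(object) {
  cat(sprintf("IsotopicEnvelope '%s': %d peaks, m/z %.4f-%.4f\n",
              object@label, length(object@mz), min(object@mz), max(object@mz)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d points, m/z %.2f-%.2f, max intensity %.3g\n",
              object@label, length(object@mz), min(object@mz), max(object@mz),
              max(object@intensity)))
})

setMethod("show", "PeakVector", function(object) {
  cat(sprintf("PeakVector (%s): %d peaks, window +/-%.2f Da, total area %.4g\n",
              object@fragment@name, length(object@centers), object@halfWidth,
              sum(object@areas)))
})

setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf("CompositionProfile over %d amides%s\n", object@nAmide,
              if (object@degenerate) " (degenerate basis; non-unique)" else ""))
  f <- round(100 * object@fractions, 1)
  cat("  ", paste0("f", seq_along(f) - 1L, "=", f, "%", collapse = " "), "\n")
})

setMethod("show", "HDXResult", function(object) {
  cat(sprintf(paste0("HDXResult '%s': %.3f of %d amides exchanged ",
                     "(%.2f%%), residual %.3g\n"),
              object@spectrumLabel, object@avgExchanged,
              object@profile@nAmide, object@deutRatio, object@residualNorm))
})

setMethod("show", "UptakeTimeSeries", function(object) {
  cat(sprintf("UptakeTimeSeries %s/%s: %d time points (%g-%g min)\n",
              object@fragment, object@state, length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "KineticsFit", function(object) {
  k <- if (is.na(object@kObs)) "-" else sprintf("%.3g", object@kObs)
  cat(sprintf(paste0("KineticsFit %s/%s: Dinf=%.1f+/-%.1f  A=%.1f+/-%.1f  ",
                     "kObs=%s /min  D0=%.1f  (%s)\n"),
              object@fragment, object@state, object@dInf, object@dInfSE,
              object@amplitude, object@amplitudeSE, k, d0(object),
              if (object@converged) "converged" else "NOT converged"))
})
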